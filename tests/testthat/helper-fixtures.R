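# Shared fixture builders. All fixtures are constructed in code; masses are
# taken from the package's residue/element tables so expectations can be
# written against independent hand sums.

PROTON <- 1.007276466812

# an MS2 spectrum containing the light/heavy doublet of `pep_mass` at charge
# `z`, optionally with isotope envelopes and extra peaks
doublet_ms2 <- function(pep_mass, xl, z = 2L, scan_id = "ms2-1", rt = 10,
                        envelope_n = 1L, extra_mz = numeric(0),
                        partner_mass = 800, prec_charge = NA_integer_) {
  light <- (pep_mass + xl$short_arm$mono_mass) / z + PROTON
  heavy <- (pep_mass + xl$long_arm$mono_mass) / z + PROTON
  env <- function(mz0) mz0 + (seq_len(envelope_n) - 1L) * 1.00336 / z
  mzs <- c(env(light), env(heavy), extra_mz)
  ints <- c(1000 * 0.7^(seq_len(envelope_n) - 1L),
            800 * 0.7^(seq_len(envelope_n) - 1L),
            rep(100, length(extra_mz)))
  prec_mass <- pep_mass + partner_mass + xl$intact_mass
  pz <- if (is.na(prec_charge)) 3L else prec_charge
  spectrum(scan_id, 2L, rt, mzs, ints,
           precursor = precursor_ref("ms1-1", prec_mass / pz + PROTON,
                                     prec_charge, 1.2),
           ms1_precursor_mz = prec_mass / pz + PROTON)
}

# an MS3 spectrum whose precursor sits on a given m/z, linked to an MS2
ms3_on <- function(sel_mz, ms2, rt_offset = 0.5, scan_id = "ms3-1",
                   mz = c(200, 300, 400), intensity = c(10, 20, 30)) {
  spectrum(scan_id, 3L, ms2$retention_time + rt_offset, mz, intensity,
           precursor = precursor_ref(ms2$scan_id, sel_mz, NA_integer_, 2.0),
           ms1_precursor_mz = ms2$ms1_precursor_mz)
}

# pooled-hit rows in the shape assemble_csms() consumes
pooled_row <- function(scan = "s1", pair = 1L, origin = "doublet",
                       pair_mz = 500, seq = "PEPKTIDER", site = 4L,
                       acc = "P1", decoy = FALSE, entrap = FALSE,
                       mass = 1000, n = 1L, score = 50) {
  data.frame(ms2_scan_id = scan, pair_id = pair, origin = origin,
             pair_mz = pair_mz, sequence = seq, crosslink_site = site,
             accession = acc, is_decoy = decoy, is_entrapment = entrap,
             neutral_mass = mass, n = n, boosted_score = score,
             stringsAsFactors = FALSE)
}

# proteins data frame from a library (peptides wrapped as mini-proteins)
library_proteins <- function(lib) {
  data.frame(accession = lib$peptides$peptide_id,
             sequence = lib$peptides$sequence,
             is_decoy = FALSE, is_entrapment = FALSE, stringsAsFactors = FALSE)
}

true_keys <- function(sim) {
  unique(with(sim$sampled_crosslinks,
              xlms:::crosslink_key(peptide_a, site_a, peptide_b, site_b)))
}

# brute-force FDR thresholding oracle: try every item score as threshold
# (with both >= and > acceptance), recompute counts from scratch, and pick
# the acceptance set maximising accepted targets at estimated FDR <= target
brute_force_fdr <- function(scores, decoy_class, target) {
  best_tt <- -1L
  best <- rep(FALSE, length(scores))
  for (thr in unique(scores)) {
    for (strict in c(FALSE, TRUE)) {
      above <- if (strict) scores > thr else scores >= thr
      tt <- sum(above & decoy_class == "TT")
      td <- sum(above & decoy_class == "TD")
      dd <- sum(above & decoy_class == "DD")
      fdr <- if (tt == 0L) { if (td + dd == 0L) 0 else 1 } else max(0, td - dd) / tt
      if (fdr <= target && tt > best_tt) {
        best_tt <- tt
        best <- above & decoy_class == "TT"
      }
    }
  }
  best
}
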