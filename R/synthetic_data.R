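# Synthetic groupwise cross-linked peptide libraries and simulated MS2/MS3
# runs with known ground truth, emulating synthetic-library benchmark
# designs where peptides are cross-linked only within their group, so any
# inter-group identification is a known false positive.

LIBRARY_AA <- strsplit("ACDEFGHMNPQSTVWY", "")[[1]]  # no K/R: sites controlled

#' Generate a groupwise cross-linkable peptide library
#'
#' Random tryptic-like peptides (length 6-20, exactly one internal lysine as
#' the cross-link site, C-terminal K or R) partitioned into groups.
#' Admissible cross-links are all intra-group peptide pairs at their lysine
#' sites. Deterministic under `seed`.
#'
#' @param n_peptides Number of peptides (>= lower group size bound).
#' @param group_size_range Group sizes `c(low, high)`, default 6-10.
#' @param length_range Peptide lengths, default 6-20.
#' @param seed Integer seed.
#' @return Object of class `xl_library`: `peptides` (data frame with
#'   `peptide_id`, `sequence`, `group`, `site`), `groups` (named vector
#'   sequence -> group), `true_crosslinks` (data frame of admissible
#'   intra-group pairs), `seed`.
#' @export
make_library <- function(n_peptides, group_size_range = c(6L, 10L),
                         length_range = c(6L, 20L), seed = 1L) {
  stopifnot(n_peptides >= group_size_range[1])
  set.seed(seed)
  seqs <- character(0)
  while (length(seqs) < n_peptides) {
    len <- sample(length_range[1]:length_range[2], 1L)
    site <- sample(2:(len - 1L), 1L)
    aa <- sample(LIBRARY_AA, len - 1L, replace = TRUE)
    aa[site] <- "K"
    pep <- paste0(paste(aa, collapse = ""), sample(c("K", "R"), 1L))
    if (!pep %in% seqs) seqs <- c(seqs, pep)
  }
  # partition into groups with sizes inside the configured range
  sizes <- integer(0)
  remaining <- n_peptides
  while (remaining > 0L) {
    lo <- group_size_range[1]; hi <- group_size_range[2]
    if (remaining <= hi) {
      s <- remaining
    } else {
      s <- sample(lo:hi, 1L)
      # never strand a remainder smaller than the lower bound
      if (remaining - s < lo && remaining - s > 0L) s <- remaining - lo
    }
    sizes <- c(sizes, s)
    remaining <- remaining - s
  }
  group <- rep(seq_along(sizes), times = sizes)
  site <- vapply(seqs, function(p) {
    aa <- strsplit(p, "")[[1]]
    which(aa == "K" & seq_along(aa) < length(aa))[1]
  }, integer(1))
  peptides <- data.frame(peptide_id = paste0("SYN", seq_len(n_peptides)),
                         sequence = seqs, group = group, site = site,
                         stringsAsFactors = FALSE)
  pairs <- do.call(rbind, lapply(split(peptides, peptides$group), function(g) {
    if (nrow(g) < 2L) return(NULL)
    idx <- utils::combn(nrow(g), 2L)
    data.frame(peptide_a = g$sequence[idx[1, ]], site_a = g$site[idx[1, ]],
               peptide_b = g$sequence[idx[2, ]], site_b = g$site[idx[2, ]],
               group = g$group[1], stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  groups <- stats::setNames(peptides$group, peptides$sequence)
  structure(list(peptides = peptides, groups = groups,
                 true_crosslinks = pairs, seed = seed),
            class = "xl_library")
}

#' @export
print.xl_library <- function(x, ...) {
  cat(sprintf("<xl_library> %d peptides in %d groups, %d admissible cross-links (seed %d)\n",
              nrow(x$peptides), length(unique(x$peptides$group)),
              nrow(x$true_crosslinks), x$seed))
  invisible(x)
}

#' Default simulation parameters
#'
#' @param n_crosslinks Intra-group cross-links sampled per run.
#' @param ms3_per_doublet MS3 scans emitted per doublet pair (0-2); they
#'   alternate between the heavy and light doublet peak.
#' @param noise_peaks Uniform-m/z noise peaks added per spectrum.
#' @param frag_sample_frac Fraction of theoretical backbone ions present.
#' @param prec_tol_ppm,frag_tol_ppm Emission tolerances; m/z jitter is
#'   Gaussian with sigma = tolerance/3 (precursor-grade for doublet and
#'   precursor peaks, fragment-grade for backbone ions).
#' @param isotope_envelope_n Envelope members per doublet peak (2-3).
#' @param ms3_on_isotope_prob Probability that an MS3 precursor was selected
#'   on the +1 isotope instead of the monoisotopic peak.
#' @param linear_rate Linear-peptide bait MS2 spectra per cross-link event.
#' @param coisolation_rate Probability of an extra MS3 triggered on a
#'   non-doublet (co-isolated) peak per cross-link event.
#' @param rt_gradient Retention-time range (minutes) events are placed on.
#' @param doublet_charge Charge state of the doublet peaks.
#' @param mz_range Spectrum m/z range for noise placement.
#' @return Named list of parameters.
#' @export
sim_params <- function(n_crosslinks = 20L, ms3_per_doublet = 1L,
                       noise_peaks = 30L, frag_sample_frac = 0.7,
                       prec_tol_ppm = 10, frag_tol_ppm = 20,
                       isotope_envelope_n = 3L, ms3_on_isotope_prob = 0.3,
                       linear_rate = 0, coisolation_rate = 0,
                       rt_gradient = c(10, 60), doublet_charge = 2L,
                       mz_range = c(200, 1600)) {
  as.list(environment())
}

#' Simulate an MS2-MS3 cross-linking run
#'
#' For each sampled intra-group cross-link, emits one MS2 spectrum holding
#' both peptides' light/heavy doublet peaks (with isotope envelopes),
#' sampled backbone fragments of both stub-modified peptides and uniform
#' noise, plus MS3 spectra per doublet (linear b/y ions of the arm-carrying
#' peptide) at retention-time offsets below 5 minutes. Optionally emits
#' linear-peptide bait MS2 spectra and co-isolation artifact MS3 scans
#' (triggered on a non-doublet peak). Deterministic under `seed`.
#'
#' @param library An [make_library()] object.
#' @param spec A [crosslinker_spec()].
#' @param params A [sim_params()] list.
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, writes `run.mzML`, `ground_truth.tsv`,
#'   `library.fasta` (peptides wrapped as mini-proteins) and `groups.tsv`
#'   there.
#' @return List with `spectra` (in-memory `xl_spectra`), `truth` (per-scan
#'   ground-truth data frame), `sampled_crosslinks`, and the written file
#'   paths (when `out_dir` is given).
#' @export
simulate_run <- function(library, spec, params = sim_params(), seed = 1L,
                         out_dir = NULL) {
  set.seed(seed)
  stopifnot(inherits(library, "xl_library"), inherits(spec, "crosslinker_spec"))
  tc <- library$true_crosslinks
  n_xl <- min(params$n_crosslinks, nrow(tc))
  picked <- tc[sample(nrow(tc), n_xl), , drop = FALSE]

  jitter_prec <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, params$prec_tol_ppm / 3 * 1e-6))
  jitter_frag <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, params$frag_tol_ppm / 3 * 1e-6))
  noise_for <- function(n) {
    if (n == 0L) return(list(mz = numeric(0), intensity = numeric(0)))
    list(mz = stats::runif(n, params$mz_range[1], params$mz_range[2]),
         intensity = stats::rlnorm(n, meanlog = log(50), sdlog = 0.8))
  }
  env_factors <- c(1, 0.65, 0.3, 0.12)

  spectra <- list()
  truth <- list()
  scan_no <- 0L
  next_id <- function() {
    scan_no <<- scan_no + 1L
    paste0("scan=", scan_no)
  }

  # one survey MS1 scan carrying the cross-linked precursor peaks
  zc_all <- sample(3:4, n_xl, replace = TRUE)
  pep_mass_v <- function(x) vapply(x, peptide_mass, numeric(1), USE.NAMES = FALSE)
  prec_mass <- pep_mass_v(picked$peptide_a) + pep_mass_v(picked$peptide_b) +
    spec$intact_mass
  prec_mz <- mz_from_neutral(prec_mass, zc_all)
  ms1_id <- next_id()
  spectra[[ms1_id]] <- spectrum(ms1_id, 1L, min(params$rt_gradient),
                                mz = jitter_prec(prec_mz),
                                intensity = stats::rlnorm(n_xl, log(1e5), 0.5))
  truth[[ms1_id]] <- data.frame(scan_id = ms1_id, kind = "ms1",
                                peptide_a = NA, site_a = NA, peptide_b = NA,
                                site_b = NA, arm = NA, charge = NA,
                                crosslink_key = NA, stringsAsFactors = FALSE)

  rt_events <- sort(stats::runif(n_xl, params$rt_gradient[1], params$rt_gradient[2]))

  for (e in seq_len(n_xl)) {
    pa <- picked$peptide_a[e]; sa <- picked$site_a[e]
    pb <- picked$peptide_b[e]; sb <- picked$site_b[e]
    zc <- zc_all[e]
    zd <- params$doublet_charge
    rt2 <- rt_events[e]
    key <- crosslink_key(pa, sa, pb, sb)

    mz_vec <- numeric(0); int_vec <- numeric(0)
    doublet_info <- list()
    for (side in c("a", "b")) {
      pep <- if (side == "a") pa else pb
      m_pep <- peptide_mass(pep)
      base_int <- stats::rlnorm(1, log(5e3), 0.4)
      for (arm in c("light", "heavy")) {
        mono <- mz_from_neutral(m_pep + arm_mass(spec, arm), zd)
        env <- mono + (seq_len(params$isotope_envelope_n) - 1L) * NEUTRON_SPACING / zd
        mz_vec <- c(mz_vec, jitter_prec(env))
        int_vec <- c(int_vec, base_int * env_factors[seq_along(env)] *
                       (if (arm == "light") 1 else 0.8))
        doublet_info[[paste(side, arm)]] <- list(pep = pep, arm = arm,
                                                 mono_mz = mono, charge = zd)
      }
      # backbone fragments of the stub-modified peptide (light-arm form)
      fr <- theoretical_fragments(pep, crosslink_site = if (side == "a") sa else sb,
                                  spec = spec, arm = "light", max_frag_charge = 1L)
      keep <- stats::runif(nrow(fr)) < params$frag_sample_frac
      if (any(keep)) {
        mz_vec <- c(mz_vec, jitter_frag(fr$mz[keep]))
        int_vec <- c(int_vec, stats::rlnorm(sum(keep), log(800), 0.6))
      }
    }
    nz <- noise_for(params$noise_peaks)
    co_mz <- NULL
    if (stats::runif(1) < params$coisolation_rate) {
      # a non-doublet peak near the doublet region that the instrument will
      # wrongly pick for MS3
      co_mz <- stats::runif(1, params$mz_range[1] + 100, params$mz_range[2] - 100)
      nz$mz <- c(nz$mz, co_mz)
      nz$intensity <- c(nz$intensity, stats::rlnorm(1, log(4e3), 0.3))
    }
    ms2_id <- next_id()
    sel_prec <- jitter_prec(prec_mz[e])
    spectra[[ms2_id]] <- spectrum(
      ms2_id, 2L, rt2,
      mz = c(mz_vec, nz$mz), intensity = c(int_vec, nz$intensity),
      precursor = precursor_ref(ms1_id, sel_prec, zc, 1.2),
      ms1_precursor_mz = sel_prec)
    truth[[ms2_id]] <- data.frame(scan_id = ms2_id, kind = "ms2_crosslink",
                                  peptide_a = pa, site_a = sa, peptide_b = pb,
                                  site_b = sb, arm = NA, charge = zc,
                                  crosslink_key = key, stringsAsFactors = FALSE)

    # MS3 scans: per doublet pair, alternate heavy / light peak selection
    for (side in c("a", "b")) {
      pep <- if (side == "a") pa else pb
      site <- if (side == "a") sa else sb
      if (params$ms3_per_doublet < 1L) next
      arms <- rep(c("heavy", "light"), length.out = params$ms3_per_doublet)
      for (arm in arms) {
        info <- doublet_info[[paste(side, arm)]]
        on_iso <- stats::runif(1) < params$ms3_on_isotope_prob
        sel_mz <- info$mono_mz + (if (on_iso) NEUTRON_SPACING / info$charge else 0)
        fr <- theoretical_fragments(pep, crosslink_site = site, spec = spec,
                                    arm = arm, max_frag_charge = 1L)
        keep <- stats::runif(nrow(fr)) < params$frag_sample_frac
        nz3 <- noise_for(params$noise_peaks)
        ms3_id <- next_id()
        spectra[[ms3_id]] <- spectrum(
          ms3_id, 3L, rt2 + stats::runif(1, 0.01, 2),
          mz = c(jitter_frag(fr$mz[keep]), nz3$mz),
          intensity = c(stats::rlnorm(sum(keep), log(600), 0.6), nz3$intensity),
          precursor = precursor_ref(ms2_id, jitter_prec(sel_mz),
                                    NA_integer_, 2.0),
          ms1_precursor_mz = spectra[[ms2_id]]$ms1_precursor_mz)
        truth[[ms3_id]] <- data.frame(scan_id = ms3_id, kind = "ms3_product",
                                      peptide_a = pep, site_a = site,
                                      peptide_b = NA, site_b = NA, arm = arm,
                                      charge = info$charge,
                                      crosslink_key = key,
                                      stringsAsFactors = FALSE)
      }
    }
    if (!is.null(co_mz)) {
      nz3 <- noise_for(max(params$noise_peaks, 10L))
      ms3_id <- next_id()
      spectra[[ms3_id]] <- spectrum(
        ms3_id, 3L, rt2 + stats::runif(1, 0.01, 2),
        mz = nz3$mz, intensity = nz3$intensity,
        precursor = precursor_ref(ms2_id, jitter_prec(co_mz), NA_integer_, 2.0),
        ms1_precursor_mz = spectra[[ms2_id]]$ms1_precursor_mz)
      truth[[ms3_id]] <- data.frame(scan_id = ms3_id, kind = "ms3_artifact",
                                    peptide_a = NA, site_a = NA, peptide_b = NA,
                                    site_b = NA, arm = NA, charge = NA,
                                    crosslink_key = NA, stringsAsFactors = FALSE)
    }
    # linear-peptide bait MS2 spectra
    n_lin <- stats::rpois(1, params$linear_rate)
    for (l in seq_len(n_lin)) {
      pep <- sample(library$peptides$sequence, 1L)
      zl <- sample(2:3, 1L)
      m <- peptide_mass(pep)
      fr <- theoretical_fragments(pep, max_frag_charge = 1L)
      keep <- stats::runif(nrow(fr)) < max(params$frag_sample_frac, 0.8)
      nzl <- noise_for(params$noise_peaks)
      lid <- next_id()
      sel_lin <- jitter_prec(mz_from_neutral(m, zl))
      spectra[[lid]] <- spectrum(
        lid, 2L, rt2 + stats::runif(1, 0, 0.5),
        mz = c(jitter_frag(fr$mz[keep]), nzl$mz),
        intensity = c(stats::rlnorm(sum(keep), log(2e3), 0.5), nzl$intensity),
        precursor = precursor_ref(ms1_id, sel_lin, zl, 1.2),
        ms1_precursor_mz = sel_lin)
      truth[[lid]] <- data.frame(scan_id = lid, kind = "ms2_linear",
                                 peptide_a = pep, site_a = NA, peptide_b = NA,
                                 site_b = NA, arm = NA, charge = zl,
                                 crosslink_key = NA, stringsAsFactors = FALSE)
    }
  }

  spectra <- unname(spectra)
  class(spectra) <- "xl_spectra"
  truth <- do.call(rbind, unname(truth))
  rownames(truth) <- NULL
  out <- list(spectra = spectra, truth = truth, sampled_crosslinks = picked,
              library = library)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out$mzml_path <- file.path(out_dir, "run.mzML")
    write_mzml(spectra, out$mzml_path)
    out$truth_path <- file.path(out_dir, "ground_truth.tsv")
    utils::write.table(truth, out$truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$fasta_path <- file.path(out_dir, "library.fasta")
    write_fasta(data.frame(accession = library$peptides$peptide_id,
                           sequence = library$peptides$sequence),
                out$fasta_path)
    out$groups_path <- file.path(out_dir, "groups.tsv")
    utils::write.table(library$peptides[, c("sequence", "group")],
                       out$groups_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
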