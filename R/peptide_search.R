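# In-silico digestion, candidate generation, theoretical stub-modified
# fragments, and the binomial fragment-match scorer.

#' Tryptic (or custom) in-silico digestion of one protein
#'
#' Cleavage rules are expressed as a (cleave-after set, block-if-next set)
#' pair; the default is trypsin (cleave after K/R, not before P).
#'
#' @param sequence Protein sequence (uppercase).
#' @param enzyme List with `cleave_after` and `block_next` character vectors.
#' @param missed_cleavages_max Maximum number of missed cleavages.
#' @param length_range Allowed peptide lengths `c(min, max)`.
#' @param mass_range Allowed peptide neutral masses in Da `c(min, max)`.
#' @param fixed_mods Fixed modifications passed to [peptide_mass()].
#' @return Data frame with `sequence`, `start` (1-based position in the
#'   protein), `missed_cleavages`, `neutral_mass`, `is_prot_nterm`,
#'   `is_prot_cterm`.
#' @export
digest <- function(sequence,
                   enzyme = list(cleave_after = c("K", "R"), block_next = "P"),
                   missed_cleavages_max = 2L,
                   length_range = c(5L, 30L),
                   mass_range = c(400, 6000),
                   fixed_mods = c(C = CARBAMIDOMETHYL_DELTA)) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  empty <- data.frame(sequence = character(), start = integer(),
                      missed_cleavages = integer(), neutral_mass = numeric(),
                      is_prot_nterm = logical(), is_prot_cterm = logical(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  # cleavage sites: after position i when aa[i] in cleave_after and
  # aa[i+1] not in block_next
  cut_after <- which(aa %in% enzyme$cleave_after)
  cut_after <- cut_after[cut_after == n |
                           !(aa[pmin(cut_after + 1L, n)] %in% enzyme$block_next)]
  bounds <- c(0L, cut_after[cut_after < n], n)  # segment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  n_seg <- length(starts)
  rows <- list()
  for (i in seq_len(n_seg)) {
    for (mc in 0:missed_cleavages_max) {
      j <- i + mc
      if (j > n_seg) break
      len <- ends[j] - starts[i] + 1L
      if (len < length_range[1] || len > length_range[2]) next
      pep <- substr(sequence, starts[i], ends[j])
      m <- tryCatch(peptide_mass(pep, fixed_mods), error = function(e) NA_real_)
      if (is.na(m) || m < mass_range[1] || m > mass_range[2]) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = pep, start = starts[i], missed_cleavages = mc,
        neutral_mass = m,
        is_prot_nterm = starts[i] == 1L, is_prot_cterm = ends[j] == n,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Digest a whole protein database into a peptide index
#'
#' @param entries Protein data frame (from [read_fasta()] /
#'   [generate_decoys()]).
#' @param ... Passed to [digest()].
#' @return Data frame with one row per (peptide, protein) occurrence, adding
#'   `accession`, `is_decoy`, `is_entrapment` to the [digest()] columns.
#' @export
digest_database <- function(entries, ...) {
  pieces <- lapply(seq_len(nrow(entries)), function(i) {
    d <- digest(entries$sequence[i], ...)
    if (nrow(d) == 0L) return(NULL)
    d$accession <- entries$accession[i]
    d$is_decoy <- entries$is_decoy[i]
    d$is_entrapment <- entries$is_entrapment[i]
    d
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) {
    stop("digestion produced no peptides")
  }
  do.call(rbind, pieces)
}

#' Generate cross-link peptide candidates for a target mass
#'
#' Selects digested peptides whose neutral mass matches the cross-linker-free
#' target mass within tolerance and that carry at least one admissible
#' cross-link site: an internal reactive residue (the C-terminal K of a
#' tryptic peptide is not a site unless the peptide is protein C-terminal,
#' since a cross-linked K is not cleaved), or position 1 for protein
#' N-terminal peptides when the linker is N-terminus reactive. One candidate
#' is produced per admissible site.
#'
#' @param peptide_index Data frame from [digest_database()].
#' @param target_mass Cross-linker-free peptide mass (Da), from
#'   [peptide_mass_from_doublet()].
#' @param prec_tol_ppm Precursor mass tolerance (ppm).
#' @param spec A [crosslinker_spec()].
#' @param arm `"light"` or `"heavy"` — which arm remnant the candidate
#'   carries (affects fragment masses, not selection).
#' @return Data frame of candidates: peptide columns plus `crosslink_site`
#'   and `arm`.
#' @export
generate_candidates <- function(peptide_index, target_mass, prec_tol_ppm,
                                spec, arm) {
  arm <- match.arg(arm, c("light", "heavy"))
  tol <- ppm_tol_da(target_mass, prec_tol_ppm)
  hits <- peptide_index[abs(peptide_index$neutral_mass - target_mass) <= tol, ,
                        drop = FALSE]
  if (nrow(hits) == 0L) {
    hits$crosslink_site <- integer(0)
    hits$arm <- character(0)
    return(hits)
  }
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    sites <- admissible_sites(hits$sequence[i], spec,
                              is_prot_nterm = hits$is_prot_nterm[i],
                              is_prot_cterm = hits$is_prot_cterm[i])
    for (s in sites) {
      r <- hits[i, , drop = FALSE]
      r$crosslink_site <- s
      r$arm <- arm
      rows[[length(rows) + 1L]] <- r
    }
  }
  if (length(rows) == 0L) {
    hits <- hits[0, , drop = FALSE]
    hits$crosslink_site <- integer(0)
    hits$arm <- character(0)
    return(hits)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# admissible cross-link sites of a peptide
admissible_sites <- function(sequence, spec, is_prot_nterm = FALSE,
                             is_prot_cterm = FALSE) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  sites <- which(aa %in% spec$reactive_residues)
  # C-terminal residue of a tryptic peptide: only a site if protein C-terminal
  if (!is_prot_cterm) sites <- sites[sites != n]
  if (spec$protein_nterm_reactive && is_prot_nterm && !(1L %in% sites)) {
    sites <- c(1L, sites)
  }
  sort(sites)
}

#' Theoretical b/y fragment ions of a stub-modified peptide
#'
#' b- and y-ions at charges 1..`max_frag_charge`; ions containing the
#' cross-link site are shifted by the arm remnant mass (plus any product
#' delta).
#'
#' @param sequence Peptide sequence.
#' @param crosslink_site 1-based site position, or `NA` for a linear
#'   (unmodified) peptide.
#' @param spec A [crosslinker_spec()]; ignored when `crosslink_site` is `NA`.
#' @param arm `"light"` or `"heavy"`.
#' @param max_frag_charge Maximum fragment charge (default 2).
#' @param fixed_mods Fixed modifications (named per-residue deltas).
#' @param product_delta Alternative-cleavage product delta on the arm.
#' @return Data frame with `ion` (label), `mz`, `charge`.
#' @export
theoretical_fragments <- function(sequence, crosslink_site = NA_integer_,
                                  spec = NULL, arm = "light",
                                  max_frag_charge = 2L,
                                  fixed_mods = c(C = CARBAMIDOMETHYL_DELTA),
                                  product_delta = 0) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(aa)
  empty <- data.frame(ion = character(), mz = numeric(), charge = integer(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  res <- RESIDUE_MONO[aa]
  mod_hit <- aa %in% names(fixed_mods)
  if (any(mod_hit)) res[mod_hit] <- res[mod_hit] + fixed_mods[aa[mod_hit]]
  shift <- 0
  if (!is.na(crosslink_site)) {
    stopifnot(!is.null(spec), crosslink_site >= 1L, crosslink_site <= n)
    shift <- arm_mass(spec, arm) + product_delta
  }
  cum <- cumsum(res)
  b_neutral <- cum[-n]                       # b_i: residues 1..i
  y_neutral <- (cum[n] - cum[-n]) + H2O_MASS # y_i: residues (n-i+1)..n
  if (!is.na(crosslink_site)) {
    i_idx <- seq_len(n - 1L)
    # b_i covers residues 1..i, the y ion at the same index covers i+1..n
    b_neutral <- b_neutral + ifelse(i_idx >= crosslink_site, shift, 0)
    y_neutral <- y_neutral + ifelse(i_idx < crosslink_site, shift, 0)
  }
  rows <- list()
  for (z in seq_len(max_frag_charge)) {
    rows[[length(rows) + 1L]] <- data.frame(
      ion = paste0("b", seq_len(n - 1L), ifelse(z > 1, paste0("^", z), "")),
      mz = b_neutral / z + PROTON_MASS, charge = z, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      ion = paste0("y", rev(seq_len(n - 1L)), ifelse(z > 1, paste0("^", z), "")),
      mz = y_neutral / z + PROTON_MASS, charge = z, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score a peptide-spectrum match (binomial fragment-match scorer)
#'
#' The score is `-10 * log10 P(X >= k)` for a Binomial(n, p) variable, where
#' `n` is the number of theoretical ions, `k` the number matched within the
#' fragment tolerance, and `p` the per-ion random-match probability estimated
#' as `2 * tol_width * n_peaks / span` of the observed spectrum. Zero matched
#' ions score 0. The scorer is deterministic and order-preserving in match
#' quality; it replaces an external search-engine score while keeping all
#' downstream min/max/boost propagation unchanged.
#'
#' @param spec_obj A [spectrum()] (MS2 or MS3).
#' @param fragments Theoretical fragment table from
#'   [theoretical_fragments()].
#' @param frag_tol Fragment tolerance value.
#' @param tol_unit `"ppm"` (Orbitrap-like) or `"da"` (ion-trap-like).
#' @return List with `raw_score`, `matched_ions`, `n_theoretical`.
#' @export
score_match <- function(spec_obj, fragments, frag_tol = 20, tol_unit = "ppm") {
  tol_unit <- match.arg(tolower(tol_unit), c("ppm", "da"))
  n_theo <- nrow(fragments)
  if (n_theo == 0L || length(spec_obj$mz) == 0L) {
    return(list(raw_score = 0, matched_ions = 0L, n_theoretical = n_theo))
  }
  obs <- spec_obj$mz
  tol_of <- function(mz) if (tol_unit == "ppm") ppm_tol_da(mz, frag_tol) else frag_tol
  matched <- vapply(fragments$mz, function(m) {
    any(abs(obs - m) <= tol_of(m))
  }, logical(1))
  k <- sum(matched)
  if (k == 0L) {
    return(list(raw_score = 0, matched_ions = 0L, n_theoretical = n_theo))
  }
  span <- max(obs) - min(obs)
  mean_tol <- if (tol_unit == "ppm") ppm_tol_da(mean(fragments$mz), frag_tol) else frag_tol
  p <- 2 * mean_tol * length(obs) / max(span, 1e-6)
  p <- min(max(p, 1e-12), 1 - 1e-12)
  # -10*log10 of the upper binomial tail P(X >= k)
  log_tail <- stats::pbinom(k - 1L, n_theo, p, lower.tail = FALSE, log.p = TRUE)
  score <- -10 * log_tail / log(10)
  list(raw_score = max(score, 0), matched_ions = as.integer(k),
       n_theoretical = as.integer(n_theo))
}

#' Flag MS2 spectra confidently explained by linear peptides
#'
#' Scores each MS2 spectrum against linear (non-cross-linked) peptide
#' candidates selected by its declared precursor mass and flags scans whose
#' best linear match passes a target-decoy q-value threshold; flagged scans
#' are excluded from the cross-link search.
#'
#' @param spectra `xl_spectra` collection (only MS2 scans are considered).
#' @param peptide_index Digested target+decoy peptide index.
#' @param threshold q-value threshold (default 0.01).
#' @param prec_tol_ppm Precursor tolerance (ppm).
#' @param frag_tol,tol_unit Fragment tolerance for scoring.
#' @param max_charge Charges enumerated when the precursor charge is unknown.
#' @return Character vector of flagged MS2 scan ids.
#' @export
linear_prefilter <- function(spectra, peptide_index, threshold = 0.01,
                             prec_tol_ppm = 10, frag_tol = 20,
                             tol_unit = "ppm", max_charge = 4L) {
  ms2 <- spectra[ms_level_of(spectra) == 2L]
  if (length(ms2) == 0L) return(character(0))
  best <- data.frame(scan_id = character(), score = numeric(),
                     is_decoy = logical(), stringsAsFactors = FALSE)
  for (s in ms2) {
    if (is.null(s$precursor)) next
    zs <- if (!is.na(s$precursor$selected_charge)) s$precursor$selected_charge
          else seq_len(max_charge)
    top_score <- 0; top_decoy <- NA
    for (z in zs) {
      target <- neutral_from_mz(s$precursor$selected_mz, z)
      tol <- ppm_tol_da(target, prec_tol_ppm)
      cand <- peptide_index[abs(peptide_index$neutral_mass - target) <= tol, ,
                            drop = FALSE]
      if (nrow(cand) == 0L) next
      for (i in seq_len(nrow(cand))) {
        fr <- theoretical_fragments(cand$sequence[i])
        sc <- score_match(s, fr, frag_tol, tol_unit)
        if (sc$raw_score > top_score) {
          top_score <- sc$raw_score
          top_decoy <- cand$is_decoy[i]
        }
      }
    }
    if (!is.na(top_decoy) && top_score > 0) {
      best <- rbind(best, data.frame(scan_id = s$scan_id, score = top_score,
                                     is_decoy = top_decoy,
                                     stringsAsFactors = FALSE))
    }
  }
  if (nrow(best) == 0L) return(character(0))
  # simple target-decoy q-value on best-per-scan linear hits
  o <- order(-best$score)
  best <- best[o, , drop = FALSE]
  fdr <- cumsum(best$is_decoy) / pmax(cumsum(!best$is_decoy), 1L)
  qval <- rev(cummin(rev(fdr)))
  best$scan_id[!best$is_decoy & qval <= threshold]
}
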