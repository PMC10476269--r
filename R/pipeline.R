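# End-to-end search pipeline, run configuration and result exporters.

#' Search run configuration
#'
#' @param crosslinker Cross-linker name or config path for
#'   [load_crosslinker()].
#' @param prec_tol_ppm Precursor mass tolerance in ppm (default 10).
#' @param frag_tol Fragment tolerance (default 20).
#' @param frag_tol_unit `"ppm"` (Orbitrap-like) or `"da"` (ion-trap-like).
#' @param max_charge Charge states enumerated when inference fails
#'   (default 4).
#' @param max_frag_charge Maximum fragment ion charge (default 2).
#' @param rt_window MS3 mapping retention-time window in minutes (default 5).
#' @param boost_p Multi-scan boost parameter (default 20).
#' @param fdr_csm,fdr_crosslink Two-step FDR targets (defaults 0.01).
#' @param prefilter_q Linear-peptide prefilter q-value threshold (default
#'   0.01); `NA` disables the prefilter.
#' @param use_ms2_supplement Also score the MS2 spectrum for peptides that
#'   have MS3 evidence (default `TRUE`).
#' @param missed_cleavages Maximum missed cleavages in digestion.
#' @param peptide_length,peptide_mass_range Digestion bounds.
#' @param intensity_ratio_band Doublet light/heavy intensity acceptance band.
#' @param seed Seed for any stochastic steps (the search itself is
#'   deterministic; kept for config completeness).
#' @return Named list of class `xl_config`.
#' @export
run_config <- function(crosslinker = "DSSO", prec_tol_ppm = 10,
                       frag_tol = 20, frag_tol_unit = "ppm",
                       max_charge = 4L, max_frag_charge = 2L,
                       rt_window = 5, boost_p = 20,
                       fdr_csm = 0.01, fdr_crosslink = 0.01,
                       prefilter_q = 0.01, use_ms2_supplement = TRUE,
                       missed_cleavages = 2L, peptide_length = c(5L, 30L),
                       peptide_mass_range = c(400, 6000),
                       intensity_ratio_band = c(0.1, 10), seed = 1L) {
  stopifnot(prec_tol_ppm > 0, frag_tol > 0,
            fdr_csm > 0, fdr_csm < 1, fdr_crosslink > 0, fdr_crosslink < 1)
  structure(as.list(environment()), class = "xl_config")
}

#' Run the full MS2-MS3 cross-link search
#'
#' Pipeline: linear prefilter -> doublet detection in MS2 scans -> MS3 to
#' doublet mapping and precursor mass correction -> candidate generation and
#' fragment-match scoring (MS3 scans plus, optionally, the MS2 itself; when
#' only one peptide of a pair has doublet evidence, the partner is searched
#' in the MS2 at the complementary precursor mass) -> per-peptide pooling
#' and multi-scan boosting -> CSM assembly -> cross-link grouping ->
#' two-step target-decoy FDR.
#'
#' @param spectra `xl_spectra` collection (from [read_mzml()] or
#'   [simulate_run()]).
#' @param proteins Target protein data frame from [read_fasta()]; reversed
#'   decoys are generated internally.
#' @param config An [run_config()] object.
#' @return List of class `xl_result`: `csms`, `crosslinks`,
#'   `accepted_crosslinks`, `csm_fdr`, `crosslink_fdr`, `stats` (stage
#'   counts), `config`.
#' @export
run_search <- function(spectra, proteins, config = run_config()) {
  spec <- load_crosslinker(config$crosslinker)
  database <- rbind(proteins, generate_decoys(proteins))
  index <- digest_database(database,
                           missed_cleavages_max = config$missed_cleavages,
                           length_range = config$peptide_length,
                           mass_range = config$peptide_mass_range)

  lvl <- ms_level_of(spectra)
  ms2_scans <- spectra[lvl == 2L]
  ms3_scans <- spectra[lvl == 3L]
  stats <- list(n_spectra = length(spectra), n_ms2 = length(ms2_scans),
                n_ms3 = length(ms3_scans))
  if (length(ms3_scans) == 0L && length(ms2_scans) > 0L) {
    warning("no MS3 scans present; proceeding in MS2-only mode")
  }

  flagged <- character(0)
  if (!is.na(config$prefilter_q)) {
    flagged <- linear_prefilter(spectra, index, threshold = config$prefilter_q,
                                prec_tol_ppm = config$prec_tol_ppm,
                                frag_tol = config$frag_tol,
                                tol_unit = config$frag_tol_unit,
                                max_charge = config$max_charge)
  }
  stats$n_prefiltered <- length(flagged)

  all_pooled <- list()
  ms2_by_id <- stats::setNames(ms2_scans,
                               vapply(ms2_scans, `[[`, character(1), "scan_id"))
  n_doublets <- 0L
  n_assigned_ms3 <- 0L

  for (ms2 in ms2_scans) {
    if (ms2$scan_id %in% flagged) next
    doublets <- detect_doublets(ms2, spec,
                                frag_tol_ppm = if (config$frag_tol_unit == "ppm")
                                  config$frag_tol else 20,
                                max_charge = config$max_charge,
                                intensity_ratio_band = config$intensity_ratio_band,
                                prec_tol_ppm = config$prec_tol_ppm)
    if (nrow(doublets) == 0L) next
    n_doublets <- n_doublets + nrow(doublets) / 2L
    assignments <- map_ms3_to_doublets(ms2, doublets, ms3_scans, spec,
                                       prec_tol_ppm = config$prec_tol_ppm,
                                       rt_window = config$rt_window)
    n_assigned_ms3 <- n_assigned_ms3 + nrow(assignments)

    prec_neutral <- NA_real_
    if (!is.null(ms2$precursor) && !is.na(ms2$precursor$selected_charge)) {
      prec_neutral <- neutral_from_mz(ms2$precursor$selected_mz,
                                      ms2$precursor$selected_charge)
    }

    psms <- list()
    add_psms <- function(cands, scan_obj, origin, pair_id, pair_mz,
                         arms_to_try) {
      if (nrow(cands) == 0L) return()
      for (i in seq_len(nrow(cands))) {
        best <- 0; best_m <- 0L
        for (arm_try in arms_to_try) {
          fr <- theoretical_fragments(cands$sequence[i],
                                      cands$crosslink_site[i], spec, arm_try,
                                      max_frag_charge = config$max_frag_charge)
          sc <- score_match(scan_obj, fr, config$frag_tol, config$frag_tol_unit)
          if (sc$raw_score > best) { best <- sc$raw_score; best_m <- sc$matched_ions }
        }
        if (best <= 0) next
        psms[[length(psms) + 1L]] <<- data.frame(
          ms2_scan_id = ms2$scan_id, scan_id = scan_obj$scan_id,
          pair_id = pair_id, origin = origin, pair_mz = pair_mz,
          sequence = cands$sequence[i], crosslink_site = cands$crosslink_site[i],
          accession = cands$accession[i], is_decoy = cands$is_decoy[i],
          is_entrapment = cands$is_entrapment[i],
          neutral_mass = cands$neutral_mass[i],
          raw_score = best, matched_ions = best_m, stringsAsFactors = FALSE)
      }
    }

    ms3_ids <- vapply(ms3_scans, `[[`, character(1), "scan_id")
    pairs <- unique(doublets$pair_id)
    for (pid in pairs) {
      dpair <- doublets[doublets$pair_id == pid, , drop = FALSE]
      pep_mass <- dpair$peptide_mass[1]
      pair_mz <- min(dpair$mz)
      asg <- assignments[assignments$pair_id == pid, , drop = FALSE]
      # MS3 evidence
      if (nrow(asg)) {
        for (k in seq_len(nrow(asg))) {
          s3 <- ms3_scans[[match(asg$ms3_scan_id[k], ms3_ids)]]
          cands <- generate_candidates(index, asg$adjusted_precursor_mass[k],
                                       config$prec_tol_ppm, spec, asg$arm[k])
          add_psms(cands, s3, "doublet", pid, pair_mz, asg$arm[k])
        }
      }
      # MS2 evidence for this peptide (fallback when no MS3, supplement
      # otherwise)
      if (nrow(asg) == 0L || config$use_ms2_supplement) {
        cands <- generate_candidates(index, pep_mass, config$prec_tol_ppm,
                                     spec, "light")
        add_psms(cands, ms2, "doublet", pid, pair_mz, c("light", "heavy"))
      }
      # complementary-mass search: the partner peptide implied by this pair
      # and the MS1 precursor, looked for in the MS2 spectrum (covers
      # partners whose own doublet went undetected)
      if (!is.na(prec_neutral)) {
        partner_mass <- prec_neutral - spec$intact_mass - pep_mass
        if (partner_mass > 0) {
          partner_mz <- mz_from_neutral(partner_mass + spec$short_arm$mono_mass,
                                        dpair$charge[1])
          cands <- generate_candidates(index, partner_mass,
                                       config$prec_tol_ppm, spec, "light")
          add_psms(cands, ms2, "complement", pid, partner_mz,
                   c("light", "heavy"))
        }
      }
    }
    if (length(psms) == 0L) next
    psms <- do.call(rbind, psms)

    # pool per (pair, origin, peptide, site) across unique MSn scans and boost
    pool_key <- paste(psms$pair_id, psms$origin, psms$sequence,
                      psms$crosslink_site, sep = "\r")
    pooled <- do.call(rbind, lapply(split(seq_len(nrow(psms)), pool_key),
                                    function(idx) {
      grp <- psms[idx, , drop = FALSE]
      ph <- pool_and_boost(grp$raw_score, grp$scan_id, config$boost_p)
      data.frame(ms2_scan_id = grp$ms2_scan_id[1], pair_id = grp$pair_id[1],
                 origin = grp$origin[1], pair_mz = grp$pair_mz[1],
                 sequence = grp$sequence[1],
                 crosslink_site = grp$crosslink_site[1],
                 accession = grp$accession[1], is_decoy = grp$is_decoy[1],
                 is_entrapment = grp$is_entrapment[1],
                 neutral_mass = grp$neutral_mass[1],
                 n = ph$n, boosted_score = ph$boosted_score,
                 stringsAsFactors = FALSE)
    }))
    all_pooled[[length(all_pooled) + 1L]] <- pooled
  }

  csms <- if (length(all_pooled)) {
    do.call(rbind, lapply(all_pooled, function(p)
      assemble_csms(p, ms2_by_id[[p$ms2_scan_id[1]]], spec,
                    config$prec_tol_ppm)))
  } else {
    assemble_csms(NULL)
  }
  rownames(csms) <- NULL
  stats$n_doublet_pairs <- n_doublets
  stats$n_assigned_ms3 <- n_assigned_ms3
  stats$n_csms <- nrow(csms)

  val <- two_step_validate(csms, config$fdr_csm, config$fdr_crosslink)
  stats$n_csms_validated <- nrow(val$csms)
  stats$n_crosslinks <- nrow(val$crosslinks)
  stats$n_accepted_crosslinks <- nrow(val$accepted_crosslinks)

  structure(list(csms = csms, crosslinks = val$crosslinks,
                 accepted_crosslinks = val$accepted_crosslinks,
                 csm_fdr = val$csm_fdr, crosslink_fdr = val$crosslink_fdr,
                 stats = stats, config = config),
            class = "xl_result")
}

#' @export
print.xl_result <- function(x, ...) {
  s <- x$stats
  cat("<xl_result>\n")
  cat(sprintf("  spectra: %d (MS2 %d, MS3 %d; %d prefiltered as linear)\n",
              s$n_spectra, s$n_ms2, s$n_ms3, s$n_prefiltered))
  cat(sprintf("  doublet pairs: %d; assigned MS3: %d\n",
              s$n_doublet_pairs, s$n_assigned_ms3))
  cat(sprintf("  CSMs: %d (%d above CSM-level threshold)\n",
              s$n_csms, s$n_csms_validated))
  cat(sprintf("  cross-links: %d grouped, %d accepted at %.1f%%/%.1f%% FDR\n",
              s$n_crosslinks, s$n_accepted_crosslinks,
              100 * x$config$fdr_csm, 100 * x$config$fdr_crosslink))
  invisible(x)
}

#' Write CSM and cross-link result tables
#'
#' Tab-separated tables with stable column names, plus a JSON run summary
#' with the stage counts.
#'
#' @param result An `xl_result` from [run_search()].
#' @param out_dir Output directory (created if missing).
#' @return Named vector of written paths, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(csms = file.path(out_dir, "csms.tsv"),
             crosslinks = file.path(out_dir, "crosslinks.tsv"),
             summary = file.path(out_dir, "run_summary.json"))
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
    df
  }
  utils::write.table(fmt(result$csms), paths["csms"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fmt(result$accepted_crosslinks), paths["crosslinks"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$stats, paths["summary"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Export cross-links to xiNET/xiVIEW CSV
#'
#' One row per cross-link with peptide sequences, link positions (1-based
#' within the peptide), protein accessions, peptide start positions within
#' the protein (1-based) and absolute protein-level link positions
#' (`AbsPos = PepPos + LinkPos - 1`). Cross-links whose peptides cannot be
#' located in any supplied protein are skipped with a warning.
#'
#' @param crosslinks Cross-link data frame (e.g. `accepted_crosslinks`).
#' @param proteins Protein data frame for position lookup.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_xiview <- function(crosslinks, proteins, path) {
  cols <- c("Protein1", "Protein2", "PepSeq1", "PepSeq2", "PepPos1",
            "PepPos2", "LinkPos1", "LinkPos2", "AbsPos1", "AbsPos2",
            "Score", "Id")
  rows <- list()
  skipped <- 0L
  locate <- function(pep, acc) {
    hit <- proteins[proteins$accession == acc, , drop = FALSE]
    if (nrow(hit) == 0L) return(NA_integer_)
    pos <- regexpr(pep, hit$sequence[1], fixed = TRUE)
    if (pos < 0L) NA_integer_ else as.integer(pos)
  }
  for (i in seq_len(nrow(crosslinks))) {
    x <- crosslinks[i, ]
    p1 <- locate(x$peptide_a, x$accession_a)
    p2 <- locate(x$peptide_b, x$accession_b)
    if (is.na(p1) || is.na(p2)) {
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      Protein1 = x$accession_a, Protein2 = x$accession_b,
      PepSeq1 = x$peptide_a, PepSeq2 = x$peptide_b,
      PepPos1 = p1, PepPos2 = p2,
      LinkPos1 = x$site_a, LinkPos2 = x$site_b,
      AbsPos1 = p1 + x$site_a - 1L, AbsPos2 = p2 + x$site_b - 1L,
      Score = x$score, Id = i, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
  if (skipped > 0L) {
    warning(skipped, " cross-link(s) skipped: peptide not found in any ",
            "supplied protein")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
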