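# Pooling of peptide hits across MSn stages, multi-scan boosting, CSM and
# cross-link assembly, and two-step target-decoy FDR validation.

#' Pool a peptide's scores across MSn scans and boost
#'
#' A peptide identified in an MS2 scan and one or more of its product MS3
#' scans gains confidence with each additional scan. The pooled score is
#'
#'   `boosted = max(scores) * (1 + p/100)^(n - 1)`
#'
#' where `n` is the number of unique MSn scans the peptide was identified in
#' and `p` the boost parameter: `p = 0` leaves the maximum score unchanged,
#' `p = 100` doubles it for every additional scan. Default `p = 20`.
#'
#' @param scores Numeric vector of raw scores for one peptide, one element
#'   per contributing scan.
#' @param scan_ids Scan identifiers parallel to `scores`; `n` is the number
#'   of distinct ids.
#' @param p Boost parameter (>= 0).
#' @return List with `scores`, `n`, `p`, `max_score`, `boosted_score`.
#' @export
pool_and_boost <- function(scores, scan_ids, p = 20) {
  if (length(scores) == 0L) stop("cannot pool an empty score vector")
  stopifnot(length(scores) == length(scan_ids), p >= 0)
  n <- length(unique(scan_ids))
  mx <- max(scores)
  list(scores = scores, n = n, p = p, max_score = mx,
       boosted_score = mx * (1 + p / 100)^(n - 1L))
}

decoy_class_of <- function(alpha_is_decoy, beta_is_decoy) {
  ifelse(!alpha_is_decoy & !beta_is_decoy, "TT",
         ifelse(alpha_is_decoy & beta_is_decoy, "DD", "TD"))
}

#' Assemble cross-link spectrum matches from pooled peptide hits
#'
#' For each MS2 scan, combines the two cross-linked peptides into one CSM.
#' Candidate combinations are enumerated across the scan's doublet pairs
#' (best hit per pair), plus each pair's complementary-mass hit searched in
#' the MS2 spectrum; combinations failing the MS1 precursor-sum check
#' (peptide A + peptide B + intact cross-linker vs. the declared MS1
#' precursor mass) are dropped — the check is applied only when the MS2
#' precursor charge is known. The best surviving combination (largest
#' min-score) becomes the scan's CSM. The CSM score is the smaller of the
#' two boosted peptide scores; the alpha peptide is the one associated with
#' the doublet of lower m/z; the decoy class (TT/TD/DD) follows from the
#' two candidates' decoy flags.
#'
#' @param pooled Data frame of pooled hits with columns `ms2_scan_id`,
#'   `pair_id`, `origin` (`"doublet"` for hits derived from a detected
#'   doublet pair, `"complement"` for partner hits found in the MS2 at the
#'   complementary precursor mass), `pair_mz` (doublet light-peak m/z, used
#'   for alpha/beta ordering), `sequence`, `crosslink_site`, `accession`,
#'   `is_decoy`, `is_entrapment`, `neutral_mass`, `n`, `boosted_score`.
#' @param ms2 The MS2 [spectrum()] (for the precursor-sum check), or `NULL`
#'   to skip the check.
#' @param spec A [crosslinker_spec()], required for the check.
#' @param prec_tol_ppm Precursor tolerance (ppm).
#' @return Data frame of CSMs (possibly empty): `ms2_scan_id`, alpha/beta
#'   peptide columns, `score`, `decoy_class`, `contains_entrapment`.
#' @export
assemble_csms <- function(pooled, ms2 = NULL, spec = NULL, prec_tol_ppm = 10) {
  empty <- data.frame(ms2_scan_id = character(),
                      alpha_sequence = character(), alpha_site = integer(),
                      alpha_accession = character(), alpha_score = numeric(),
                      alpha_n = integer(), alpha_is_decoy = logical(),
                      beta_sequence = character(), beta_site = integer(),
                      beta_accession = character(), beta_score = numeric(),
                      beta_n = integer(), beta_is_decoy = logical(),
                      score = numeric(), decoy_class = character(),
                      contains_entrapment = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(pooled) || nrow(pooled) == 0L) return(empty)
  if (is.null(pooled$origin)) pooled$origin <- "doublet"
  if (is.null(pooled$pair_mz)) pooled$pair_mz <- pooled$pair_id
  prec_neutral <- NA_real_
  if (!is.null(ms2) && !is.null(ms2$precursor) &&
      !is.na(ms2$precursor$selected_charge)) {
    prec_neutral <- neutral_from_mz(ms2$precursor$selected_mz,
                                    ms2$precursor$selected_charge)
  }
  sum_ok <- function(a, b) {
    if (is.na(prec_neutral) || is.null(spec)) return(TRUE)
    implied <- a$neutral_mass + b$neutral_mass + spec$intact_mass
    abs(implied - prec_neutral) <= ppm_tol_da(prec_neutral, prec_tol_ppm)
  }
  rows <- list()
  for (scan in unique(pooled$ms2_scan_id)) {
    ph <- pooled[pooled$ms2_scan_id == scan, , drop = FALSE]
    # best hit per (doublet pair, origin)
    bk <- paste(ph$pair_id, ph$origin)
    best <- do.call(rbind, lapply(split(seq_len(nrow(ph)), bk), function(idx) {
      g <- ph[idx, , drop = FALSE]
      g[which.max(g$boosted_score), , drop = FALSE]
    }))
    dbl <- best[best$origin == "doublet", , drop = FALSE]
    cmp <- best[best$origin == "complement", , drop = FALSE]
    combos <- list()
    np <- nrow(dbl)
    if (np >= 2L) {
      for (i in seq_len(np - 1L)) for (j in seq((i + 1L), np)) {
        a <- dbl[i, , drop = FALSE]; b <- dbl[j, , drop = FALSE]
        if (a$sequence == b$sequence && a$crosslink_site == b$crosslink_site &&
            a$pair_id == b$pair_id) next
        if (sum_ok(a, b)) combos[[length(combos) + 1L]] <- list(a = a, b = b)
      }
    }
    # a doublet pair plus the complementary-mass hit searched in the MS2
    for (i in seq_len(np)) {
      ci <- cmp[cmp$pair_id == dbl$pair_id[i], , drop = FALSE]
      if (nrow(ci) == 0L) next
      a <- dbl[i, , drop = FALSE]
      if (sum_ok(a, ci)) combos[[length(combos) + 1L]] <- list(a = a, b = ci)
    }
    if (length(combos) == 0L) next  # one-sided evidence only: no CSM
    # dedupe by unordered peptide pair, keep best min-score, then pick the
    # scan's best combination
    keys <- vapply(combos, function(cb)
      crosslink_key(cb$a$sequence, cb$a$crosslink_site,
                    cb$b$sequence, cb$b$crosslink_site), character(1))
    sc <- vapply(combos, function(cb)
      min(cb$a$boosted_score, cb$b$boosted_score), numeric(1))
    keep <- !duplicated(keys) | sc == stats::ave(sc, keys, FUN = max)
    pick <- which.max(ifelse(keep, sc, -Inf))
    a <- combos[[pick]]$a; b <- combos[[pick]]$b
    # alpha is the peptide of the lower-m/z doublet
    if (b$pair_mz < a$pair_mz) { tmp <- a; a <- b; b <- tmp }
    rows[[length(rows) + 1L]] <- data.frame(
      ms2_scan_id = scan,
      alpha_sequence = a$sequence, alpha_site = a$crosslink_site,
      alpha_accession = a$accession, alpha_score = a$boosted_score,
      alpha_n = a$n, alpha_is_decoy = a$is_decoy,
      beta_sequence = b$sequence, beta_site = b$crosslink_site,
      beta_accession = b$accession, beta_score = b$boosted_score,
      beta_n = b$n, beta_is_decoy = b$is_decoy,
      score = min(a$boosted_score, b$boosted_score),
      decoy_class = decoy_class_of(a$is_decoy, b$is_decoy),
      contains_entrapment = isTRUE(a$is_entrapment) || isTRUE(b$is_entrapment),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# unordered (sequence, site) pair key
crosslink_key <- function(seq_a, site_a, seq_b, site_b) {
  a <- paste0(seq_a, ":", site_a)
  b <- paste0(seq_b, ":", site_b)
  ifelse(a <= b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

#' Group CSMs of the same peptide pair into cross-links
#'
#' CSMs are keyed by the unordered (sequence, cross-link position) pair. The
#' cross-link score is the maximum score of its member CSMs; its decoy class
#' and orientation are taken from the maximum-scoring CSM.
#'
#' @param csms CSM data frame from [assemble_csms()].
#' @return Data frame of cross-links: peptide columns, `key`, `n_csms`,
#'   `csm_scan_ids`, `score`, `decoy_class`, `contains_entrapment`.
#' @export
group_crosslinks <- function(csms) {
  empty <- data.frame(key = character(), peptide_a = character(),
                      site_a = integer(), accession_a = character(),
                      peptide_b = character(), site_b = integer(),
                      accession_b = character(), n_csms = integer(),
                      csm_scan_ids = character(), score = numeric(),
                      decoy_class = character(),
                      contains_entrapment = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(csms) == 0L) return(empty)
  key <- crosslink_key(csms$alpha_sequence, csms$alpha_site,
                       csms$beta_sequence, csms$beta_site)
  rows <- lapply(split(seq_len(nrow(csms)), key), function(idx) {
    grp <- csms[idx, , drop = FALSE]
    top <- grp[which.max(grp$score), , drop = FALSE]
    data.frame(
      key = crosslink_key(top$alpha_sequence, top$alpha_site,
                          top$beta_sequence, top$beta_site),
      peptide_a = top$alpha_sequence, site_a = top$alpha_site,
      accession_a = top$alpha_accession,
      peptide_b = top$beta_sequence, site_b = top$beta_site,
      accession_b = top$beta_accession,
      n_csms = nrow(grp),
      csm_scan_ids = paste(grp$ms2_scan_id, collapse = ";"),
      score = max(grp$score),
      decoy_class = top$decoy_class,
      contains_entrapment = any(grp$contains_entrapment),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-decoy FDR estimation and thresholding
#'
#' Items are sorted by descending score; at each candidate threshold the FDR
#' is estimated as `max(0, TD - DD) / TT` over the items at or above it (DD
#' matches estimate the rate at which TD matches arise by chance, so they are
#' subtracted). Candidate thresholds are the distinct item scores, so tied
#' items are always accepted or rejected together (a cut inside a tie run is
#' not achievable by score thresholding); the lowest threshold whose
#' estimate is at or below `target` is returned, which maximises the number
#' of accepted targets. The result is identical to exhaustively scanning
#' every achievable acceptance set.
#'
#' @param scores Numeric score vector.
#' @param decoy_class Character vector (`"TT"`, `"TD"`, `"DD"`) parallel to
#'   `scores`.
#' @param target Target FDR in (0, 1).
#' @return List with `threshold_score`, `estimated_fdr`, `counts` (TT/TD/DD
#'   at or above threshold), `accepted` (logical vector: item passes and is
#'   TT) and `above` (logical: item passes regardless of class).
#' @export
estimate_fdr <- function(scores, decoy_class, target = 0.01) {
  stopifnot(length(scores) == length(decoy_class), target > 0, target < 1)
  n <- length(scores)
  if (n == 0L) {
    return(list(threshold_score = Inf, estimated_fdr = 0,
                counts = c(TT = 0L, TD = 0L, DD = 0L),
                accepted = logical(0), above = logical(0)))
  }
  o <- order(-scores)
  tt <- cumsum(decoy_class[o] == "TT")
  td <- cumsum(decoy_class[o] == "TD")
  dd <- cumsum(decoy_class[o] == "DD")
  fdr_at <- ifelse(tt == 0L, ifelse(td + dd == 0L, 0, 1),
                   pmax(0, td - dd) / pmax(tt, 1L))
  # achievable cuts end at tie-run boundaries only
  boundary <- c(scores[o][-n] != scores[o][-1L], TRUE)
  ok <- which(fdr_at <= target & boundary)
  if (length(ok) == 0L) {
    return(list(threshold_score = Inf, estimated_fdr = NA_real_,
                counts = c(TT = 0L, TD = 0L, DD = 0L),
                accepted = rep(FALSE, n), above = rep(FALSE, n)))
  }
  i_best <- max(ok)
  thr <- scores[o][i_best]
  above <- scores >= thr
  accepted <- above & decoy_class == "TT"
  list(threshold_score = thr,
       estimated_fdr = fdr_at[i_best],
       counts = c(TT = sum(above & decoy_class == "TT"),
                  TD = sum(above & decoy_class == "TD"),
                  DD = sum(above & decoy_class == "DD")),
       accepted = accepted, above = above)
}

#' Two-step validation: CSM-level then cross-link-level FDR
#'
#' CSMs are validated at `target_csm`; surviving CSMs (targets and decoys)
#' are grouped into cross-links, which are validated again at `target_xl`.
#' Decoy cross-links are removed from the final report.
#'
#' @param csms CSM data frame from [assemble_csms()].
#' @param target_csm,target_xl FDR targets (defaults 0.01 each).
#' @return List with `csm_fdr`, `crosslink_fdr` (both [estimate_fdr()]
#'   results), `csms` (CSMs above the CSM threshold), `crosslinks` (all
#'   grouped from surviving CSMs) and `accepted_crosslinks` (final TT
#'   report).
#' @export
two_step_validate <- function(csms, target_csm = 0.01, target_xl = 0.01) {
  f1 <- estimate_fdr(csms$score, csms$decoy_class, target_csm)
  surv <- csms[f1$above, , drop = FALSE]
  xls <- group_crosslinks(surv)
  f2 <- estimate_fdr(xls$score, xls$decoy_class, target_xl)
  list(csm_fdr = f1, crosslink_fdr = f2,
       csms = surv, crosslinks = xls,
       accepted_crosslinks = xls[f2$accepted, , drop = FALSE])
}

#' Groupwise experimentally-validated FDR
#'
#' For synthetic libraries whose peptides are cross-linked groupwise, any
#' identified cross-link joining peptides of different groups, or involving
#' a peptide not in the library, is a known false positive. The validated
#' FDR is the fraction of such false positives among all identified
#' cross-links.
#'
#' @param crosslinks Accepted cross-link data frame (needs `peptide_a`,
#'   `peptide_b`).
#' @param groups Named vector or list mapping peptide sequence to group id;
#'   peptides absent from it are non-library.
#' @return The validated FDR fraction; 0 with a warning for an empty input.
#' @export
validated_group_fdr <- function(crosslinks, groups) {
  if (nrow(crosslinks) == 0L) {
    warning("no cross-links: groupwise validated FDR undefined, returning 0")
    return(0)
  }
  lookup <- function(pep) {
    ifelse(pep %in% names(groups), unlist(groups)[match(pep, names(groups))], NA)
  }
  ga <- lookup(crosslinks$peptide_a)
  gb <- lookup(crosslinks$peptide_b)
  false_pos <- is.na(ga) | is.na(gb) | ga != gb
  sum(false_pos) / nrow(crosslinks)
}

#' Entrapment filtering
#'
#' Iteratively removes the lowest-scoring cross-link while the fraction of
#' cross-links containing an entrapment peptide (e.g. spiked E. coli
#' proteins absent from the sample) is at or above `max_fraction`.
#'
#' @param crosslinks Cross-link data frame with `score` and
#'   `contains_entrapment`.
#' @param max_fraction Entrapment fraction to push below (default 0.01).
#' @return The surviving cross-link data frame.
#' @export
entrapment_filter <- function(crosslinks, max_fraction = 0.01) {
  out <- crosslinks
  while (nrow(out) > 0L &&
         mean(out$contains_entrapment) >= max_fraction) {
    out <- out[-which.min(out$score), , drop = FALSE]
  }
  out
}
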