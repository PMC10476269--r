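# Doublet detection in MS2 spectra, deisotoping, charge inference, MS3 ->
# doublet mapping and cross-linker-free precursor mass correction.

#' Infer a peak's charge state from its isotope envelope
#'
#' Looks for at least one further envelope member spaced by 1.00336/z above
#' the peak (so the envelope has >= 2 consecutive peaks) with plausibly
#' decaying intensities. If several charge states are consistent the largest
#' is returned; if none, `NA`.
#'
#' @param spec A [spectrum()].
#' @param peak_index 1-based index into the spectrum's peak list.
#' @param max_charge Largest charge considered (default 4).
#' @param tol_ppm Matching tolerance in ppm.
#' @return Integer charge, or `NA_integer_` when no envelope is found.
#' @export
infer_charge <- function(spec, peak_index, max_charge = 4L, tol_ppm = 20) {
  stopifnot(peak_index >= 1L, peak_index <= length(spec$mz), max_charge >= 1L)
  mz0 <- spec$mz[peak_index]
  int0 <- spec$intensity[peak_index]
  consistent <- integer(0)
  for (z in seq_len(max_charge)) {
    step <- NEUTRON_SPACING / z
    # walk up the envelope from the selected peak
    n_members <- 1L
    cur_mz <- mz0
    cur_int <- int0
    repeat {
      target <- cur_mz + step
      j <- which(abs(spec$mz - target) <= ppm_tol_da(target, tol_ppm))
      if (length(j) == 0L) break
      j <- j[which.min(abs(spec$mz[j] - target))]
      # plausibly decaying: allow some rise (isotope maxima can sit above
      # the selected peak for heavy peptides) but cap runaway growth
      if (spec$intensity[j] > 5 * cur_int) break
      n_members <- n_members + 1L
      cur_mz <- spec$mz[j]
      cur_int <- spec$intensity[j]
      if (n_members >= 6L) break
    }
    if (n_members >= 2L) consistent <- c(consistent, z)
  }
  if (length(consistent) == 0L) return(NA_integer_)
  max(consistent)
}

#' Charge states to consider for a peak
#'
#' The inferred envelope charge when available; otherwise all charge states
#' up to `max_charge` (default 4) are enumerated.
#'
#' @inheritParams infer_charge
#' @return Integer vector of candidate charges.
#' @export
candidate_charges <- function(spec, peak_index, max_charge = 4L, tol_ppm = 20) {
  z <- infer_charge(spec, peak_index, max_charge, tol_ppm)
  if (is.na(z)) seq_len(max_charge) else z
}

#' Deisotope a doublet peak to its monoisotopic neutral mass
#'
#' Walks the isotope envelope downward in steps of 1.00336/z from the
#' selected peak to the lowest consistent envelope member and returns the
#' neutral mass `z * (mono_mz - proton)`. A peak without an envelope below
#' it is assumed monoisotopic.
#'
#' @param spec A [spectrum()].
#' @param peak_index 1-based peak index.
#' @param charge Known charge state.
#' @param tol_ppm Envelope matching tolerance in ppm.
#' @return List with `mono_mz`, `mono_index` and `neutral_mass` (Da).
#' @export
deisotope_peak <- function(spec, peak_index, charge, tol_ppm = 20) {
  stopifnot(!is.na(charge), charge >= 1L)
  step <- NEUTRON_SPACING / charge
  idx <- peak_index
  repeat {
    target <- spec$mz[idx] - step
    j <- which(abs(spec$mz - target) <= ppm_tol_da(target, tol_ppm))
    if (length(j) == 0L) break
    idx <- j[which.min(abs(spec$mz[j] - target))]
  }
  mono_mz <- spec$mz[idx]
  list(mono_mz = mono_mz, mono_index = idx,
       neutral_mass = neutral_from_mz(mono_mz, charge))
}

#' Cross-linker-free peptide mass from a doublet peak mass
#'
#' The corrected precursor mass of an MS3 scan: the deisotoped neutral mass
#' of the doublet peak minus the cross-linker arm remnant and minus any
#' alternative-cleavage product delta the cross-linker fragment underwent.
#'
#' @param mono_neutral_mass Deisotoped neutral mass of the doublet peak (Da).
#' @param arm `"light"` or `"heavy"`.
#' @param spec A [crosslinker_spec()].
#' @param product_delta Signed mass of an alternative cleavage product
#'   applied to this arm (0 for none).
#' @return Peptide neutral mass in Da.
#' @export
peptide_mass_from_doublet <- function(mono_neutral_mass, arm, spec,
                                      product_delta = 0) {
  m <- mono_neutral_mass - arm_mass(spec, arm) - product_delta
  if (m <= 0) {
    stop("doublet mass ", format(mono_neutral_mass),
         " is smaller than the subtracted cross-linker arm mass")
  }
  m
}

#' Detect cross-linker doublets in an MS2 spectrum
#'
#' Searches all peak pairs for the cross-linker-specific mass difference
#' (doublet delta, optionally shifted by alternative cleavage products) at
#' each charge state. Each accepted pair is deisotoped and reported as two
#' annotations (light and heavy arm) sharing a `pair_id`. The alpha role is
#' assigned to the doublet of lowest m/z within the scan, beta to the rest.
#'
#' @param ms2 An MS2 [spectrum()].
#' @param spec A [crosslinker_spec()].
#' @param frag_tol_ppm Pair/envelope matching tolerance in ppm.
#' @param max_charge Largest doublet charge considered.
#' @param intensity_ratio_band Acceptance band for the light/heavy intensity
#'   ratio (documented stand-in for the detector's peak-quality heuristics).
#' @param prec_tol_ppm Precursor tolerance for the MS1 consistency check.
#' @param min_peptide_mass Smallest plausible partner peptide mass used in
#'   the precursor-sum consistency check (Da).
#' @return Data frame of doublet annotations: `ms2_scan_id`, `pair_id`,
#'   `role`, `arm`, `peak_index`, `partner_index`, `charge`, `mz`,
#'   `mono_mz`, `mono_neutral_mass`, `peptide_mass`, `product_label`,
#'   `product_delta`.
#' @export
detect_doublets <- function(ms2, spec, frag_tol_ppm = 20, max_charge = 4L,
                            intensity_ratio_band = c(0.1, 10),
                            prec_tol_ppm = 10, min_peptide_mass = 200) {
  stopifnot(ms2$ms_level == 2L)
  empty <- data.frame(ms2_scan_id = character(), pair_id = integer(),
                      role = character(), arm = character(),
                      peak_index = integer(), partner_index = integer(),
                      charge = integer(), mz = numeric(), mono_mz = numeric(),
                      mono_neutral_mass = numeric(), peptide_mass = numeric(),
                      product_label = character(), product_arm = character(),
                      product_delta = numeric(),
                      stringsAsFactors = FALSE)
  n <- length(ms2$mz)
  if (n < 2L) return(empty)
  delta <- doublet_delta(spec)
  # product combinations searched: none, plus each single product on one arm.
  # A product of delta d on the light arm shifts the observed doublet spacing
  # by -d, on the heavy arm by +d.
  prods <- data.frame(label = NA_character_, arm = "none", delta = 0,
                      shift = 0, stringsAsFactors = FALSE)
  if (nrow(spec$products)) {
    for (r in seq_len(nrow(spec$products))) {
      p <- spec$products[r, ]
      if (p$applies_to %in% c("short", "both")) {
        prods <- rbind(prods, data.frame(label = p$label, arm = "light",
                                         delta = p$delta_mass,
                                         shift = -p$delta_mass))
      }
      if (p$applies_to %in% c("long", "both")) {
        prods <- rbind(prods, data.frame(label = p$label, arm = "heavy",
                                         delta = p$delta_mass,
                                         shift = p$delta_mass))
      }
    }
  }

  # known MS1 precursor neutral mass, if charge is declared
  prec_neutral <- NA_real_
  if (!is.null(ms2$precursor) && !is.na(ms2$precursor$selected_charge)) {
    prec_neutral <- neutral_from_mz(ms2$precursor$selected_mz,
                                    ms2$precursor$selected_charge)
  }

  rows <- list()
  for (z in seq_len(max_charge)) {
    for (pi in seq_len(nrow(prods))) {
      gap <- (delta + prods$shift[pi]) / z
      if (gap <= 0) next
      for (i in seq_len(n - 1L)) {
        target <- ms2$mz[i] + gap
        js <- which(abs(ms2$mz - target) <= ppm_tol_da(target, frag_tol_ppm))
        for (j in js) {
          if (j <= i) next
          ratio <- ms2$intensity[i] / max(ms2$intensity[j], .Machine$double.eps)
          if (ratio < intensity_ratio_band[1] || ratio > intensity_ratio_band[2]) next
          # charge plausibility: if an envelope pins the charge of either
          # peak, it must agree with z
          zi <- infer_charge(ms2, i, max_charge, frag_tol_ppm)
          zj <- infer_charge(ms2, j, max_charge, frag_tol_ppm)
          if (!is.na(zi) && zi != z) next
          if (!is.na(zj) && zj != z) next
          di <- deisotope_peak(ms2, i, z, frag_tol_ppm)
          dj <- deisotope_peak(ms2, j, z, frag_tol_ppm)
          p_arm <- prods$arm[pi]
          p_delta <- prods$delta[pi]
          # recover the peptide mass from both arms; both must agree
          pm_light <- di$neutral_mass - spec$short_arm$mono_mass -
            (if (p_arm == "light") p_delta else 0)
          pm_heavy <- dj$neutral_mass - spec$long_arm$mono_mass -
            (if (p_arm == "heavy") p_delta else 0)
          if (pm_light <= 0 || pm_heavy <= 0) next
          tol2 <- 2 * ppm_tol_da(dj$neutral_mass, frag_tol_ppm)
          if (abs(pm_light - pm_heavy) > tol2) next
          pep_mass <- (pm_light + pm_heavy) / 2
          # MS1 precursor-sum consistency (only when precursor charge known):
          # the partner peptide implied by this doublet must have a plausible
          # mass, precursor = pepA + pepB + intact cross-linker
          if (!is.na(prec_neutral)) {
            partner <- prec_neutral - spec$intact_mass - pep_mass
            if (partner < min_peptide_mass -
                ppm_tol_da(prec_neutral, prec_tol_ppm)) next
          }
          rows[[length(rows) + 1L]] <- data.frame(
            ms2_scan_id = ms2$scan_id, pair_id = NA_integer_,
            role = NA_character_,
            arm = c("light", "heavy"),
            peak_index = c(i, j), partner_index = c(j, i),
            charge = z, mz = c(ms2$mz[i], ms2$mz[j]),
            mono_mz = c(di$mono_mz, dj$mono_mz),
            mono_neutral_mass = c(di$neutral_mass, dj$neutral_mass),
            peptide_mass = pep_mass,
            product_label = prods$label[pi], product_arm = p_arm,
            product_delta = p_delta,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  # deduplicate envelope-shifted rediscoveries of the same doublet: identical
  # (mono light, mono heavy, charge, product) after deisotoping
  odd <- seq(1, nrow(out), 2)
  key <- paste(round(out$mono_mz[odd], 4), round(out$mono_mz[odd + 1], 4),
               out$charge[odd], out$product_arm[odd], out$product_delta[odd])
  keep_pairs <- !duplicated(key)
  keep <- rep(keep_pairs, each = 2L)
  out <- out[keep, , drop = FALSE]
  n_pairs <- nrow(out) / 2L
  out$pair_id <- rep(seq_len(n_pairs), each = 2L)
  # alpha = doublet of lowest m/z (by its light peak), beta = the others
  light_mz <- out$mz[out$arm == "light"]
  ord <- order(light_mz)
  role_by_pair <- rep("beta", n_pairs)
  role_by_pair[ord[1]] <- "alpha"
  # renumber pairs in ascending m/z order so alpha is pair 1
  new_id <- match(seq_len(n_pairs), ord)
  out$role <- role_by_pair[out$pair_id]
  out$pair_id <- new_id[out$pair_id]
  out <- out[order(out$pair_id, out$arm == "heavy"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map MS3 scans to MS2 doublet peaks
#'
#' An MS3 scan is assigned to a doublet peak iff (a) it was recorded within
#' `rt_window` minutes after its MS2 scan (one-sided window), (b) it shares
#' the MS2's MS1-level precursor m/z within `prec_tol_ppm`, and (c) its own
#' selected precursor m/z matches the doublet peak or one of the peak's
#' isotope envelope members within `prec_tol_ppm`. MS3 scans matching no
#' doublet peak (e.g. co-isolated non-cross-linked peaks) are excluded from
#' the cross-link search; their count is in `attr(x, "n_unassigned")`.
#'
#' When an MS3 precursor matches two doublet peaks within tolerance it is
#' assigned to the closer one; on an exact tie, to the lower-m/z doublet.
#'
#' @param ms2 The MS2 [spectrum()] the doublets were detected in.
#' @param doublets Annotation data frame from [detect_doublets()].
#' @param ms3_scans List of MS3 [spectrum()] objects from the same run.
#' @param spec A [crosslinker_spec()].
#' @param prec_tol_ppm Precursor matching tolerance (ppm).
#' @param rt_window Retention-time window in minutes (default 5).
#' @param max_isotope Number of envelope members above the mono peak that an
#'   MS3 precursor may have been selected on.
#' @return Data frame of assignments: `ms3_scan_id`, `ms2_scan_id`,
#'   `pair_id`, `role`, `arm`, `charge`, `adjusted_precursor_mass`,
#'   `product_delta`.
#' @export
map_ms3_to_doublets <- function(ms2, doublets, ms3_scans, spec,
                                prec_tol_ppm = 10, rt_window = 5,
                                max_isotope = 3L) {
  empty <- data.frame(ms3_scan_id = character(), ms2_scan_id = character(),
                      pair_id = integer(), role = character(),
                      arm = character(), charge = integer(),
                      adjusted_precursor_mass = numeric(),
                      product_delta = numeric(), stringsAsFactors = FALSE)
  n_unassigned <- 0L
  if (nrow(doublets) == 0L || length(ms3_scans) == 0L) {
    return(structure(empty, n_unassigned = length(ms3_scans)))
  }
  rows <- list()
  for (s3 in ms3_scans) {
    stopifnot(s3$ms_level == 3L)
    ok_rt <- {
      d <- s3$retention_time - ms2$retention_time
      d >= 0 && d <= rt_window
    }
    ok_ms1 <- !is.na(s3$ms1_precursor_mz) && !is.na(ms2$ms1_precursor_mz) &&
      abs(s3$ms1_precursor_mz - ms2$ms1_precursor_mz) <=
        ppm_tol_da(ms2$ms1_precursor_mz, prec_tol_ppm)
    if (!ok_rt || !ok_ms1 || is.null(s3$precursor)) {
      n_unassigned <- n_unassigned + 1L
      next
    }
    sel <- s3$precursor$selected_mz
    # match against each doublet peak's envelope members
    best <- NULL
    for (k in seq_len(nrow(doublets))) {
      z <- doublets$charge[k]
      env <- doublets$mono_mz[k] + (0:max_isotope) * NEUTRON_SPACING / z
      d <- min(abs(env - sel))
      if (d <= ppm_tol_da(sel, prec_tol_ppm)) {
        cand <- list(k = k, dist = d)
        if (is.null(best) || cand$dist < best$dist ||
            (cand$dist == best$dist &&
             doublets$mz[cand$k] < doublets$mz[best$k])) {
          best <- cand
        }
      }
    }
    if (is.null(best)) {
      n_unassigned <- n_unassigned + 1L
      next
    }
    k <- best$k
    arm <- doublets$arm[k]
    applied <- if (identical(doublets$product_arm[k], arm))
      doublets$product_delta[k] else 0
    rows[[length(rows) + 1L]] <- data.frame(
      ms3_scan_id = s3$scan_id, ms2_scan_id = ms2$scan_id,
      pair_id = doublets$pair_id[k], role = doublets$role[k],
      arm = arm, charge = doublets$charge[k],
      adjusted_precursor_mass = peptide_mass_from_doublet(
        doublets$mono_neutral_mass[k], arm, spec, applied),
      product_delta = doublets$product_delta[k], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  structure(out, n_unassigned = n_unassigned)
}
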