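# mzML reading/writing and the MS1 -> MS2 -> MS3 scan hierarchy.
#
# A Spectrum is a light-weight list: scan_id (native id string), ms_level,
# retention_time (minutes), mz/intensity vectors (ascending, deduplicated),
# precursor (parent_scan_id, selected_mz, selected_charge, isolation_width)
# and ms1_precursor_mz, the MS1-level selection m/z the scan chain descends
# from (an MS2's own selected m/z; for an MS3, its MS2 parent's).

#' Construct a single MSn spectrum
#'
#' @param scan_id Unique scan identifier within the run.
#' @param ms_level 1, 2 or 3.
#' @param retention_time Retention time in minutes.
#' @param mz,intensity Numeric peak vectors; peaks are sorted by m/z and
#'   exact duplicate m/z values merged by intensity sum.
#' @param precursor For MSn (n >= 2): list with `parent_scan_id`,
#'   `selected_mz`, `selected_charge` (`NA` if unknown), `isolation_width`.
#' @param ms1_precursor_mz Selected m/z at the MS1 level of this scan chain.
#' @return An object of class `xl_spectrum`.
#' @export
spectrum <- function(scan_id, ms_level, retention_time, mz, intensity,
                     precursor = NULL, ms1_precursor_mz = NA_real_) {
  stopifnot(ms_level %in% 1:3, length(mz) == length(intensity))
  if (any(mz <= 0)) stop("peak m/z must be > 0")
  if (any(intensity < 0)) stop("peak intensity must be >= 0")
  if (ms_level >= 2 && is.null(precursor)) {
    stop("MS", ms_level, " spectrum requires a precursor reference")
  }
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
      mz <- unique(mz)
    }
  }
  structure(list(scan_id = as.character(scan_id),
                 ms_level = as.integer(ms_level),
                 retention_time = as.numeric(retention_time),
                 mz = as.numeric(mz), intensity = as.numeric(intensity),
                 precursor = precursor,
                 ms1_precursor_mz = as.numeric(ms1_precursor_mz)),
            class = "xl_spectrum")
}

#' @export
print.xl_spectrum <- function(x, ...) {
  cat(sprintf("<xl_spectrum> %s MS%d rt=%.3f min, %d peaks",
              x$scan_id, x$ms_level, x$retention_time, length(x$mz)))
  if (!is.null(x$precursor)) {
    cat(sprintf(", precursor %.4f (z=%s, parent %s)",
                x$precursor$selected_mz,
                ifelse(is.na(x$precursor$selected_charge), "?",
                       x$precursor$selected_charge),
                x$precursor$parent_scan_id))
  }
  cat("\n")
  invisible(x)
}

precursor_ref <- function(parent_scan_id, selected_mz, selected_charge = NA_integer_,
                          isolation_width = NA_real_) {
  if (!is.na(selected_charge) &&
      (selected_charge < 1L || selected_charge > 15L)) {
    stop("precursor charge out of range 1..15: ", selected_charge)
  }
  list(parent_scan_id = as.character(parent_scan_id),
       selected_mz = as.numeric(selected_mz),
       selected_charge = as.integer(selected_charge),
       isolation_width = as.numeric(isolation_width))
}

#' Read an mzML file into a spectrum collection
#'
#' Reads all MS1/MS2/MS3 scans with their precursor linkage and resolves each
#' MSn scan's MS1-level precursor m/z by walking the parent chain. Retention
#' times are normalized to minutes. MSn scans whose precursor reference is
#' missing or unresolvable are skipped with a warning; the skip count is
#' available as `attr(x, "n_skipped")`.
#'
#' MGF input is rejected: the search requires MSn stage and MS2-/MS3-level
#' precursor linkage, which MGF does not carry.
#'
#' @param path Path to an mzML 1.1 file (indexed or plain).
#' @return List of [spectrum()] objects, class `xl_spectra`.
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (tolower(tools::file_ext(path)) == "mgf") {
    stop("MGF files are not supported: the MS2-MS3 search requires MSn ",
         "stage and precursor linkage; supply mzML instead")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) {
    return(structure(list(), class = "xl_spectra", n_skipped = 0L))
  }
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)

  ids <- hdr$spectrumId
  if (is.null(ids) || any(is.na(ids)) || anyDuplicated(ids)) {
    ids <- as.character(seq_len(nrow(hdr)))
  }
  # retention time: mzR reports seconds
  rt_min <- hdr$retentionTime / 60

  acq2idx <- match(hdr$precursorScanNum, hdr$acquisitionNum)

  skipped <- 0L
  out <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    lvl <- hdr$msLevel[i]
    prec <- NULL
    ms1_mz <- NA_real_
    if (lvl >= 2L) {
      pmz <- hdr$precursorMZ[i]
      pidx <- acq2idx[i]
      if (is.na(pmz) || pmz <= 0 || is.na(pidx)) {
        skipped <- skipped + 1L
        next
      }
      z <- hdr$precursorCharge[i]
      if (!is.na(z) && (z < 1L || z > 15L)) z <- NA_integer_
      iso <- if ("isolationWindowLowerOffset" %in% names(hdr)) {
        hdr$isolationWindowLowerOffset[i] + hdr$isolationWindowUpperOffset[i]
      } else NA_real_
      prec <- precursor_ref(ids[pidx], pmz, z, iso)
      # walk to MS1: an MS2's own selection is the MS1 selection; an MS3
      # inherits its MS2 parent's precursorMZ
      ms1_mz <- pmz
      j <- i
      while (!is.na(acq2idx[j]) && hdr$msLevel[acq2idx[j]] >= 2L) {
        j <- acq2idx[j]
        ms1_mz <- hdr$precursorMZ[j]
      }
    }
    mat <- pk[[i]]
    out[[i]] <- spectrum(ids[i], lvl, rt_min[i],
                         mz = mat[, 1], intensity = mat[, 2],
                         precursor = prec, ms1_precursor_mz = ms1_mz)
  }
  kept <- out[!vapply(out, is.null, logical(1))]
  if (skipped > 0L) {
    warning(skipped, " MSn scan(s) without a resolvable precursor reference ",
            "were skipped")
  }
  structure(kept, class = "xl_spectra", n_skipped = skipped)
}

#' Write a spectrum collection to mzML
#'
#' Inverse of [read_mzml()] for collections produced in-memory (e.g. by
#' [simulate_run()]). Scan ids are stored as 1-based acquisition numbers;
#' precursor links are preserved.
#'
#' @param spectra List of [spectrum()] objects (an `xl_spectra` collection).
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  n <- length(spectra)
  if (n == 0L) stop("cannot write an empty spectrum collection")
  ids <- vapply(spectra, function(s) s$scan_id, character(1))
  acq <- seq_len(n)
  parent_acq <- vapply(spectra, function(s) {
    if (is.null(s$precursor)) return(0L)
    j <- match(s$precursor$parent_scan_id, ids)
    if (is.na(j)) 0L else j
  }, integer(1))
  num_or <- function(f, default) vapply(spectra, function(s) {
    v <- f(s); if (length(v) == 0L || is.na(v)) default else v
  }, numeric(1))
  hdr <- data.frame(
    seqNum = acq, acquisitionNum = acq,
    msLevel = vapply(spectra, function(s) s$ms_level, integer(1)),
    polarity = 1L,
    peaksCount = vapply(spectra, function(s) length(s$mz), integer(1)),
    totIonCurrent = num_or(function(s) sum(s$intensity), 0),
    retentionTime = vapply(spectra, function(s) s$retention_time * 60, numeric(1)),
    basePeakMZ = num_or(function(s) if (length(s$mz)) s$mz[which.max(s$intensity)] else NA_real_, 0),
    basePeakIntensity = num_or(function(s) if (length(s$mz)) max(s$intensity) else NA_real_, 0),
    collisionEnergy = vapply(spectra, function(s) c(0, 25, 35)[s$ms_level], numeric(1)),
    ionisationEnergy = 0,
    lowMZ = num_or(function(s) if (length(s$mz)) min(s$mz) else NA_real_, 0),
    highMZ = num_or(function(s) if (length(s$mz)) max(s$mz) else NA_real_, 0),
    precursorScanNum = parent_acq,
    precursorMZ = vapply(spectra, function(s)
      if (is.null(s$precursor)) 0 else s$precursor$selected_mz, numeric(1)),
    precursorCharge = vapply(spectra, function(s)
      if (is.null(s$precursor) || is.na(s$precursor$selected_charge)) 0L
      else s$precursor$selected_charge, integer(1)),
    precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 10,
    filterString = NA_character_,
    spectrumId = paste0("scan=", acq),
    centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = vapply(spectra, function(s)
      if (is.null(s$precursor)) NA_real_ else s$precursor$selected_mz, numeric(1)),
    isolationWindowLowerOffset = vapply(spectra, function(s)
      if (is.null(s$precursor) || is.na(s$precursor$isolation_width)) NA_real_
      else s$precursor$isolation_width / 2, numeric(1)),
    isolationWindowUpperOffset = vapply(spectra, function(s)
      if (is.null(s$precursor) || is.na(s$precursor$isolation_width)) NA_real_
      else s$precursor$isolation_width / 2, numeric(1)),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  pk <- lapply(spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read a protein database from FASTA
#'
#' @param path FASTA file. Accessions are the first whitespace-delimited
#'   header token; sequences are uppercased on read.
#' @param entrapment_predicate Function of the accession (and full header)
#'   returning `TRUE` for entrapment entries (e.g. spiked E. coli proteins),
#'   or `NULL` for none.
#' @return Data frame with columns `accession`, `sequence`, `is_decoy`,
#'   `is_entrapment`.
#' @export
read_fasta <- function(path, entrapment_predicate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  headers <- names(seqs)
  accession <- vapply(strsplit(headers, "[[:space:]]+"), `[`, character(1), 1L)
  sequence <- toupper(as.character(seqs))
  bad <- grepl("[^A-Z]", sequence)
  if (any(bad)) {
    stop("FASTA record '", accession[which(bad)[1]],
         "' contains characters outside A-Z")
  }
  is_entrap <- if (is.null(entrapment_predicate)) {
    rep(FALSE, length(accession))
  } else {
    vapply(seq_along(accession), function(i)
      isTRUE(entrapment_predicate(accession[i], headers[i])), logical(1))
  }
  data.frame(accession = accession, sequence = sequence,
             is_decoy = FALSE, is_entrapment = is_entrap,
             stringsAsFactors = FALSE)
}

#' Generate reversed-sequence decoy proteins
#'
#' One decoy per target, with the full protein sequence reversed and the
#' accession prefixed with `"REV_"`. Reversal is an involution: reversing a
#' decoy recovers its target.
#'
#' @param entries Target protein data frame from [read_fasta()].
#' @return Decoy data frame of the same shape with `is_decoy = TRUE`.
#' @export
generate_decoys <- function(entries) {
  stopifnot(is.data.frame(entries), !any(entries$is_decoy))
  rev_seq <- vapply(strsplit(entries$sequence, "", fixed = TRUE),
                    function(x) paste(rev(x), collapse = ""), character(1))
  data.frame(accession = paste0("REV_", entries$accession),
             sequence = rev_seq,
             is_decoy = TRUE,
             is_entrapment = entries$is_entrapment,
             stringsAsFactors = FALSE)
}

#' Write protein entries to FASTA
#' @param entries Protein data frame (`accession`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(entries, path) {
  x <- Biostrings::AAStringSet(entries$sequence)
  names(x) <- entries$accession
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# subset helper preserving class
ms_level_of <- function(spectra) vapply(spectra, function(s) s$ms_level, integer(1))
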