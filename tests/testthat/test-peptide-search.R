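DSSO <- crosslinker("DSSO")

test_that("tryptic digestion follows the cleave-after-K/R-not-before-P rule", {
  d0 <- digest("AKRPLKWE", missed_cleavages_max = 0L,
               length_range = c(1L, 30L), mass_range = c(0, 1e5))
  expect_setequal(d0$sequence, c("AK", "RPLK", "WE"))
  d1 <- digest("AKRPLKWE", missed_cleavages_max = 1L,
               length_range = c(1L, 30L), mass_range = c(0, 1e5))
  expect_setequal(d1$sequence, c("AK", "RPLK", "WE", "AKRPLK", "RPLKWE"))
  # positions and terminal flags
  expect_identical(d0$start[d0$sequence == "RPLK"], 3L)
  expect_true(d0$is_prot_nterm[d0$sequence == "AK"])
  expect_true(d0$is_prot_cterm[d0$sequence == "WE"])
})

test_that("proteins below the minimum peptide length digest to nothing", {
  expect_identical(nrow(digest("AKR", length_range = c(5L, 30L))), 0L)
})

test_that("digestion matches a character-walk reference on random proteins", {
  # independent oracle: walk the sequence, collect segment boundaries, then
  # join adjacent segments up to the missed-cleavage budget
  oracle <- function(seq, mc_max) {
    aa <- strsplit(seq, "")[[1]]
    n <- length(aa)
    ends <- integer(0)
    for (i in seq_len(n)) {
      if (aa[i] %in% c("K", "R") && (i == n || aa[i + 1] != "P")) {
        ends <- c(ends, i)
      }
    }
    if (length(ends) == 0L || ends[length(ends)] != n) ends <- c(ends, n)
    starts <- c(1L, head(ends, -1) + 1L)
    peps <- character(0)
    for (i in seq_along(starts)) {
      for (mc in 0:mc_max) {
        if (i + mc > length(ends)) break
        peps <- c(peps, substr(seq, starts[i], ends[i + mc]))
      }
    }
    peps
  }
  set.seed(99)
  for (rep in 1:100) {
    seq <- paste(sample(c("A", "G", "K", "R", "P", "L", "S", "T"), 40,
                        replace = TRUE), collapse = "")
    mine <- digest(seq, missed_cleavages_max = 2L, length_range = c(1L, 40L),
                   mass_range = c(0, 1e6))
    expect_identical(sort(mine$sequence), sort(oracle(seq, 2L)),
                     info = seq)
  }
})

test_that("cross-link sites exclude the C-terminal lysine of tryptic peptides", {
  # internal K admissible
  expect_identical(xlms:::admissible_sites("AKCDEFGR", DSSO), 2L)
  # C-terminal K only when protein C-terminal
  expect_identical(xlms:::admissible_sites("PEPTIDEK", DSSO), integer(0))
  expect_identical(xlms:::admissible_sites("PEPTIDEK", DSSO,
                                           is_prot_cterm = TRUE), 8L)
  # protein N-terminus reactivity adds position 1
  expect_identical(xlms:::admissible_sites("ACDEFGR", DSSO,
                                           is_prot_nterm = TRUE), 1L)
  expect_identical(xlms:::admissible_sites("ACDEFGR", DSSO), integer(0))
})

test_that("candidate generation matches a brute-force mass filter", {
  set.seed(12)
  prot <- data.frame(
    accession = paste0("P", 1:6),
    sequence = vapply(1:6, function(i)
      paste(sample(c("A", "G", "K", "L", "S", "V", "E", "D"), 35,
                   replace = TRUE), collapse = ""), character(1)),
    is_decoy = FALSE, is_entrapment = FALSE, stringsAsFactors = FALSE)
  idx <- digest_database(prot, length_range = c(4L, 30L),
                         mass_range = c(200, 6000))
  target <- idx$neutral_mass[7]
  cands <- generate_candidates(idx, target, 5, DSSO, "light")
  # brute force: exhaustive mass comparison then site enumeration
  brute <- idx[abs(idx$neutral_mass - target) <= target * 5e-6, , drop = FALSE]
  brute_n <- sum(vapply(seq_len(nrow(brute)), function(i)
    length(xlms:::admissible_sites(brute$sequence[i], DSSO,
                                   brute$is_prot_nterm[i],
                                   brute$is_prot_cterm[i])), integer(1)))
  expect_identical(nrow(cands), brute_n)
  expect_true(all(abs(cands$neutral_mass - target) <= target * 5e-6))
  # peptides without any reactive site are excluded
  no_k <- digest_database(data.frame(accession = "X", sequence = "GGGALLVDER",
                                     is_decoy = FALSE, is_entrapment = FALSE),
                          length_range = c(4L, 30L), mass_range = c(200, 6000))
  no_k <- no_k[!no_k$is_prot_nterm, , drop = FALSE]
  if (nrow(no_k)) {
    c2 <- generate_candidates(no_k, no_k$neutral_mass[1], 5, DSSO, "light")
    expect_identical(nrow(c2), 0L)
  }
})

test_that("theoretical fragments shift arm-containing ions only", {
  fr <- theoretical_fragments("AK", crosslink_site = 2L, spec = DSSO,
                              arm = "light", max_frag_charge = 1L,
                              fixed_mods = NULL)
  b1 <- fr$mz[fr$ion == "b1"]
  y1 <- fr$mz[fr$ion == "y1"]
  expect_equal(b1, 72.04439, tolerance = 1e-4)   # unmodified A
  expect_equal(y1, 147.11280 + 54.01057, tolerance = 1e-4)  # K + light arm
  expect_equal(y1, 201.12337, tolerance = 1e-4)
  # site at position 1 shifts all b ions instead
  fr2 <- theoretical_fragments("KA", crosslink_site = 1L, spec = DSSO,
                               arm = "light", max_frag_charge = 1L,
                               fixed_mods = NULL)
  expect_equal(fr2$mz[fr2$ion == "b1"],
               128.09496 + 1.00728 + 54.01057, tolerance = 1e-4)
  expect_equal(fr2$mz[fr2$ion == "y1"], 71.03711 + 18.01056 + 1.00728,
               tolerance = 1e-4)
  # a length-1 peptide has no b/y pairs
  expect_identical(nrow(theoretical_fragments("K")), 0L)
})

test_that("the binomial scorer behaves monotonically", {
  fr <- theoretical_fragments("PEPKTIDER", crosslink_site = 4L, spec = DSSO,
                              arm = "light", max_frag_charge = 1L)
  mk_spec <- function(mz) spectrum("s", 3L, 1, mz, rep(100, length(mz)),
                                   precursor = precursor_ref("p", 500, NA),
                                   ms1_precursor_mz = 500)
  # no matching peaks: score 0
  s0 <- score_match(mk_spec(c(150.7, 222.9)), fr)
  expect_identical(s0$raw_score, 0)
  # the exact theoretical list scores maximally for this n, monotone in n
  full <- score_match(mk_spec(fr$mz), fr)
  expect_identical(full$matched_ions, nrow(fr))
  partial <- score_match(mk_spec(fr$mz[1:5]), fr)
  expect_gt(full$raw_score, 0)
  # adding one more matched peak (same n) never decreases the score
  more <- score_match(mk_spec(fr$mz[1:6]), fr)
  expect_gte(more$raw_score, partial$raw_score)
  # widening the tolerance with the same matches never increases the score
  tight <- score_match(mk_spec(fr$mz[1:5]), fr, frag_tol = 10)
  wide <- score_match(mk_spec(fr$mz[1:5]), fr, frag_tol = 20)
  expect_lte(wide$raw_score, tight$raw_score)
  # unmatched theoretical ions dilute the score
  fr_extra <- rbind(fr, data.frame(ion = "x1", mz = 1500.5, charge = 1L))
  diluted <- score_match(mk_spec(fr$mz[1:5]), fr_extra)
  expect_lte(diluted$raw_score, partial$raw_score)
})

test_that("score is monotone in the number of theoretical ions matched fully", {
  mk_spec <- function(mz) spectrum("s", 3L, 1, mz, rep(100, length(mz)),
                                   precursor = precursor_ref("p", 500, NA),
                                   ms1_precursor_mz = 500)
  fr_small <- theoretical_fragments("PEPK", crosslink_site = 4L, spec = DSSO,
                                    arm = "light", max_frag_charge = 1L)
  fr_large <- theoretical_fragments("PEPKTIDER", crosslink_site = 4L,
                                    spec = DSSO, arm = "light",
                                    max_frag_charge = 1L)
  s_small <- score_match(mk_spec(fr_small$mz), fr_small)
  s_large <- score_match(mk_spec(fr_large$mz), fr_large)
  expect_gt(s_large$raw_score, s_small$raw_score)
})

test_that("the linear prefilter flags linear spectra but not cross-linked ones", {
  lib <- make_library(12, c(6, 6), seed = 3)
  prot <- library_proteins(lib)
  idx <- digest_database(rbind(prot, generate_decoys(prot)),
                         length_range = c(5L, 30L), mass_range = c(400, 6000))
  sim <- simulate_run(lib, DSSO,
                      sim_params(n_crosslinks = 4L, ms3_per_doublet = 0L,
                                 noise_peaks = 5L, linear_rate = 1.5),
                      seed = 21)
  flagged <- linear_prefilter(sim$spectra, idx)
  lin_ids <- sim$truth$scan_id[sim$truth$kind == "ms2_linear"]
  xl_ids <- sim$truth$scan_id[sim$truth$kind == "ms2_crosslink"]
  expect_gt(length(lin_ids), 0L)
  expect_gt(length(intersect(flagged, lin_ids)), 0L)
  expect_identical(intersect(flagged, xl_ids), character(0))
  # empty collection: empty flag set
  expect_identical(
    linear_prefilter(structure(list(), class = "xl_spectra"), idx),
    character(0))
})
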