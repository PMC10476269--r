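DSSO <- crosslinker("DSSO")

test_that("multi-scan boosting matches its anchor cases", {
  # single scan: no boost regardless of p
  expect_equal(pool_and_boost(50, "a", p = 20)$boosted_score, 50)
  expect_equal(pool_and_boost(50, "a", p = 100)$boosted_score, 50)
  # p = 100 doubles the maximum for every additional scan
  expect_equal(pool_and_boost(c(50, 40), c("a", "b"), p = 100)$boosted_score, 100)
  # p = 0: no boosting
  expect_equal(pool_and_boost(c(50, 40), c("a", "b"), p = 0)$boosted_score, 50)
  # three scans at the default p = 20: 50 * 1.2^2
  expect_equal(pool_and_boost(c(50, 40, 30), c("a", "b", "c"),
                              p = 20)$boosted_score, 72.0)
  # n counts unique scans, not score entries
  expect_equal(pool_and_boost(c(50, 40), c("a", "a"), p = 100)$n, 1L)
  expect_error(pool_and_boost(numeric(0), character(0)), "empty")
})

test_that("boosted scores are monotone in p and n and bounded below by max", {
  set.seed(5)
  for (i in 1:20) {
    k <- sample(1:5, 1)
    sc <- runif(k, 1, 100)
    ids <- paste0("s", seq_len(k))
    b0 <- pool_and_boost(sc, ids, p = 0)$boosted_score
    b20 <- pool_and_boost(sc, ids, p = 20)$boosted_score
    b100 <- pool_and_boost(sc, ids, p = 100)$boosted_score
    expect_equal(b0, max(sc))
    expect_true(b0 <= b20 && b20 <= b100)
    if (k > 1) expect_gt(b20, max(sc)) else expect_equal(b20, max(sc))
    # one more contributing scan never lowers the boosted score
    b_more <- pool_and_boost(c(sc, 1), c(ids, "extra"), p = 20)$boosted_score
    expect_gte(b_more, b20)
  }
})

test_that("CSM assembly takes the min score and derives the decoy class", {
  pooled <- rbind(
    pooled_row(pair = 1L, pair_mz = 450, seq = "AAKGGGR", mass = 700, score = 80),
    pooled_row(pair = 2L, pair_mz = 650, seq = "CCKDDDR", mass = 1000, score = 60))
  csm <- assemble_csms(pooled)
  expect_identical(nrow(csm), 1L)
  expect_equal(csm$score, 60)
  expect_identical(csm$decoy_class, "TT")
  expect_identical(csm$alpha_sequence, "AAKGGGR")  # lower-m/z doublet
  expect_identical(csm$beta_sequence, "CCKDDDR")

  # target + decoy -> TD; decoy + decoy -> DD
  td <- rbind(
    pooled_row(pair = 1L, pair_mz = 450, seq = "AAKGGGR", score = 80),
    pooled_row(pair = 2L, pair_mz = 650, seq = "RKGGGAA", decoy = TRUE,
               score = 60))
  expect_identical(assemble_csms(td)$decoy_class, "TD")
  dd <- rbind(
    pooled_row(pair = 1L, pair_mz = 450, seq = "RGGGKAA", decoy = TRUE,
               score = 80),
    pooled_row(pair = 2L, pair_mz = 650, seq = "RDDDKCC", decoy = TRUE,
               score = 60))
  expect_identical(assemble_csms(dd)$decoy_class, "DD")

  # one-sided evidence: no CSM
  expect_identical(nrow(assemble_csms(pooled_row())), 0L)
})

test_that("CSM assembly enforces the precursor-sum check when charge is known", {
  xl <- DSSO
  m_a <- 700; m_b <- 1000
  prec_mass <- m_a + m_b + xl$intact_mass
  z <- 3L
  ms2 <- spectrum("s1", 2L, 1, c(300.5, 600.7), c(10, 10),
                  precursor = precursor_ref("p", prec_mass / z + PROTON, z),
                  ms1_precursor_mz = prec_mass / z + PROTON)
  good <- rbind(
    pooled_row(pair = 1L, pair_mz = 450, seq = "AAKGGGR", mass = m_a, score = 80),
    pooled_row(pair = 2L, pair_mz = 650, seq = "CCKDDDR", mass = m_b, score = 60))
  expect_identical(nrow(assemble_csms(good, ms2, xl)), 1L)
  bad <- good
  bad$neutral_mass[2] <- m_b + 1  # 1 Da off: fails a 10 ppm sum check
  expect_identical(nrow(assemble_csms(bad, ms2, xl)), 0L)
})

test_that("cross-link grouping keys unordered peptide pairs and takes max", {
  base <- assemble_csms(rbind(
    pooled_row(pair = 1L, pair_mz = 450, seq = "AAKGGGR", site = 3L, score = 60),
    pooled_row(pair = 2L, pair_mz = 650, seq = "CCKDDDR", site = 3L, score = 90)))
  swapped <- assemble_csms(rbind(
    pooled_row(scan = "s2", pair = 1L, pair_mz = 400, seq = "CCKDDDR",
               site = 3L, score = 75),
    pooled_row(scan = "s2", pair = 2L, pair_mz = 700, seq = "AAKGGGR",
               site = 3L, score = 95)))
  xl <- group_crosslinks(rbind(base, swapped))
  expect_identical(nrow(xl), 1L)      # same unordered pair
  expect_equal(xl$score, 75)          # max over CSM scores (60, 75)
  expect_identical(xl$n_csms, 2L)

  # 5 CSMs over 3 distinct pairs -> 3 cross-links
  mk <- function(scan, s1, s2, sc) assemble_csms(rbind(
    pooled_row(scan = scan, pair = 1L, pair_mz = 450, seq = s1, score = sc + 5),
    pooled_row(scan = scan, pair = 2L, pair_mz = 650, seq = s2, score = sc)))
  five <- rbind(mk("a", "AAKGGGR", "CCKDDDR", 50),
                mk("b", "AAKGGGR", "CCKDDDR", 55),
                mk("c", "EEKFFFR", "CCKDDDR", 60),
                mk("d", "EEKFFFR", "CCKDDDR", 40),
                mk("e", "GGKHHHR", "CCKDDDR", 45))
  expect_identical(nrow(group_crosslinks(five)), 3L)
})

test_that("FDR estimation reproduces hand-computed examples", {
  # 100 targets and 1 TD above any cut: estimated FDR 1%, all targets kept
  sc <- c(seq(200, 101), 150.5)
  cls <- c(rep("TT", 100), "TD")
  f <- estimate_fdr(sc, cls, target = 0.01)
  expect_equal(f$estimated_fdr, 0.01)
  expect_identical(sum(f$accepted), 100L)

  # all targets, no decoys: FDR 0, everything accepted
  f2 <- estimate_fdr(c(10, 20, 30), rep("TT", 3), target = 0.01)
  expect_equal(f2$estimated_fdr, 0)
  expect_identical(sum(f2$accepted), 3L)

  # a TD above part of the targets forces the threshold up
  f3 <- estimate_fdr(c(90, 80, 70, 85), c("TT", "TT", "TT", "TD"),
                     target = 0.01)
  expect_identical(sum(f3$accepted), 1L)
  expect_true(f3$accepted[1])

  # DD matches offset TD matches
  f4 <- estimate_fdr(c(90, 85, 84, 80, 70), c("TT", "TD", "DD", "TT", "TT"),
                     target = 0.01)
  expect_identical(sum(f4$accepted), 3L)

  # empty input
  f5 <- estimate_fdr(numeric(0), character(0))
  expect_identical(sum(f5$accepted), 0L)
})

test_that("FDR thresholding matches exhaustive threshold scanning", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(1:20, 1)
    sc <- round(runif(n, 0, 100), sample(0:1, 1))  # induce occasional ties
    cls <- sample(c("TT", "TD", "DD"), n, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1))
    target <- sample(c(0.01, 0.05, 0.2), 1)
    mine <- estimate_fdr(sc, cls, target)$accepted
    oracle <- brute_force_fdr(sc, cls, target)
    expect_identical(mine, oracle,
                     info = paste("case", i, paste(sc, cls, collapse = " ")))
  }
})

test_that("two-step validation filters decoys at both levels", {
  set.seed(8)
  mk_csm <- function(scan, s1, s2, sc, d1 = FALSE, d2 = FALSE) {
    assemble_csms(rbind(
      pooled_row(scan = scan, pair = 1L, pair_mz = 450, seq = s1,
                 decoy = d1, score = sc + 5),
      pooled_row(scan = scan, pair = 2L, pair_mz = 650, seq = s2,
                 decoy = d2, score = sc)))
  }
  csms <- rbind(
    do.call(rbind, lapply(1:30, function(i)
      mk_csm(paste0("t", i), paste0("AAK", i, "R"), paste0("CCK", i, "R"),
             60 + i))),
    mk_csm("d1", "RKAA1R", "CCK1R", 12, d1 = TRUE),
    mk_csm("d2", "RKAA2R", "RKCC2R", 11, d1 = TRUE, d2 = TRUE))
  v <- two_step_validate(csms, 0.01, 0.01)
  expect_lte(v$csm_fdr$estimated_fdr, 0.01)
  expect_lte(v$crosslink_fdr$estimated_fdr, 0.01)
  expect_identical(nrow(v$accepted_crosslinks), 30L)
  expect_true(all(v$accepted_crosslinks$decoy_class == "TT"))

  # empty input
  v0 <- two_step_validate(assemble_csms(NULL))
  expect_identical(nrow(v0$accepted_crosslinks), 0L)

  # all-decoy input yields nothing
  alldec <- rbind(mk_csm("x1", "RKZZ1R", "CCK1R", 50, d1 = TRUE),
                  mk_csm("x2", "RKZZ2R", "CCK2R", 40, d1 = TRUE))
  vd <- two_step_validate(alldec)
  expect_identical(nrow(vd$accepted_crosslinks), 0L)
})

test_that("score propagation invariants hold on validated output", {
  lib <- make_library(14, c(7, 7), seed = 17)
  sim <- simulate_run(lib, DSSO, sim_params(n_crosslinks = 8L), seed = 17)
  res <- run_search(sim$spectra, library_proteins(lib), run_config())
  expect_gt(nrow(res$csms), 0L)
  expect_equal(res$csms$score,
               pmin(res$csms$alpha_score, res$csms$beta_score))
  for (i in seq_len(nrow(res$crosslinks))) {
    members <- strsplit(res$crosslinks$csm_scan_ids[i], ";")[[1]]
    member_scores <- res$csms$score[res$csms$ms2_scan_id %in% members]
    expect_equal(res$crosslinks$score[i], max(member_scores))
  }
})

test_that("groupwise validated FDR counts inter-group and non-library links", {
  xl <- data.frame(peptide_a = c(rep("A", 96), rep("B", 4)),
                   peptide_b = c(rep("A2", 96), rep("C", 4)),
                   stringsAsFactors = FALSE)
  groups <- list(A = 1, A2 = 1, B = 2, C = 3)
  expect_equal(validated_group_fdr(xl, groups), 0.04)

  intra <- data.frame(peptide_a = "A", peptide_b = "A2")
  expect_equal(validated_group_fdr(intra, groups), 0)

  mixed <- data.frame(peptide_a = c(rep("A", 49), "A"),
                      peptide_b = c(rep("A2", 49), "UNKNOWN"))
  expect_equal(validated_group_fdr(mixed, groups), 0.02)

  expect_warning(v <- validated_group_fdr(xl[0, ], groups), "undefined")
  expect_identical(v, 0)
})

test_that("entrapment filtering trims from the bottom until the fraction drops", {
  set.seed(31)
  xl <- data.frame(score = seq(100, 51), contains_entrapment = FALSE)
  xl$contains_entrapment[30] <- TRUE  # 1/50 = 2% entrapment
  out <- entrapment_filter(xl, 0.01)
  expect_false(any(out$contains_entrapment))
  # everything below the entrapment hit was removed with it
  expect_identical(nrow(out), 29L)
  expect_true(all(out$score > xl$score[30]))

  clean <- data.frame(score = 1:10, contains_entrapment = FALSE)
  expect_identical(entrapment_filter(clean, 0.01), clean)

  dirty <- data.frame(score = 1:5, contains_entrapment = TRUE)
  expect_identical(nrow(entrapment_filter(dirty, 0.01)), 0L)
})
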