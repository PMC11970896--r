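make_candidate <- function(sequence = NULL, tm = NA_real_, vis = NA_integer_,
                           distinct = NULL) {
  if (is.null(sequence))
    sequence <- paste(sample(aa_alphabet(), 30, replace = TRUE), collapse = "")
  if (is.null(distinct))
    distinct <- length(unique(strsplit(sequence, "")[[1]]))
  out <- list(sequence = sequence, distinct_aa_count = distinct,
              visibility = vis, tm_score = tm, predicted_structure = NULL)
  class(out) <- "design_candidate"
  out
}

test_that("candidate generation fills lengths, diversity and visibility", {
  w <- tiny_world()
  pwm <- small_pwm()
  cands <- generate_candidates(w$base, w$structures[[1]], n = 3,
                               temperature = 1.0, predictor = pwm, seed = 4)
  expect_length(cands, 3)
  for (cand in cands) {
    expect_equal(nchar(cand$sequence), 50L)
    expect_equal(cand$distinct_aa_count,
                 length(unique(strsplit(cand$sequence, "")[[1]])))
    expect_true(is.finite(cand$visibility))
  }
  c1 <- generate_candidates(w$base, w$structures[[1]], n = 1, seed = 9)
  c2 <- generate_candidates(w$base, w$structures[[1]], n = 1, seed = 9)
  expect_identical(c1[[1]]$sequence, c2[[1]]$sequence)
})

test_that("the low-diversity filter is strict at 10 amino-acid types", {
  mono <- make_candidate(paste(rep("A", 30), collapse = ""))
  ten <- make_candidate(paste(c(aa_alphabet()[1:10],
                                rep("A", 20)), collapse = ""))
  expect_length(filter_low_diversity(list(mono)), 0)
  expect_length(filter_low_diversity(list(ten)), 1)

  # mixed batch against a set-cardinality recount
  set.seed(12)
  batch <- lapply(1:40, function(i) {
    k <- sample(1:20, 1)
    make_candidate(paste(sample(aa_alphabet()[seq_len(k)], 30,
                                replace = TRUE), collapse = ""))
  })
  kept <- filter_low_diversity(batch)
  oracle_kept <- Filter(function(cand)
    length(unique(strsplit(cand$sequence, "")[[1]])) >= 10, batch)
  expect_identical(vapply(kept, `[[`, character(1), "sequence"),
                   vapply(oracle_kept, `[[`, character(1), "sequence"))
})

test_that("design selection follows the TM-gate-then-min-visibility rule", {
  a <- make_candidate(tm = 0.95, vis = 12L)
  b <- make_candidate(tm = 0.92, vis = 7L)
  c_ <- make_candidate(tm = 0.85, vis = 2L)
  expect_identical(select_design(list(a, b, c_))$sequence, b$sequence)

  # fallback: no candidate above the 0.9 gate -> maximum TM-score
  d <- make_candidate(tm = 0.8, vis = 5L)
  e <- make_candidate(tm = 0.6, vis = 1L)
  expect_identical(select_design(list(d, e))$sequence, d$sequence)
  expect_identical(select_design(list(e))$sequence, e$sequence)
  expect_null(select_design(list()))
  # the gate is strict: a candidate at exactly 0.9 is not eligible for the
  # min-visibility branch even with visibility 0 ...
  f <- make_candidate(tm = 0.9, vis = 0L)
  expect_identical(select_design(list(f, a))$sequence, a$sequence)
  # ... though it can still win the no-gate fallback on maximum TM-score
  expect_identical(select_design(list(f, d))$sequence, f$sequence)
})

test_that("selection agrees with an exhaustive rule-application oracle", {
  oracle_select <- function(tm, vis) {
    elig <- which(tm > 0.9)
    if (length(elig)) elig[order(vis[elig])][1] else order(-tm)[1]
  }
  set.seed(99)
  for (trial in 1:200) {
    n <- sample(1:6, 1)
    tm <- round(runif(n), 2)
    vis <- sample(0:30, n, replace = TRUE)
    cands <- lapply(seq_len(n), function(i)
      make_candidate(sequence = paste0("SEQ", i), tm = tm[i], vis = vis[i],
                     distinct = 20))
    picked <- select_design(cands)
    expect_identical(picked$sequence, paste0("SEQ", oracle_select(tm, vis)))
  }
})

test_that("sequence recovery is the identical-position fraction", {
  expect_equal(sequence_recovery("AAAA", "AAAA"), 1.0)
  expect_equal(sequence_recovery("AAAA", "AAAC"), 0.75)
  expect_equal(sequence_recovery("AAAA", "AAAC"),
               sequence_recovery("AAAC", "AAAA"))
  expect_error(sequence_recovery("AAA", "AAAA"), "equal length")
})

test_that("the built-in TM-score behaves across similarity regimes", {
  bb <- generate_backbone(60, "mixed", noise_sigma = 0.2, seed = 14)
  expect_equal(tm_score(bb, bb), 1.0, tolerance = 1e-9)

  # rigid motion of the same structure still scores 1
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  co <- bb$coords
  for (i in 1:60) for (j in 1:4)
    co[i, j, ] <- as.numeric(R %*% bb$coords[i, j, ]) + c(3, 1, -8)
  expect_equal(tm_score(backbone_structure(co), bb), 1.0, tolerance = 1e-6)

  # sub-Angstrom noise stays above the 0.9 selection gate
  set.seed(15)
  near <- structure_stub_backend(noise_sigma = 0.3)("A", bb)
  expect_gt(tm_score(near, bb), 0.9)

  # a random-coordinate decoy of equal length falls in the unrelated regime
  set.seed(16)
  decoy_co <- array(rnorm(60 * 4 * 3, sd = 10), dim = c(60, 4, 3))
  expect_lt(tm_score(backbone_structure(decoy_co), bb), 0.2)

  short <- generate_backbone(10, "helix")
  expect_error(tm_score(short, bb), "equal-length")
  expect_error(tm_score(bb, bb, backend = "tmalign",
                        tmalign_path = "no_such_tmalign_exe"), "not found")
})

test_that("the stub structure backend perturbs the template and can fail", {
  bb <- generate_backbone(30, "helix", seed = 2)
  set.seed(3)
  pred <- structure_stub_backend(noise_sigma = 0.1)("AAA", bb)
  expect_s3_class(pred, "backbone_structure")
  expect_lt(max(abs(pred$coords - bb$coords)), 1)
  set.seed(4)
  always_fail <- structure_stub_backend(fail_rate = 1)
  expect_null(always_fail("AAA", bb))

  # failed predictions surface as TM 0 through the full design protocol
  w <- tiny_world()
  pwm <- small_pwm()
  sel <- design_sequence(w$base, w$structures[[1]], pwm,
                         structure_backend = always_fail,
                         temperature = 1.0, seed = 5)
  if (!is.null(sel)) expect_equal(sel$tm_score, 0)
})

test_that("checkpoint evaluation aggregates per-structure rows", {
  w <- tiny_world()
  pwm <- small_pwm()
  expect_error(evaluate_checkpoint(w$base, list(), character(0), pwm),
               "empty")
  ev <- evaluate_checkpoint(w$base, w$structures, w$seqs, pwm,
                            protocol = "single", seed = 31)
  expect_equal(nrow(ev$rows), length(w$structures))
  expect_equal(ev$mean_visibility, mean(ev$rows$visibility))
  expect_equal(ev$mean_relative_visibility,
               mean(ev$rows$relative_visibility, na.rm = TRUE))
  expect_equal(ev$mean_recovery, mean(ev$rows$recovery))

  ev3 <- evaluate_checkpoint(w$base, w$structures[1:3], w$seqs[1:3], pwm,
                             protocol = "best_of_3", temperature = 1.0,
                             seed = 32)
  expect_equal(nrow(ev3$rows), 3L)
  expect_true(all(ev3$rows$tm_score >= 0 & ev3$rows$tm_score <= 1))
})

test_that("rank histograms partition the k-mers into binder categories", {
  s <- paste(rep("A", 20), collapse = "")
  k <- nrow(enumerate_kmers(s))
  set.seed(6)
  ranks <- runif(k, 0, 100)
  h <- rank_category_histogram(s, ranks)
  expect_equal(sum(h), k)
  # strong binders below 0.5, weak binders in (0.5, 2]
  h2 <- rank_category_histogram(s, c(0.1, 0.4, 1.0, rep(50, k - 3)))
  expect_equal(unname(h2[1]), 2L)
  expect_equal(unname(h2[2]), 1L)
  expect_equal(sum(rank_category_histogram("AAAA", numeric(0))), 0L)
  expect_error(rank_category_histogram(s, 1:3), "one entry per")
  expect_error(netmhcpan_adapter("HLA-A*02:01", path = "no_such_netmhcpan"),
               "not found")
})
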