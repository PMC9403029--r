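test_that("the score-difference rule is strict and infinity-safe", {
  r <- score_difference_rule(c(0.69, 0.52, 0.8, 0.8, Inf, 0.3),
                             c(0.83, 0.74, 0.8, 0.7, Inf, Inf))
  expect_equal(r$delta[1:2], c(-0.14, -0.22), tolerance = 1e-12)
  expect_equal(r$predicted, c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(r$delta[5], Inf)   # NaN sentinel
})

test_that("classify_positive_only applies the strict 0.85 cutoff", {
  expect_true(classify_positive_only(0.69))
  expect_false(classify_positive_only(0.85))
  expect_false(classify_positive_only(Inf))
  expect_equal(classify_positive_only(c(0.1, 0.9)), c(TRUE, FALSE))
})

test_that("rank_targets keeps passing targets in ascending docking order", {
  preds <- data.frame(
    id = c("A", "B", "C"),
    pocket_rank = 1L, score_pos = 0, score_neg = 0,
    delta = c(-0.14, -0.47, 0.1),
    predicted = c(TRUE, TRUE, FALSE),
    docking_score = NA_real_, significance = NA_real_)
  dock <- c(A = -167.63, B = -92.22, C = -200)
  out <- rank_targets(preds, dock)
  expect_equal(out$id, c("A", "B"))              # C excluded despite best dock
  expect_equal(out$docking_score, c(-167.63, -92.22))

  expect_equal(nrow(rank_targets(preds[preds$delta > 0, ], dock)), 0)

  # equal docking scores tie-break by delta
  dock2 <- c(A = -50, B = -50)
  out2 <- rank_targets(preds[1:2, ], dock2)
  expect_equal(out2$id, c("B", "A"))

  # missing docking scores sort last with a warning
  expect_warning(out3 <- rank_targets(preds[1:2, ], dock["B"]),
                 "no docking score")
  expect_equal(out3$id, c("B", "A"))
})

test_that("empirical_significance counts random scores at least as good", {
  set.seed(1)
  rnd <- runif(100, -100, 0)
  expect_equal(empirical_significance(min(rnd) - 1, rnd), 0)
  expect_equal(empirical_significance(max(rnd) + 1, rnd), 1)
  expect_equal(empirical_significance(-10, c(-20, -5, 0, 5)), 0.25)
  expect_error(empirical_significance(-10, numeric(0)), "at least one")
  # adding a worse (higher) random score never increases significance
  s0 <- empirical_significance(-10, rnd)
  expect_lte(empirical_significance(-10, c(rnd, 50)), s0)
  expect_true(all(vapply(seq(-200, 50, 25), function(t)
    empirical_significance(t, rnd), 1) %in% seq(0, 1, by = 0.01)))
})

test_that("evaluate computes standard confusion rates", {
  expect_equal(evaluate(c(TRUE, FALSE), c(TRUE, FALSE))$sensitivity, 1)
  expect_equal(evaluate(c(TRUE, FALSE), c(TRUE, FALSE))$specificity, 1)
  inv <- evaluate(c(FALSE, TRUE), c(TRUE, FALSE))
  expect_equal(c(inv$sensitivity, inv$specificity), c(0, 0))
  ev <- evaluate(c(rep(TRUE, 3), rep(FALSE, 5)),
                 c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(c(ev$tp, ev$fp, ev$tn, ev$fn), c(2, 1, 3, 2))
  expect_equal(ev$sensitivity, 0.5)
  expect_equal(ev$specificity, 0.75)
  expect_equal(ev$tp + ev$fp + ev$tn + ev$fn, 8)
  expect_error(evaluate(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("score_protein applies the min-delta pocket rule", {
  m <- make_motif(12, seed = 201)
  pos_pk <- lapply(1:4, function(i) {
    set.seed(210 + i)
    xyz <- as.matrix(m[, c("x", "y", "z")]) + matrix(rnorm(36, 0, 0.2), ncol = 3)
    aa3 <- names(pocketsig:::AA3TO1)[match(m$residue, pocketsig:::AA3TO1)]
    fixture_pocket(xyz, m$element, aa3, id = paste0("pp", i))
  })
  pos_sig <- build_positive_signature(pos_pk, drug_id = "sp")
  m2 <- make_motif(12, seed = 202)
  neg_pk <- lapply(1:4, function(i) {
    set.seed(220 + i)
    xyz <- as.matrix(m2[, c("x", "y", "z")]) + matrix(rnorm(36, 0, 0.2), ncol = 3)
    aa3 <- names(pocketsig:::AA3TO1)[match(m2$residue, pocketsig:::AA3TO1)]
    fixture_pocket(xyz, m2$element, aa3, id = paste0("np", i))
  })
  neg_sig <- pocketsig:::build_signature(neg_pk, scoring_params(),
                                         "negative", "sp")
  st <- fixture_structure(matrix(rnorm(90, sd = 8), ncol = 3), id = "query")
  pr <- score_protein(st, pos_sig, neg_sig, pockets = pos_pk[1])
  expect_true(pr$predicted)
  expect_lt(pr$delta, 0)
  expect_identical(pr$delta, pr$score_pos - pr$score_neg)

  # same signature on both sides -> delta exactly 0 -> not predicted (strict)
  pr0 <- score_protein(st, pos_sig, pos_sig, pockets = pos_pk[1])
  expect_equal(pr0$delta, 0)
  expect_false(pr0$predicted)

  # no pockets at all -> non-target with +Inf sentinel and a warning
  expect_warning(prE <- score_protein(st, pos_sig, neg_sig, pockets = list()),
                 "no detectable pockets")
  expect_false(prE$predicted)
  expect_equal(prE$delta, Inf)

  # unalignable pocket -> infinite scores
  tinyp <- random_pocket(9, seed = 231)
  prU <- score_protein(st, pos_sig, neg_sig, pockets = list(tinyp))
  expect_true(is.infinite(prU$score_pos) || prU$score_pos > 0)
})

test_that("cross_validate is seed-reproducible and validates inputs", {
  b <- make_benchmark(n_pos = 10, n_neg = 10, noise_sigma = 0.25,
                      dropout = 0.1, confusability = 0.2, seed = 42)
  cv1 <- suppressWarnings(cross_validate(b$structures, b$labels, folds = 5,
                                         seed = 9))
  cv2 <- suppressWarnings(cross_validate(b$structures, b$labels, folds = 5,
                                         seed = 9))
  expect_equal(cv1$folds, cv2$folds)
  expect_equal(c(cv1$tp, cv1$fp, cv1$tn, cv1$fn),
               c(cv2$tp, cv2$fp, cv2$tn, cv2$fn))
  expect_equal(cv1$tp + cv1$fp + cv1$tn + cv1$fn, 20)
  expect_true(all(table(cv1$folds, b$labels) >= 1))

  expect_error(cross_validate(b$structures[1:6], b$labels[1:6], folds = 5),
               "at least 5")
})

test_that("difference and positive-only modes are isolated and co-computable", {
  b <- make_benchmark(n_pos = 10, n_neg = 10, noise_sigma = 0.25,
                      dropout = 0.1, confusability = 0.2, seed = 43)
  both <- suppressWarnings(cross_validate(
    b$structures, b$labels, folds = 5, seed = 3,
    mode = c("difference", "positive_only")))
  expect_named(both, c("difference", "positive_only"))
  for (ev in both) {
    expect_s3_class(ev, "eval_result")
    expect_equal(ev$tp + ev$fp + ev$tn + ev$fn, 20)
    expect_true(ev$sensitivity >= 0 && ev$sensitivity <= 1)
    expect_true(ev$specificity >= 0 && ev$specificity <= 1)
  }
  # the well-separated benchmark is solved by the difference rule
  expect_gte(both$difference$sensitivity, 0.8)
  expect_gte(both$difference$specificity, 0.8)
})
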