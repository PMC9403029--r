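test_that("structural_score follows RMSD * N^(-1/3)", {
  expect_equal(structural_score(2.0, 64), 0.5)
  expect_equal(structural_score(0.0, 10), 0.0)
  expect_equal(structural_score(1.5, 27), 0.5)
  expect_error(structural_score(1.0, 0), "n must be >= 1")
  # strictly increasing in rmsd, strictly decreasing in n
  r <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(structural_score(r, 10)) > 0))
  n <- 3:50
  expect_true(all(diff(structural_score(1.3, n)) < 0))
})

test_that("sequence_score spans [0, 1] with the stated limits", {
  expect_equal(sequence_score(5, 5), 0)
  expect_equal(sequence_score(0, 5), 1)
  expect_equal(sequence_score(2.5, 5), 0.5)
  expect_error(sequence_score(1, 0), "best_similarity")
})

test_that("combined_score obeys its defining identity", {
  expect_equal(combined_score(0.5, 0.0, 1.2), 0.5)
  expect_equal(combined_score(0.0, 1.0, 1.2), 1.2)
  expect_equal(combined_score(0.5, 0.5, 1.2), 1.1)
  set.seed(99)
  s <- runif(200, 0, 3); q <- runif(200); a <- runif(200, 0.5, 2)
  expect_identical(combined_score(s, q, a), s + a * q)
})

test_that("kabsch_superpose recovers exact rigid transforms", {
  set.seed(5)
  P <- matrix(rnorm(30), ncol = 3)
  self <- kabsch_superpose(P, P)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9)

  rigid <- random_rigid(13)
  Q <- P %*% t(rigid$R)
  Q <- sweep(Q, 2, -rigid$t)
  out <- kabsch_superpose(P, Q)
  expect_lt(out$rmsd, 1e-9)
  expect_equal(out$rotation, rigid$R, tolerance = 1e-6)
  expect_equal(out$translation, rigid$t, tolerance = 1e-6)
  expect_equal(det(out$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), ">= 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("kabsch_superpose matches the frozen oracle residual for a known perturbation", {
  P <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  Q <- P
  Q[1, ] <- Q[1, ] + c(0, 0, 0.4)
  out <- kabsch_superpose(P, Q)
  expect_equal(out$rmsd, 0.100975726199, tolerance = 1e-9)  # frozen from oracle
  expect_equal(out$rmsd, oracle_kabsch(P, Q)$rmsd, tolerance = 1e-12)
})

test_that("self- and rigid-copy alignments are exact", {
  p <- random_pocket(12, seed = 31)
  prm <- scoring_params()
  self <- align_pockets(p, p, prm)
  expect_true(self$aligned)
  expect_equal(self$n, 12L)
  expect_lt(self$rmsd, 1e-9)
  expect_equal(self$sequence_score, 0)
  expect_lt(self$combined_score, 1e-9)

  q <- transform_pocket(p, random_rigid(77))
  al <- align_pockets(p, q, prm)
  expect_equal(al$n, 12L)
  expect_lt(al$rmsd, 1e-6)
  expect_lt(abs(al$combined_score - self$combined_score), 1e-6)
})

test_that("tiny scrambled pockets match the brute-force oracle", {
  prm <- scoring_params(min_aligned = 3L)
  for (seed in c(101, 102, 103, 104, 105, 106)) {
    set.seed(seed)
    n <- sample(4:5, 1)
    a <- random_pocket(n, seed = seed, spread = 3)
    b <- random_pocket(n, seed = seed + 1000, spread = 3)
    al <- align_pockets(a, b, prm)
    oracle <- oracle_align_score(a, b, prm)
    if (is.finite(oracle)) {
      expect_lt(abs(al$combined_score - oracle), 1e-6)
    } else {
      expect_false(al$aligned)
    }
    # scrambling the atom order must not change the optimum
    ord <- sample(n)
    a2 <- fixture_pocket(as.matrix(a$atoms[ord, c("x", "y", "z")]),
                         a$atoms$element[ord], a$atoms$residue_name[ord])
    al2 <- align_pockets(a2, b, prm)
    expect_equal(al2$combined_score, al$combined_score, tolerance = 1e-9)
  }
})

test_that("pairwise alignment is symmetric at the optimum (tiny pockets)", {
  prm <- scoring_params(min_aligned = 3L)
  for (seed in c(11, 12, 13, 14)) {
    a <- random_pocket(5, seed = seed, spread = 3)
    b <- random_pocket(5, seed = seed + 500, spread = 3)
    sab <- align_pockets(a, b, prm)$combined_score
    sba <- align_pockets(b, a, prm)$combined_score
    if (is.finite(sab) || is.finite(sba)) {
      expect_lt(abs(sab - sba), 1e-6)
    } else succeed()
  }
})

test_that("combined-score identity holds on every alignment result", {
  checked <- 0L
  for (seed in c(61, 62, 63)) {
    a <- random_pocket(14, seed = seed)
    # noisy rigid copy so the alignment always succeeds
    set.seed(seed + 20)
    xyz <- as.matrix(a$atoms[, c("x", "y", "z")]) +
      matrix(rnorm(42, 0, 0.2), ncol = 3)
    b <- transform_pocket(
      fixture_pocket(xyz, a$atoms$element, a$atoms$residue_name),
      random_rigid(seed))
    al <- align_pockets(a, b)
    expect_true(al$aligned)
    checked <- checked + 1L
    expect_identical(al$combined_score,
                     al$structural_score + al$alpha * al$sequence_score)
    expect_identical(al$sequence_score,
                     1 - al$sequence_similarity / al$best_sequence_similarity)
    expect_identical(al$structural_score, al$rmsd * al$n^(-1 / 3))
    expect_equal(al$n, nrow(al$pairs))
    expect_false(any(duplicated(al$pairs$query)))
    expect_false(any(duplicated(al$pairs$ref)))
    expect_true(al$sequence_score >= 0 && al$sequence_score <= 1)
  }
  expect_equal(checked, 3L)
})

test_that("rigid invariance holds for seeded random pockets", {
  prm <- scoring_params()
  for (seed in c(301, 302, 303, 304, 305)) {
    set.seed(seed)
    p <- random_pocket(sample(9:16, 1), seed = seed)
    q <- transform_pocket(p, random_rigid(seed + 7))
    al <- align_pockets(p, q, prm)
    expect_equal(al$n, nrow(p$atoms))
    expect_lt(al$rmsd, 1e-6)
    expect_lt(al$combined_score, 1e-6)
  }
})

test_that("align_to_signature reproduces the hand-computed worked example", {
  # 3 positions, hand-built frequency tables
  coords <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0))
  af <- matrix(c(0.9, 0.0, 0.1,
                 0.0, 0.8, 0.0,
                 0.0, 0.0, 0.6),
               3, 3, byrow = TRUE, dimnames = list(NULL, c("C", "N", "O")))
  rf <- matrix(c(0.7, 0.2,
                 0.8, 0.0,
                 0.0, 0.5),
               3, 2, byrow = TRUE, dimnames = list(NULL, c("A", "G")))
  sig <- fixture_signature(coords, af, rf, preservation = c(0.9, 0.8, 0.6))
  # query: same geometry; types C/A, N/G, S/A
  q <- fixture_pocket(coords, element = c("C", "N", "S"),
                      residue = c("ALA", "GLY", "ALA"))
  al <- align_to_signature(q, sig, scoring_params(min_aligned = 3L))
  expect_equal(al$n, 3L)
  expect_lt(al$rmsd, 1e-9)
  # The triangle is isoceles (legs 4, 4), so two rmsd-0 correspondences
  # exist: identity and the in-plane flip (q2 -> p3, q3 -> p2).  Hand sums:
  #   identity: (0.9 + 0.7) + (0.8 + 0.0) + (0.0 + 0.0) = 2.4
  #   flip:     (0.9 + 0.7) + (0.0 + 0.5) + (0.0 + 0.8) = 2.9  <- optimum
  # best similarity over the aligned positions (either way):
  #   (0.9 + 0.7) + (0.8 + 0.8) + (0.6 + 0.5) = 4.3
  expect_equal(al$sequence_similarity, 2.9)
  expect_equal(al$best_sequence_similarity, 4.3)
  expect_equal(al$sequence_score, 1 - 2.9 / 4.3)
  expect_equal(al$combined_score, 1.2 * (1 - 2.9 / 4.3), tolerance = 1e-9)
  expect_equal(al$pairs$ref, c(1L, 3L, 2L))   # the flip correspondence
  # absent types contribute exactly 0; with an O atom (present only at
  # position 3) and a W residue (absent everywhere) the identity mapping
  # becomes optimal with hand sum (0.9+0.7) + (0.8+0) + (0.6+0) = 3.0
  q3 <- fixture_pocket(coords, element = c("C", "N", "O"),
                       residue = c("ALA", "GLY", "TRP"))
  al3 <- align_to_signature(q3, sig, scoring_params(min_aligned = 3L))
  expect_equal(al3$sequence_similarity, 3.0)
  expect_equal(al3$pairs$ref, 1:3)
})

test_that("a pocket matches a signature built from copies of itself", {
  m <- make_motif(10, seed = 41)
  pk <- motif_pocket(m)
  sig <- build_positive_signature(list(pk, pk, pk), scoring_params(),
                                  drug_id = "self")
  al <- align_to_signature(pk, sig, scoring_params())
  expect_equal(al$n, 10L)
  expect_lt(al$rmsd, 1e-6)
  expect_equal(al$sequence_score, 0, tolerance = 1e-9)
})

test_that("undersized pockets yield a no-alignment result, not an error", {
  a <- random_pocket(4, seed = 3)
  b <- random_pocket(12, seed = 4)
  al <- align_pockets(a, b, scoring_params(min_aligned = 8L))
  expect_false(al$aligned)
  expect_equal(al$combined_score, Inf)
  expect_equal(al$n, 0L)
})
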