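noisy_motif_pocket <- function(motif, seed, sigma = 0.3, drop = 0L,
                               id = paste0("n", seed)) {
  set.seed(seed)
  keep <- seq_len(nrow(motif))
  if (drop > 0) keep <- keep[-(seq_len(drop))]
  xyz <- as.matrix(motif[keep, c("x", "y", "z")]) +
    matrix(rnorm(3 * length(keep), 0, sigma), ncol = 3)
  aa3 <- names(pocketsig:::AA3TO1)[match(motif$residue[keep],
                                         pocketsig:::AA3TO1)]
  fixture_pocket(xyz, motif$element[keep], aa3, id = id)
}

test_that("pairwise_score_matrix is symmetric with a zero diagonal", {
  m <- make_motif(10, seed = 51)
  p <- motif_pocket(m)
  M <- pairwise_score_matrix(list(p, p))
  expect_equal(dim(M), c(2, 2))
  expect_equal(diag(M), c(0, 0))
  expect_lt(M[1, 2], 1e-9)

  q <- random_pocket(10, seed = 52)
  M3 <- pairwise_score_matrix(list(p, p, q))
  expect_equal(M3, t(M3))
  expect_true(M3[1, 2] < M3[1, 3] && M3[1, 2] < M3[2, 3])

  expect_error(pairwise_score_matrix(list(p)), ">= 2")
})

test_that("guide_tree performs average linkage with deterministic ties", {
  D <- matrix(c(0, 0.1, 1, 0.1, 0, 1, 1, 1, 0), 3, 3)
  tr <- guide_tree(D)
  expect_equal(sort(tr$merge[1, ]), c(-2L, -1L))   # forced first merge {1,2}

  # equal distances merge in index order
  E <- matrix(1, 4, 4); diag(E) <- 0
  tr2 <- guide_tree(E)
  expect_equal(sort(tr2$merge[1, ]), c(-2L, -1L))
  expect_equal(sort(tr2$merge[2, ]), c(-3L, 1L))
  expect_equal(sort(tr2$merge[3, ]), c(-4L, 2L))

  # hand-executed 4-item average linkage:
  # d(1,2)=2 d(1,3)=6 d(1,4)=10 d(2,3)=5 d(2,4)=9 d(3,4)=4
  # step1 {1,2}@2; step2 {3,4}@4; step3 @ (6+10+5+9)/4 = 7.5
  H <- matrix(0, 4, 4)
  H[1, 2] <- 2; H[1, 3] <- 6; H[1, 4] <- 10
  H[2, 3] <- 5; H[2, 4] <- 9; H[3, 4] <- 4
  H <- H + t(H)
  tr3 <- guide_tree(H)
  expect_equal(tr3$height, c(2, 4, 7.5))
  expect_equal(sort(tr3$merge[1, ]), c(-2L, -1L))
  expect_equal(sort(tr3$merge[2, ]), c(-4L, -3L))
  expect_equal(sort(tr3$merge[3, ]), c(1L, 2L))
  # agrees with stats::hclust on this tie-free matrix
  hc <- stats::hclust(stats::as.dist(H), method = "average")
  expect_equal(tr3$height, hc$height)

  expect_error(guide_tree(matrix(1:6, 2, 3)), "square")
})

test_that("progressive_profile pools identical and partially deleted pockets", {
  m <- make_motif(10, seed = 61)
  pks <- lapply(1:4, function(i) motif_pocket(m, id = paste0("c", i)))
  M <- pairwise_score_matrix(pks)
  prof <- progressive_profile(pks, guide_tree(M))
  expect_equal(nrow(prof$positions), 10)
  expect_equal(prof$positions$preservation, rep(1, 10))
  expect_equal(unname(apply(prof$atom_freq, 1, max)), rep(1, 10))
  expect_equal(unname(apply(prof$atom_freq, 1, sum)), rep(1, 10))

  # delete the same atom from 2 of 4 copies -> preservation 0.5 there
  pks2 <- list(motif_pocket(m, id = "f1"), motif_pocket(m, id = "f2"),
               noisy_motif_pocket(m, 1, sigma = 0, drop = 1L, id = "d1"),
               noisy_motif_pocket(m, 2, sigma = 0, drop = 1L, id = "d2"))
  prof2 <- progressive_profile(pks2, guide_tree(pairwise_score_matrix(pks2)))
  expect_equal(nrow(prof2$positions), 10)
  expect_equal(sort(prof2$positions$preservation),
               c(0.5, rep(1, 9)))
})

test_that("progressive_profile recovers a noisy motif within 0.5 A", {
  m <- make_motif(8, seed = 71)
  pks <- lapply(1:6, function(i) noisy_motif_pocket(m, 700 + i, sigma = 0.3))
  prof <- progressive_profile(pks, guide_tree(pairwise_score_matrix(pks)))
  expect_equal(nrow(prof$positions), 8)
  sig <- prune_profiles(prof, drug_id = "rec")
  al <- align_to_signature(motif_pocket(m), sig, scoring_params())
  expect_equal(al$n, 8L)
  tp <- as.matrix(m[al$pairs$query, c("x", "y", "z")]) %*% t(al$rotation)
  tp <- sweep(tp, 2, -al$translation)
  d <- sqrt(rowSums((tp - pocketsig:::signature_coords(sig)[al$pairs$ref, ])^2))
  expect_lt(max(d), 0.5)
})

test_that("prune_profiles applies the preservation schedule and cap", {
  mk_prof <- function(pres) {
    P <- length(pres)
    structure(list(
      positions = data.frame(index = seq_len(P), x = seq_len(P), y = 0, z = 0,
                             preservation = pres,
                             support = as.integer(round(pres * 20))),
      atom_freq = matrix(pres, P, 1, dimnames = list(NULL, "C")),
      res_freq = matrix(pres, P, 1, dimnames = list(NULL, "A")),
      n_structures = 20L), class = "position_profiles")
  }
  s1 <- prune_profiles(mk_prof(c(0.4, 0.6, 0.9)))
  expect_equal(nrow(s1$positions), 2)
  expect_equal(s1$preservation_cutoff, 0.5)

  s2 <- prune_profiles(mk_prof(rep(0.8, 150)))
  expect_equal(nrow(s2$positions), 100)      # cap via the tie rule
  expect_equal(s2$positions$x, as.numeric(1:100))

  s3 <- prune_profiles(mk_prof(c(rep(0.9, 90), rep(0.55, 30))))
  expect_equal(nrow(s3$positions), 90)
  expect_equal(s3$preservation_cutoff, 0.6, tolerance = 1e-9)

  expect_error(prune_profiles(mk_prof(c(0.1, 0.2))), "no conserved core")
})

test_that("build_positive_signature of identical pockets echoes the pocket", {
  m <- make_motif(9, seed = 81)
  p <- motif_pocket(m)
  sig <- build_positive_signature(list(p, p), drug_id = "dup")
  expect_equal(sig$polarity, "positive")
  expect_equal(nrow(sig$positions), 9)
  expect_equal(sig$positions$preservation, rep(1, 9))
  expect_equal(unname(apply(sig$atom_freq, 1, max)), rep(1, 9))
  expect_error(build_positive_signature(list(p), drug_id = "one"), ">= 2")
})

test_that("select_negative_pocket picks the pocket most similar to the reference", {
  m <- make_motif(10, seed = 91)
  ref <- motif_pocket(m, id = "ref")
  copy <- motif_pocket(m, id = "copy")
  decoy <- random_pocket(10, seed = 92)
  st <- fixture_structure(matrix(rnorm(60), ncol = 3), id = "host")
  sel <- select_negative_pocket(st, ref, pockets = list(decoy, copy))
  expect_identical(sel$structure_id, "copy")

  sel1 <- select_negative_pocket(st, ref, pockets = list(decoy))
  expect_identical(sel1$structure_id, decoy$structure_id)

  noisy <- noisy_motif_pocket(m, 93, sigma = 0.5, id = "noisy1")
  unrelated <- random_pocket(10, seed = 94)
  sel2 <- select_negative_pocket(st, ref, pockets = list(unrelated, noisy))
  expect_identical(sel2$structure_id, "noisy1")
  # oracle check on the underlying scores
  s_noisy <- align_pockets(noisy, ref)$combined_score
  s_unrel <- align_pockets(unrelated, ref)$combined_score
  expect_lt(s_noisy, s_unrel)

  tiny <- random_pocket(4, seed = 95)
  expect_warning(sel3 <- select_negative_pocket(st, ref, pockets = list(tiny)),
                 "no alignable pocket")
  expect_null(sel3)
})

test_that("negatives that copy the positives give a near-identical signature", {
  m <- make_motif(10, seed = 96)
  pks <- lapply(1:4, function(i) noisy_motif_pocket(m, 960 + i, sigma = 0.1,
                                                   id = paste0("p", i)))
  pos_sig <- build_positive_signature(pks, drug_id = "same")
  sts <- lapply(1:4, function(i)
    fixture_structure(matrix(rnorm(60), ncol = 3), id = paste0("s", i)))
  neg_sig <- build_negative_signature(sts, pks[[1]], drug_id = "same",
                                      pockets = lapply(pks, list))
  expect_equal(neg_sig$polarity, "negative")
  expect_equal(nrow(neg_sig$positions), nrow(pos_sig$positions))
  # scoring the same pocket against both gives delta ~ 0
  sp <- align_to_signature(pks[[2]], pos_sig)$combined_score
  sn <- align_to_signature(pks[[2]], neg_sig)$combined_score
  expect_lt(abs(sp - sn), 0.05)

  expect_error(build_negative_signature(sts[1], pks[[1]],
                                        pockets = lapply(pks[1], list)),
               ">= 2 negative")
})

test_that("signature frequencies are invariant to input order", {
  m <- make_motif(11, seed = 97)
  pks <- lapply(1:6, function(i)
    noisy_motif_pocket(m, 970 + i, sigma = 0.25, drop = (i - 1L) %% 3L,
                       id = paste0("m", i)))
  s1 <- build_positive_signature(pks, drug_id = "perm")
  s2 <- build_positive_signature(rev(pks), drug_id = "perm")
  expect_equal(sort(s1$positions$preservation), sort(s2$positions$preservation),
               tolerance = 1e-9)
  expect_equal(sort(apply(s1$atom_freq, 1, max)),
               sort(apply(s2$atom_freq, 1, max)), tolerance = 1e-9)
  expect_equal(s1$n_structures, s2$n_structures)
})

test_that("more coordinate noise never increases mean preservation", {
  m <- make_motif(9, seed = 98)
  mean_pres <- function(sigma, seed) {
    pks <- lapply(1:6, function(i) noisy_motif_pocket(m, seed + i, sigma))
    sig <- suppressWarnings(build_positive_signature(pks, drug_id = "mono"))
    mean(sig$positions$preservation) * nrow(sig$positions)
  }
  lo <- mean(vapply(c(100, 200, 300), function(s) mean_pres(0.1, s), 1))
  hi <- mean(vapply(c(100, 200, 300), function(s) mean_pres(0.7, s), 1))
  expect_gte(lo, hi)
})

test_that("built signatures always satisfy their invariants", {
  m <- make_motif(12, seed = 99)
  pks <- lapply(1:5, function(i) noisy_motif_pocket(m, 990 + i, sigma = 0.4))
  sig <- suppressWarnings(build_positive_signature(pks, drug_id = "inv"))
  expect_silent(pocketsig:::validate_signature(sig))
  expect_lte(nrow(sig$positions), 100)
  expect_gte(sig$preservation_cutoff, 0.5)
  expect_true(all(sig$positions$preservation >= sig$preservation_cutoff - 1e-9))
  expect_true(all(sig$atom_freq <= sig$positions$preservation + 1e-9))
})
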