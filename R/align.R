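#' Score components of the pocket alignment
#'
#' The combined alignment score is
#' `Score = StructuralScore + alpha * SequenceScore` with
#' `StructuralScore = RMSD * N^(-1/3)` and
#' `SequenceScore = 1 - SequenceSimilarity / BestSequenceSimilarity`.
#' Lower is better.  `SequenceSimilarity` sums, over aligned positions, the
#' reference frequency of the query atom's element plus that of its residue
#' type; `BestSequenceSimilarity` sums the modal frequencies over the same
#' aligned positions, so the sequence score always lies in `[0, 1]`.
#'
#' @param rmsd Root-mean-square distance of the superposed correspondence
#'   (Angstrom, >= 0).
#' @param n Number of aligned positions (>= 1).
#' @return `structural_score()`: `rmsd * n^(-1/3)`.
#' @export
structural_score <- function(rmsd, n) {
  if (any(n < 1)) stopf("undefined alignment: n must be >= 1")
  if (any(rmsd < 0)) stopf("rmsd must be >= 0")
  rmsd * n^(-1 / 3)
}

#' @rdname structural_score
#' @param similarity Summed aligned-position frequency of the query types.
#' @param best_similarity Summed modal frequencies over the same positions
#'   (> 0).
#' @return `sequence_score()`: `1 - similarity / best_similarity`.
#' @export
sequence_score <- function(similarity, best_similarity) {
  if (any(best_similarity <= 0))
    stopf("empty profile: best_similarity must be > 0")
  if (any(similarity < 0 | similarity > best_similarity + 1e-12))
    stopf("similarity must lie in [0, best_similarity]")
  1 - similarity / best_similarity
}

#' @rdname structural_score
#' @param structural,sequence Finite score components (`sequence` in
#'   `[0, 1]`).
#' @param alpha Sequence-score weight (default 1.2).
#' @return `combined_score()`: `structural + alpha * sequence`.
#' @export
combined_score <- function(structural, sequence, alpha = 1.2) {
  if (any(!is.finite(structural)) || any(!is.finite(sequence)))
    stopf("score components must be finite")
  if (any(sequence < -1e-12 | sequence > 1 + 1e-12))
    stopf("sequence score must lie in [0, 1]")
  structural + alpha * sequence
}

#' Optimal rigid superposition of matched point pairs
#'
#' Least-squares proper rotation and translation (Kabsch algorithm) mapping
#' `P` onto `Q`, with the residual RMSD.
#'
#' @param P,Q Numeric matrices (k x 3) of matched points, `k >= 3`,
#'   non-collinear.
#' @return List with `rotation` (3 x 3 proper orthonormal), `translation`
#'   (length 3; `q ~ rotation %*% p + translation`) and `rmsd`.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) < 3 || nrow(Q) != nrow(P) || ncol(P) != 3 || ncol(Q) != 3)
    stopf("need >= 3 matched 3D point pairs")
  sv <- svd(scale(P, scale = FALSE))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stopf("degenerate (collinear) point set")
  out <- .kabsch_cpp(P, Q)
  out$translation <- as.numeric(out$translation)
  out
}

# ---------------------------------------------------------------------------
# Internal alignment machinery

no_alignment <- function(params) {
  structure(list(
    aligned = FALSE, pairs = data.frame(query = integer(0), ref = integer(0)),
    n = 0L, rmsd = NA_real_, rotation = NULL, translation = NULL,
    structural_score = Inf, sequence_similarity = NA_real_,
    best_sequence_similarity = NA_real_, sequence_score = NA_real_,
    combined_score = Inf, alpha = params$alpha,
    match_distance = params$match_distance
  ), class = "pocket_alignment")
}

# Triangle seeds between two typed point sets.  Vertex pools favour rare
# element types and central atoms; triangle pairs are matched by congruence
# of sorted side lengths (each side within 0.5 A) and ranked by element
# compatibility then total side difference.  Deterministic.
triangle_seeds <- function(qc, qe, rc, re, params, pool_size = 12L) {
  pool <- function(coords, elems) {
    n <- nrow(coords)
    freq <- table(elems)
    rar <- 1 / as.numeric(freq[elems])
    cen <- colMeans(coords)
    dcen <- sqrt(rowSums((coords - matrix(cen, n, 3, byrow = TRUE))^2))
    order(-rar, dcen, seq_len(n))[seq_len(min(pool_size, n))]
  }
  tris <- function(coords, ids) {
    if (length(ids) < 3) return(NULL)
    cmb <- t(utils::combn(ids, 3))
    v1 <- cmb[, 1]; v2 <- cmb[, 2]; v3 <- cmb[, 3]
    d1 <- sqrt(rowSums((coords[v2, , drop = FALSE] - coords[v3, , drop = FALSE])^2))
    d2 <- sqrt(rowSums((coords[v1, , drop = FALSE] - coords[v3, , drop = FALSE])^2))
    d3 <- sqrt(rowSums((coords[v1, , drop = FALSE] - coords[v2, , drop = FALSE])^2))
    sp <- (d1 + d2 + d3) / 2
    area2 <- sp * (sp - d1) * (sp - d2) * (sp - d3)
    keep <- pmin(d1, d2, d3) >= 1.5 & !is.na(area2) & area2 >= 0.25
    if (!any(keep)) return(NULL)
    D <- cbind(d1, d2, d3)[keep, , drop = FALSE]
    V <- cmb[keep, , drop = FALSE]
    # order vertices by their opposite side length (epsilon index tie-break)
    Dt <- D + V * 1e-9
    r1 <- 1L + (Dt[, 2] < Dt[, 1]) + (Dt[, 3] < Dt[, 1])
    r2 <- 1L + (Dt[, 1] <= Dt[, 2]) + (Dt[, 3] < Dt[, 2])
    r3 <- 6L - r1 - r2
    n <- nrow(D)
    sides <- matrix(0, n, 3)
    verts <- matrix(0L, n, 3)
    sides[cbind(seq_len(n), r1)] <- D[, 1]
    sides[cbind(seq_len(n), r2)] <- D[, 2]
    sides[cbind(seq_len(n), r3)] <- D[, 3]
    verts[cbind(seq_len(n), r1)] <- V[, 1]
    verts[cbind(seq_len(n), r2)] <- V[, 2]
    verts[cbind(seq_len(n), r3)] <- V[, 3]
    list(sides = sides, verts = verts)
  }
  tq <- tris(qc, pool(qc, qe))
  tr <- tris(rc, pool(rc, re))
  if (is.null(tq) || is.null(tr)) return(NULL)
  nq <- nrow(tq$sides); nr <- nrow(tr$sides)
  d1 <- abs(outer(tq$sides[, 1], tr$sides[, 1], "-"))
  d2 <- abs(outer(tq$sides[, 2], tr$sides[, 2], "-"))
  d3 <- abs(outer(tq$sides[, 3], tr$sides[, 3], "-"))
  ok <- d1 <= 0.5 & d2 <= 0.5 & d3 <= 0.5
  if (!any(ok)) return(NULL)
  w <- which(ok, arr.ind = TRUE)
  tot <- d1[ok] + d2[ok] + d3[ok]
  EQ <- matrix(qe[tq$verts[w[, 1], ]], nrow(w), 3)
  ER <- matrix(re[tr$verts[w[, 2], ]], nrow(w), 3)
  mism <- rowSums(EQ != ER)
  ord <- order(mism, tot, w[, 1], w[, 2])
  ord <- ord[seq_len(min(params$max_seed_pairs, length(ord)))]
  list(seedsA = tq$verts[w[ord, 1], , drop = FALSE],
       seedsB = tr$verts[w[ord, 2], , drop = FALSE])
}

# Shared alignment core: query typed atoms against reference points with a
# per-pair similarity matrix and per-position modal ("best") vector.
# `re` carries the reference's (modal) element types, used only for seeding.
align_impl <- function(qc, qe, qr, rc, re, simMat, bestVec, params) {
  n <- nrow(qc); m <- nrow(rc)
  if (n < params$min_aligned || m < params$min_aligned)
    return(no_alignment(params))
  exhaustive <- n <= params$exhaustive_limit && m <= params$exhaustive_limit
  if (exhaustive) {
    seedsA <- matrix(0L, 0, 3); seedsB <- matrix(0L, 0, 3)
  } else {
    sd <- triangle_seeds(qc, qe, rc, re, params)
    if (is.null(sd)) return(no_alignment(params))
    seedsA <- sd$seedsA; seedsB <- sd$seedsB
  }
  res <- .align_search_cpp(qc, rc, simMat, bestVec,
                           params$alpha, params$match_distance,
                           params$min_aligned, seedsA, seedsB,
                           exhaustive, params$max_iter, params$tie_tol,
                           params$max_polish)
  if (!isTRUE(res$aligned)) return(no_alignment(params))
  nal <- res$n
  struct_sc <- structural_score(res$rmsd, nal)
  seq_sc <- sequence_score(res$similarity, res$best_similarity)
  structure(list(
    aligned = TRUE,
    pairs = data.frame(query = res$pairs[, 1], ref = res$pairs[, 2]),
    n = as.integer(nal), rmsd = res$rmsd,
    rotation = res$rotation, translation = as.numeric(res$translation),
    structural_score = struct_sc,
    sequence_similarity = res$similarity,
    best_sequence_similarity = res$best_similarity,
    sequence_score = seq_sc,
    combined_score = combined_score(struct_sc, seq_sc, params$alpha),
    alpha = params$alpha, match_distance = params$match_distance
  ), class = "pocket_alignment")
}

#' @export
print.pocket_alignment <- function(x, ...) {
  if (!x$aligned) {
    cat("<pocket_alignment> no alignment (score Inf)\n")
  } else {
    cat(sprintf(
      "<pocket_alignment> N=%d rmsd=%.3f structural=%.3f sequence=%.3f combined=%.3f\n",
      x$n, x$rmsd, x$structural_score, x$sequence_score, x$combined_score))
  }
  invisible(x)
}

#' Sequence-order-independent alignment of two pockets
#'
#' Finds a one-to-one atom correspondence between two pockets by geometry
#' and atom typing, ignoring chain order.  Candidate superpositions are
#' seeded from approximately congruent atom triangles (side differences
#' at most 0.5 A), grown by iterated threshold matching with optimal
#' bipartite refinement, and the candidate minimising the combined score is
#' returned.  Pockets with at most `exhaustive_limit` atoms on both sides
#' are aligned by exhaustive enumeration of all admissible correspondences,
#' which guarantees the optimum for tiny pockets.  In the pairwise case the
#' reference pocket acts as a one-member profile: type frequencies are
#' indicators, so each aligned pair contributes 1 per matching element and
#' residue type out of a maximum of 2.
#'
#' @param query,ref `pocket` objects with at least `min_aligned` atoms.
#' @param params A [scoring_params()] list.
#' @return A `pocket_alignment`; when no correspondence of at least
#'   `min_aligned` atoms exists the result has `aligned = FALSE` and
#'   infinite combined score (degenerate geometry is not an error).
#' @export
align_pockets <- function(query, ref, params = scoring_params()) {
  params <- as_scoring_params(params)
  qc <- pocket_coords(query); rc <- pocket_coords(ref)
  qe <- query$atoms$element; qr <- query$atoms$residue
  re <- ref$atoms$element; rr <- ref$atoms$residue
  simMat <- outer(qe, re, "==") + outer(qr, rr, "==")
  storage.mode(simMat) <- "double"
  bestVec <- rep(2, nrow(rc))
  align_impl(qc, qe, qr, rc, re, simMat, bestVec, params)
}

#' Align a pocket to a structural signature
#'
#' As [align_pockets()], but the reference points are the signature position
#' centroids and the sequence similarity uses the signature's frequency
#' tables: each aligned position contributes the relative frequency of the
#' query atom's element plus that of its residue type, and the best
#' similarity sums the modal atom and residue frequencies over the same
#' aligned positions.
#'
#' @param pocket A `pocket` with at least `min_aligned` atoms.
#' @param signature A `structural_signature`.
#' @param params A [scoring_params()] list.
#' @return A `pocket_alignment` (see [align_pockets()]).
#' @export
align_to_signature <- function(pocket, signature, params = scoring_params()) {
  params <- as_scoring_params(params)
  qc <- pocket_coords(pocket)
  qe <- pocket$atoms$element; qr <- pocket$atoms$residue
  rc <- signature_coords(signature)
  sim <- signature_similarity_matrix(signature, qe, qr)
  align_impl(qc, qe, qr, rc, sim$modal_element, sim$simMat, sim$bestVec,
             params)
}
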