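# Structural signature construction: pairwise pocket alignment, an
# average-linkage guide tree, progressive profile merging along the tree,
# and preservation-ratio pruning.

# --- profile representation -------------------------------------------------
# A profile holds pooled positions over a set of member pockets:
#   coords      P x 3 centroids (support-weighted means)
#   atom_counts P x E member counts per element
#   res_counts  P x R member counts per residue type
#   support     P     members contributing any atom at the position
#   members     number of pockets pooled so far
#   leaves      leaf ids pooled so far

profile_from_pocket <- function(pocket, leaf_id) {
  el <- pocket$atoms$element
  rs <- pocket$atoms$residue
  P <- nrow(pocket$atoms)
  elev <- sort(unique(el)); rlev <- sort(unique(rs))
  ac <- matrix(0, P, length(elev), dimnames = list(NULL, elev))
  rc <- matrix(0, P, length(rlev), dimnames = list(NULL, rlev))
  ac[cbind(seq_len(P), match(el, elev))] <- 1
  rc[cbind(seq_len(P), match(rs, rlev))] <- 1
  list(coords = pocket_coords(pocket), atom_counts = ac, res_counts = rc,
       support = rep(1L, P), members = 1L, leaves = leaf_id)
}

# Extend count matrix columns to a common level set.
grow_cols <- function(m, levels) {
  missing <- setdiff(levels, colnames(m))
  if (length(missing) > 0) {
    m <- cbind(m, matrix(0, nrow(m), length(missing),
                         dimnames = list(NULL, missing)))
  }
  m[, levels, drop = FALSE]
}

modal_types <- function(counts) {
  colnames(counts)[max.col(counts, ties.method = "first")]
}

# Merge the smaller profile into the frame of the larger one.  Matched
# positions pool their counts and take support-weighted mean centroids;
# unmatched query positions are appended.  Positions that can no longer
# reach the preservation cutoff even if every remaining member contributes
# are dropped (this cannot change the final signature).
merge_profiles <- function(a, b, params, total_members) {
  if (b$members > a$members ||
      (b$members == a$members && nrow(b$coords) > nrow(a$coords)) ||
      (b$members == a$members && nrow(b$coords) == nrow(a$coords) &&
         min(b$leaves) < min(a$leaves))) {
    tmp <- a; a <- b; b <- tmp
  }
  relA <- a$atom_counts / a$members
  relR <- a$res_counts / a$members
  qe <- modal_types(b$atom_counts)
  qr <- modal_types(b$res_counts)
  ae <- match(qe, colnames(relA))
  ar <- match(qr, colnames(relR))
  m <- nrow(a$coords); n <- nrow(b$coords)
  simMat <- matrix(0, n, m)
  okA <- !is.na(ae)
  if (any(okA)) simMat[okA, ] <- t(relA[, ae[okA], drop = FALSE])
  okR <- !is.na(ar)
  if (any(okR)) simMat[okR, ] <- simMat[okR, ] + t(relR[, ar[okR], drop = FALSE])
  bestVec <- apply(relA, 1, max) + apply(relR, 1, max)
  al <- align_impl(b$coords, qe, qr, a$coords, modal_types(a$atom_counts),
                   simMat, bestVec, params)
  if (!al$aligned) {
    return(list(profile = a, dropped = b$members))
  }
  tc <- t(al$rotation %*% t(b$coords) + al$translation)

  elev <- sort(union(colnames(a$atom_counts), colnames(b$atom_counts)))
  rlev <- sort(union(colnames(a$res_counts), colnames(b$res_counts)))
  aAC <- grow_cols(a$atom_counts, elev); bAC <- grow_cols(b$atom_counts, elev)
  aRC <- grow_cols(a$res_counts, rlev); bRC <- grow_cols(b$res_counts, rlev)

  coords <- a$coords
  support <- a$support
  qi <- al$pairs$query; ri <- al$pairs$ref
  wa <- a$support[ri]; wb <- b$support[qi]
  coords[ri, ] <- (coords[ri, , drop = FALSE] * wa + tc[qi, , drop = FALSE] * wb) /
    (wa + wb)
  aAC[ri, ] <- aAC[ri, , drop = FALSE] + bAC[qi, , drop = FALSE]
  aRC[ri, ] <- aRC[ri, , drop = FALSE] + bRC[qi, , drop = FALSE]
  support[ri] <- support[ri] + b$support[qi]

  un <- setdiff(seq_len(n), qi)
  if (length(un) > 0) {
    coords <- rbind(coords, tc[un, , drop = FALSE])
    aAC <- rbind(aAC, bAC[un, , drop = FALSE])
    aRC <- rbind(aRC, bRC[un, , drop = FALSE])
    support <- c(support, b$support[un])
  }
  members <- a$members + b$members
  # lossless look-ahead prune
  rem <- total_members - members
  keep <- (support + rem) / total_members >= params$min_preservation - 1e-9
  list(profile = list(coords = coords[keep, , drop = FALSE],
                      atom_counts = aAC[keep, , drop = FALSE],
                      res_counts = aRC[keep, , drop = FALSE],
                      support = support[keep], members = members,
                      leaves = c(a$leaves, b$leaves)),
       dropped = 0L)
}

# --- operations -------------------------------------------------------------

#' Pairwise combined-score matrix of a pocket set
#'
#' @param pockets List of at least two `pocket` objects.
#' @param params A [scoring_params()] list.
#' @return Symmetric matrix of pairwise combined alignment scores with zero
#'   diagonal.  Pairs with no admissible alignment get `Inf`.
#' @export
pairwise_score_matrix <- function(pockets, params = scoring_params()) {
  params <- as_scoring_params(params)
  n <- length(pockets)
  if (n < 2) stopf("need >= 2 pockets for a pairwise score matrix")
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sc <- align_pockets(pockets[[i]], pockets[[j]], params)$combined_score
      M[i, j] <- M[j, i] <- sc
    }
  }
  M
}

#' Average-linkage guide tree
#'
#' Agglomerative average-linkage clustering with a deterministic tie rule:
#' equal merge distances are resolved in favour of the pair whose clusters
#' contain the smallest leaf indices.  Infinite distances are replaced by
#' twice the largest finite entry (plus one) so that unalignable members
#' merge last.
#'
#' @param dmat Symmetric distance/score matrix.
#' @return List of class `guide_tree` with hclust-style `merge` (negative
#'   entries are leaves) and `height`.
#' @export
guide_tree <- function(dmat) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  if (n < 2 || ncol(dmat) != n) stopf("need a square matrix of size >= 2")
  if (max(abs(dmat - t(dmat)), na.rm = TRUE) > 1e-8)
    stopf("matrix must be symmetric")
  if (any(!is.finite(dmat[upper.tri(dmat)]))) {
    finite <- dmat[upper.tri(dmat)][is.finite(dmat[upper.tri(dmat)])]
    repl <- if (length(finite) > 0) 2 * max(finite) + 1 else 1
    dmat[!is.finite(dmat)] <- repl
  }
  active <- as.list(seq_len(n))          # leaf sets per active cluster
  ids <- -seq_len(n)                     # hclust-style node ids
  sizes <- rep(1L, n)
  D <- dmat
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        d <- D[i, j]
        key <- c(min(active[[i]][1], active[[j]][1]),
                 max(active[[i]][1], active[[j]][1]))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
               (key[1] < best$key[1] ||
                  (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(ids[i], ids[j]))
    height[step] <- best$d
    newrow <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    active <- c(active[keep], list(sort(c(active[[i]], active[[j]]))))
    ids <- c(ids[keep], step)
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
  }
  structure(list(merge = merge, height = height, n = n), class = "guide_tree")
}

#' Progressive profile construction along a guide tree
#'
#' Pockets are merged leaf-to-root; at each internal node the smaller
#' profile is aligned to the larger with signature-alignment semantics,
#' matched positions pool their contributions (support-weighted centroid
#' mean), and unmatched positions are appended.  Members whose merge fails
#' to reach `min_aligned` positions are dropped with a warning and excluded
#' from the preservation denominators.
#'
#' @param pockets List of `pocket` objects (the tree leaves, same order).
#' @param tree A [guide_tree()].
#' @param params A [scoring_params()] list.
#' @return A `position_profiles` list: `positions` data frame (centroid,
#'   preservation, support), `atom_freq` and `res_freq` matrices with
#'   frequencies as fractions of contributing members, and `n_structures`.
#' @export
progressive_profile <- function(pockets, tree, params = scoring_params()) {
  params <- as_scoring_params(params)
  stopifnot(inherits(tree, "guide_tree"), length(pockets) == tree$n)
  total <- length(pockets)
  nodes <- vector("list", nrow(tree$merge))
  get_node <- function(id) {
    if (id < 0) profile_from_pocket(pockets[[-id]], -id) else nodes[[id]]
  }
  dropped <- 0L
  for (s in seq_len(nrow(tree$merge))) {
    a <- get_node(tree$merge[s, 1])
    b <- get_node(tree$merge[s, 2])
    res <- merge_profiles(a, b, params, total)
    dropped <- dropped + res$dropped
    nodes[[s]] <- res$profile
  }
  if (dropped > 0)
    warnf("%d member(s) failed to align during profiling and were dropped",
          dropped)
  prof <- nodes[[nrow(tree$merge)]]
  nm <- prof$members
  ord <- order(-prof$support, seq_along(prof$support))
  positions <- data.frame(
    index = seq_along(ord),
    x = prof$coords[ord, 1], y = prof$coords[ord, 2], z = prof$coords[ord, 3],
    preservation = prof$support[ord] / nm,
    support = as.integer(prof$support[ord])
  )
  structure(list(positions = positions,
                 atom_freq = prof$atom_counts[ord, , drop = FALSE] / nm,
                 res_freq = prof$res_counts[ord, , drop = FALSE] / nm,
                 n_structures = nm),
            class = "position_profiles")
}

#' Prune position profiles into a structural signature
#'
#' Positions preserved in fewer than `min_preservation` of the member
#' structures are dropped.  While more than `max_positions` positions
#' remain, the cutoff is raised in `cutoff_step` increments; if ties prevent
#' getting under the cap, the `max_positions` positions with highest
#' preservation are kept (ties to larger modal atom frequency, then lower
#' index).
#'
#' @param profiles A `position_profiles` object from
#'   [progressive_profile()].
#' @param params A [scoring_params()] list (supplies `min_preservation`,
#'   `max_positions`, `cutoff_step`).
#' @param drug_id,polarity Signature metadata (`polarity` is `"positive"`
#'   or `"negative"`).
#' @return A `structural_signature`.
#' @export
prune_profiles <- function(profiles, params = scoring_params(),
                           drug_id = "drug", polarity = "positive") {
  params <- as_scoring_params(params)
  polarity <- match.arg(polarity, c("positive", "negative"))
  pres <- profiles$positions$preservation
  cutoff <- params$min_preservation
  keep <- which(pres >= cutoff - 1e-9)
  if (length(keep) == 0) stopf("no conserved core: all positions pruned")
  # raise the cutoff stepwise while over the cap; stop short of a step that
  # would empty the signature (ties then resolved by the tie rule below)
  while (length(keep) > params$max_positions &&
           cutoff + params$cutoff_step <= 1 + 1e-9) {
    nxt <- which(pres >= cutoff + params$cutoff_step - 1e-9)
    if (length(nxt) == 0) break
    cutoff <- cutoff + params$cutoff_step
    keep <- nxt
  }
  if (length(keep) > params$max_positions) {
    maf <- apply(profiles$atom_freq[keep, , drop = FALSE], 1, max)
    ord <- order(-pres[keep], -maf, keep)
    keep <- sort(keep[ord[seq_len(params$max_positions)]])
  }
  pos <- profiles$positions[keep, , drop = FALSE]
  pos$index <- seq_len(nrow(pos))
  rownames(pos) <- NULL
  sig <- structure(list(
    drug_id = drug_id, polarity = polarity,
    positions = pos,
    atom_freq = profiles$atom_freq[keep, , drop = FALSE],
    res_freq = profiles$res_freq[keep, , drop = FALSE],
    n_structures = profiles$n_structures,
    preservation_cutoff = cutoff,
    params = unclass(params)
  ), class = "structural_signature")
  validate_signature(sig)
  sig
}

validate_signature <- function(sig) {
  if (is.null(sig$polarity) ||
      !sig$polarity %in% c("positive", "negative"))
    stopf("signature validation: polarity must be 'positive' or 'negative'")
  p <- sig$positions
  if (nrow(p) == 0) stopf("signature validation: no positions")
  if (any(p$preservation < sig$preservation_cutoff - 1e-9))
    stopf("signature validation: position preservation below recorded cutoff %.2f",
          sig$preservation_cutoff)
  if (any(p$preservation > 1 + 1e-9) || any(p$preservation <= 0))
    stopf("signature validation: preservation out of (0, 1]")
  maxp <- sig$params$max_positions %||% 100L
  if (nrow(p) > maxp)
    stopf("signature validation: %d positions exceed the cap %d", nrow(p), maxp)
  if (any(apply(sig$atom_freq, 1, max) <= 0))
    stopf("signature validation: position with empty atom frequency table")
  if (any(sig$atom_freq > p$preservation + 1e-9) ||
      any(sig$res_freq > p$preservation + 1e-9))
    stopf("signature validation: frequency exceeds preservation")
  invisible(sig)
}

signature_coords <- function(signature) {
  as.matrix(signature$positions[, c("x", "y", "z")])
}

signature_similarity_matrix <- function(signature, qe, qr) {
  A <- signature$atom_freq; R <- signature$res_freq
  m <- nrow(A); n <- length(qe)
  ae <- match(qe, colnames(A)); ar <- match(qr, colnames(R))
  simMat <- matrix(0, n, m)
  ok <- !is.na(ae)
  if (any(ok)) simMat[ok, ] <- t(A[, ae[ok], drop = FALSE])
  ok <- !is.na(ar)
  if (any(ok)) simMat[ok, ] <- simMat[ok, , drop = FALSE] + t(R[, ar[ok], drop = FALSE])
  list(simMat = simMat,
       bestVec = apply(A, 1, max) + apply(R, 1, max),
       modal_element = colnames(A)[max.col(A, ties.method = "first")])
}

#' @export
print.structural_signature <- function(x, ...) {
  cat(sprintf("<structural_signature> %s (%s): %d positions from %d structures, preservation >= %.2f\n",
              x$drug_id, x$polarity, nrow(x$positions), x$n_structures,
              x$preservation_cutoff))
  invisible(x)
}

# shared pipeline: pairwise matrix -> tree -> profiles -> prune
build_signature <- function(pockets, params, polarity, drug_id) {
  if (length(pockets) < 2)
    stopf("need >= 2 pockets to build a %s signature", polarity)
  M <- pairwise_score_matrix(pockets, params)
  tree <- guide_tree(M)
  prof <- progressive_profile(pockets, tree, params)
  sig <- prune_profiles(prof, params, drug_id, polarity)
  attr(sig, "score_matrix") <- M
  sig
}

#' Build the positive structural signature
#'
#' Runs the signature pipeline (pairwise sequence-order-independent
#' alignment, average-linkage guide tree, progressive profiling,
#' preservation pruning) over the binding pockets of the known targets.
#'
#' @param binding_pockets List of at least two `pocket` objects, one or
#'   more per positive structure (co-crystal binding pockets and/or
#'   detected pockets).
#' @param params A [scoring_params()] list.
#' @param drug_id Identifier stored in the signature.
#' @return A `structural_signature` with polarity `"positive"`.  The
#'   pairwise score matrix is attached as attribute `"score_matrix"`.
#' @export
build_positive_signature <- function(binding_pockets,
                                     params = scoring_params(),
                                     drug_id = "drug") {
  params <- as_scoring_params(params)
  build_signature(binding_pockets, params, "positive", drug_id)
}

#' Select the negative-signature pocket of a non-target structure
#'
#' Among the structure's top-k largest detected pockets, returns the one
#' most similar to the reference binding pocket (minimum combined alignment
#' score).
#'
#' @param structure A `protein_structure`.
#' @param reference_binding_pocket A `pocket` (typically a positive
#'   binding pocket).
#' @param params A [scoring_params()] list.
#' @param pockets Optional pre-computed pocket list for `structure`.
#' @return A `pocket`, or `NULL` (with a warning) when no pocket aligns.
#' @export
select_negative_pocket <- function(structure, reference_binding_pocket,
                                   params = scoring_params(),
                                   pockets = NULL) {
  params <- as_scoring_params(params)
  pk <- pockets %||% detect_pockets(structure, params)
  pk <- top_pockets(pk, params$top_k_pockets)
  pk <- Filter(function(p) nrow(p$atoms) >= params$min_aligned, pk)
  if (length(pk) == 0) {
    warnf("structure %s has no alignable pocket; skipped", structure$id)
    return(NULL)
  }
  if (length(pk) == 1) return(pk[[1]])
  sc <- vapply(pk, function(p)
    align_pockets(p, reference_binding_pocket, params)$combined_score,
    numeric(1))
  if (all(!is.finite(sc))) {
    warnf("structure %s has no alignable pocket; skipped", structure$id)
    return(NULL)
  }
  pk[[which.min(sc)]]
}

#' Build the negative structural signature
#'
#' For each non-target structure the pocket most similar to the reference
#' binding pocket is selected, and the positive-signature pipeline is then
#' applied to those pockets.
#'
#' @param structures List of `protein_structure` objects (non-targets).
#' @param reference_binding_pocket A `pocket` from the positive set.
#' @param params A [scoring_params()] list.
#' @param drug_id Identifier stored in the signature.
#' @param pockets Optional list (parallel to `structures`) of pre-computed
#'   pocket lists.
#' @return A `structural_signature` with polarity `"negative"`.
#' @export
build_negative_signature <- function(structures, reference_binding_pocket,
                                     params = scoring_params(),
                                     drug_id = "drug", pockets = NULL) {
  params <- as_scoring_params(params)
  sel <- list()
  for (i in seq_along(structures)) {
    p <- select_negative_pocket(structures[[i]], reference_binding_pocket,
                                params,
                                pockets = if (!is.null(pockets)) pockets[[i]])
    if (!is.null(p)) sel[[length(sel) + 1L]] <- p
  }
  if (length(sel) < 2)
    stopf("need >= 2 negative structures with selectable pockets (got %d)",
          length(sel))
  build_signature(sel, params, "negative", drug_id)
}
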