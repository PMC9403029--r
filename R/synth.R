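# Synthetic-structure benchmark generator.  Structures carry a weakly
# conserved pocket motif (per-atom Gaussian noise, positional dropout,
# occasional type perturbation) embedded in a randomised hollow scaffold
# shell, so the motif lines a detectable interior cavity.  The shell is
# deliberately decorrelated across structures (random radius, orientation
# and tangential jitter): scaffold atoms enter individual pockets but do
# not form conserved signature positions.  Everything is deterministic
# under the seed.

MOTIF_ELEMENTS <- c("C", "N", "O", "S")

#' Generate a random pocket motif template
#'
#' Rejection-samples `n_positions` points inside a 10 Angstrom-diameter
#' ball with a minimum inter-position distance of 1.5 Angstrom; elements
#' are drawn from C/N/O/S and residue types from the 20 standard codes.
#'
#' @param n_positions Number of motif positions (>= 8).
#' @param seed Integer seed (same seed, same motif).
#' @param id Motif identifier.
#' @return A `motif_template`: data frame columns x, y, z, element,
#'   residue, plus attributes `id` and `seed`.
#' @export
make_motif <- function(n_positions, seed = 1L, id = "motif") {
  if (n_positions < 8) stopf("a motif needs >= 8 positions")
  radius <- 5.0
  min_dist <- 1.5
  with_local_seed(seed, {
    pts <- matrix(NA_real_, 0, 3)
    tries <- 0L
    while (nrow(pts) < n_positions) {
      tries <- tries + 1L
      if (tries > 100000L) stopf("motif sampling failed (ball too crowded)")
      p <- stats::runif(3, -radius, radius)
      if (sum(p^2) > radius^2) next
      if (nrow(pts) > 0 &&
          min(sqrt(rowSums((pts - matrix(p, nrow(pts), 3, byrow = TRUE))^2))) < min_dist)
        next
      pts <- rbind(pts, p)
    }
    out <- data.frame(
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      element = sample(MOTIF_ELEMENTS, n_positions, replace = TRUE),
      residue = sample(names(AA3TO1), n_positions, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  attr(out, "id") <- id
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("motif_template", "data.frame")
  out
}

#' Embed a motif into a synthetic structure
#'
#' The motif is copied with per-coordinate Gaussian noise, each position is
#' independently deleted with probability `dropout`, element/residue
#' identities are perturbed with probability 0.1, a random rigid transform
#' is applied, and the motif is surrounded by a hollow scaffold shell of
#' alanine-like carbon pseudo-atoms at least 4 Angstrom away, so that the
#' motif lines an enclosed, detectable cavity.  The shell radius,
#' orientation and atom placement are randomised per structure.
#'
#' @param motif A `motif_template`.
#' @param noise_sigma Per-coordinate Gaussian noise SD (Angstrom).
#' @param dropout Per-position deletion probability (in `[0, 0.5)`).
#' @param scaffold_size Approximate scaffold shell radius (Angstrom); the
#'   realised radius is jittered by up to +/- 2 Angstrom per structure.
#' @param seed Integer seed.
#' @param id Structure identifier.
#' @param type_noise Probability of perturbing a motif atom's element and
#'   residue identity.
#' @return A `protein_structure` whose first atoms are the surviving motif
#'   copies; the generating truth (motif row indices, transform) is
#'   attached as attribute `"truth"`.
#' @export
embed_motif <- function(motif, noise_sigma = 0.3, dropout = 0.2,
                        scaffold_size = 12.5, seed = 1L, id = "synth",
                        type_noise = 0.1) {
  if (dropout < 0 || dropout >= 0.5) stopf("dropout must be in [0, 0.5)")
  n <- nrow(motif)
  with_local_seed(seed, {
    keep <- which(stats::runif(n) >= dropout)
    if (length(keep) < 4) keep <- seq_len(min(4, n))   # keep a detectable core
    mc <- as.matrix(motif[keep, c("x", "y", "z")])
    mc <- mc + matrix(stats::rnorm(length(mc), 0, noise_sigma), ncol = 3)
    elem <- motif$element[keep]
    res <- motif$residue[keep]
    flip <- stats::runif(length(keep)) < type_noise
    if (any(flip)) {
      elem[flip] <- sample(MOTIF_ELEMENTS, sum(flip), replace = TRUE)
      res[flip] <- sample(names(AA3TO1), sum(flip), replace = TRUE)
    }

    # hollow shell: spherical Fibonacci lattice, randomly rotated, with a
    # random centre offset and radial/tangential jitter.  The offset and
    # radius jitter decorrelate shells across structures so scaffold atoms
    # do not form conserved positions; spacing ~2.6 A seals the cavity.
    r <- scaffold_size + stats::runif(1, -3, 3)
    centre <- stats::runif(3, -2.5, 2.5)
    K <- max(60L, as.integer(round(4 * pi * r^2 / 7)))
    dirs <- fibonacci_sphere(K) %*% random_rotation()
    dirs <- dirs + matrix(stats::rnorm(3 * K, 0, 0.1), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    shell <- dirs * (r + stats::runif(K, -0.5, 0.5))
    shell <- shell + matrix(centre, K, 3, byrow = TRUE)
    # enforce the 4 A clearance from motif atoms
    ok <- rep(TRUE, K)
    for (i in seq_len(nrow(mc))) {
      d2 <- (shell[, 1] - mc[i, 1])^2 + (shell[, 2] - mc[i, 2])^2 +
        (shell[, 3] - mc[i, 3])^2
      ok <- ok & d2 >= 16
    }
    shell <- shell[ok, , drop = FALSE]

    # random rigid placement of the whole structure
    R <- random_rotation()
    t0 <- stats::runif(3, -10, 10)
    mc_t <- mc %*% t(R) + matrix(t0, nrow(mc), 3, byrow = TRUE)
    shell_t <- shell %*% t(R) + matrix(t0, nrow(shell), 3, byrow = TRUE)

    res3 <- names(AA3TO1)[match(res, names(AA3TO1))]
    na <- nrow(mc_t) + nrow(shell_t)
    atoms <- data.frame(
      serial = seq_len(na),
      atom_name = c(ifelse(elem == "C", "CA", paste0(elem, "1")),
                    rep("CB", nrow(shell_t))),
      element = c(elem, rep("C", nrow(shell_t))),
      residue_name = c(res3, rep("ALA", nrow(shell_t))),
      residue_seq = seq_len(na),
      chain_id = "A",
      x = c(mc_t[, 1], shell_t[, 1]),
      y = c(mc_t[, 2], shell_t[, 2]),
      z = c(mc_t[, 3], shell_t[, 3]),
      is_hetero = FALSE,
      stringsAsFactors = FALSE)
    st <- new_structure(id, atoms)
    attr(st, "truth") <- list(motif_rows = keep, rotation = R,
                              translation = t0, n_motif_atoms = nrow(mc_t))
    st
  })
}

#' Generate a labelled synthetic benchmark
#'
#' Positives embed the positive motif; negatives embed a distinct motif
#' sharing a `confusability` fraction of the positive motif's positions
#' (the rest resampled), emulating non-targets whose pockets resemble the
#' drug-binding pocket to a controllable degree.  Confusability 0 gives
#' well-separated classes; confusability 1 makes them indistinguishable.
#'
#' @param n_pos,n_neg Structures per class (>= 10 recommended for
#'   cross-validation).
#' @param noise_sigma,dropout Per-structure motif noise parameters.
#' @param confusability Fraction of negative-motif positions copied from
#'   the positive motif, in `[0, 1]`.
#' @param seed Master seed; everything (motifs, structures, labels) is
#'   reproducible from it.
#' @param n_motif Motif size (default 14 positions, a realistic pocket lining).
#' @param out_dir Optional directory: writes one PDB per structure plus
#'   `labels.tsv` and `truth.json`.
#' @return A `synthetic_benchmark` list: `structures`, `labels`,
#'   `positive_motif`, `negative_motif`, and the generator settings.
#' @export
make_benchmark <- function(n_pos = 15L, n_neg = 15L, noise_sigma = 0.3,
                           dropout = 0.2, confusability = 0.5, seed = 1L,
                           n_motif = 14L, out_dir = NULL) {
  if (confusability < 0 || confusability > 1)
    stopf("confusability must be in [0, 1]")
  pos_motif <- make_motif(n_motif, seed = sub_seed(seed, 1L), id = "pos")
  neg_motif <- confusable_motif(pos_motif, confusability,
                                seed = sub_seed(seed, 2L))
  structures <- vector("list", n_pos + n_neg)
  labels <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  for (i in seq_len(n_pos + n_neg)) {
    motif <- if (labels[i]) pos_motif else neg_motif
    structures[[i]] <- embed_motif(
      motif, noise_sigma, dropout, seed = sub_seed(seed, 10L + i),
      id = sprintf("%s%02d", if (labels[i]) "pos" else "neg",
                   if (labels[i]) i else i - n_pos))
  }
  bench <- structure(list(
    structures = structures, labels = labels,
    positive_motif = pos_motif, negative_motif = neg_motif,
    noise_sigma = noise_sigma, dropout = dropout,
    confusability = confusability, seed = as.integer(seed)
  ), class = "synthetic_benchmark")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ids <- vapply(structures, `[[`, character(1), "id")
    for (i in seq_along(structures))
      write_structure(structures[[i]], file.path(out_dir, paste0(ids[i], ".pdb")))
    utils::write.table(
      data.frame(id = ids, label = ifelse(labels, "interacting", "non-interacting")),
      file.path(out_dir, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, noise_sigma = noise_sigma, dropout = dropout,
           confusability = confusability,
           positive_motif = as.data.frame(pos_motif),
           negative_motif = as.data.frame(neg_motif)),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  bench
}

# Negative motif at a stated confusability: round(c * n) positions copied
# from the positive motif, the rest resampled under the same constraints.
confusable_motif <- function(pos_motif, confusability, seed) {
  n <- nrow(pos_motif)
  n_copy <- as.integer(round(confusability * n))
  if (n_copy >= n) {
    out <- pos_motif
    attr(out, "id") <- "neg"
    return(out)
  }
  radius <- 5.0
  min_dist <- 1.5
  with_local_seed(seed, {
    keep_rows <- sort(sample(n, n_copy))
    pts <- as.matrix(pos_motif[keep_rows, c("x", "y", "z")])
    tries <- 0L
    while (nrow(pts) < n) {
      tries <- tries + 1L
      if (tries > 100000L) stopf("motif resampling failed")
      p <- stats::runif(3, -radius, radius)
      if (sum(p^2) > radius^2) next
      if (nrow(pts) > 0 &&
          min(sqrt(rowSums((pts - matrix(p, nrow(pts), 3, byrow = TRUE))^2))) < min_dist)
        next
      pts <- rbind(pts, p)
    }
    n_new <- n - n_copy
    out <- data.frame(
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      element = c(pos_motif$element[keep_rows],
                  sample(MOTIF_ELEMENTS, n_new, replace = TRUE)),
      residue = c(pos_motif$residue[keep_rows],
                  sample(names(AA3TO1), n_new, replace = TRUE)),
      stringsAsFactors = FALSE)
  })
  attr(out, "id") <- "neg"
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("motif_template", "data.frame")
  out
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf("<synthetic_benchmark> %d positives + %d negatives (sigma=%g, dropout=%g, confusability=%g, seed=%d)\n",
              sum(x$labels), sum(!x$labels), x$noise_sigma, x$dropout,
              x$confusability, x$seed))
  invisible(x)
}
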