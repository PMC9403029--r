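# Independent oracles.  These deliberately re-implement the mathematics in
# plain R, separate from the package's C++ search, so that the dual-route
# checks stay meaningful.

# Kabsch superposition via base-R svd.
oracle_kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Pt <- Pc %*% t(R)
  list(R = R, t = qbar - as.numeric(R %*% pbar),
       rmsd = sqrt(mean(rowSums((Pt - Qc)^2))))
}

# all permutations of 1..n (tiny n only)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(c(seq_len(n)[-k])[sub], nrow(sub)))
  }))
}

# Brute-force sequence-order-independent alignment of two tiny pockets:
# enumerate every subset of >= min_aligned query atoms and every injective
# assignment to reference atoms, Kabsch-superpose, require all matched
# distances <= match_distance, and score with the indicator (one-member
# profile) frequencies.  Returns the minimal combined score (Inf if none).
oracle_align_score <- function(qp, rp, params) {
  qxyz <- as.matrix(qp$atoms[, c("x", "y", "z")])
  rxyz <- as.matrix(rp$atoms[, c("x", "y", "z")])
  nq <- nrow(qxyz); nr <- nrow(rxyz)
  best <- Inf
  if (params$min_aligned > min(nq, nr)) return(best)
  for (k in params$min_aligned:min(nq, nr)) {
    qsub <- utils::combn(nq, k)
    rsub <- utils::combn(nr, k)
    pm <- perms(k)
    for (a in seq_len(ncol(qsub))) {
      qi <- qsub[, a]
      for (b in seq_len(ncol(rsub))) {
        rj <- rsub[, b]
        for (p in seq_len(nrow(pm))) {
          ri <- rj[pm[p, ]]
          kb <- oracle_kabsch(qxyz[qi, , drop = FALSE], rxyz[ri, , drop = FALSE])
          Pt <- sweep(qxyz[qi, , drop = FALSE], 2, colMeans(qxyz[qi, , drop = FALSE])) %*% t(kb$R)
          Pt <- sweep(Pt, 2, -colMeans(rxyz[ri, , drop = FALSE]))
          d <- sqrt(rowSums((Pt - rxyz[ri, , drop = FALSE])^2))
          if (any(d > params$match_distance + 1e-12)) next
          sim <- sum(qp$atoms$element[qi] == rp$atoms$element[ri]) +
            sum(qp$atoms$residue[qi] == rp$atoms$residue[ri])
          seqsc <- 1 - sim / (2 * k)
          sc <- kb$rmsd * k^(-1 / 3) + params$alpha * seqsc
          if (sc < best) best <- sc
        }
      }
    }
  }
  best
}

# Flood-fill cavity oracle: voxels within vdw+probe of an atom are
# excluded; empty voxels not reachable from the box boundary (through any
# empty voxel, burial ignored) are enclosed cavity voxels.  Returns sorted
# cavity component volumes (in voxels).
oracle_enclosed_volumes <- function(structure, spacing = 1.0,
                                    probe = 1.4, vdw = 1.7, margin = 2.0) {
  idx <- pocketsig:::heavy_atom_indices(structure)
  xyz <- as.matrix(structure$atoms[idx, c("x", "y", "z")])
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- as.integer(floor((hi - lo) / spacing)) + 1L
  gx <- lo[1] + (seq_len(dims[1]) - 1) * spacing
  gy <- lo[2] + (seq_len(dims[2]) - 1) * spacing
  gz <- lo[3] + (seq_len(dims[3]) - 1) * spacing
  G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  rex2 <- (vdw + probe)^2
  excluded <- rep(FALSE, nrow(G))
  for (a in seq_len(nrow(xyz))) {
    d2 <- (G[, 1] - xyz[a, 1])^2 + (G[, 2] - xyz[a, 2])^2 + (G[, 3] - xyz[a, 3])^2
    excluded <- excluded | d2 <= rex2
  }
  arr <- array(excluded, dim = dims)
  lab <- array(0L, dim = dims)
  # BFS from all boundary empty voxels
  q <- which(!arr &
               (slice.index(arr, 1) %in% c(1, dims[1]) |
                  slice.index(arr, 2) %in% c(1, dims[2]) |
                  slice.index(arr, 3) %in% c(1, dims[3])))
  lab[q] <- 1L
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  offs <- c(-1, 1, -nx, nx, -nx * ny, nx * ny)
  while (length(q) > 0) {
    i <- (q - 1) %% nx; j <- ((q - 1) %/% nx) %% ny; k <- (q - 1) %/% (nx * ny)
    nxt <- integer(0)
    for (o in 1:6) {
      valid <- switch(o, i > 0, i < nx - 1, j > 0, j < ny - 1, k > 0, k < nz - 1)
      nb <- q[valid] + offs[o]
      nxt <- c(nxt, nb[!arr[nb] & lab[nb] == 0L])
    }
    nxt <- unique(nxt)
    lab[nxt] <- 1L
    q <- nxt
  }
  enclosed <- which(!arr & lab == 0L)
  if (length(enclosed) == 0) return(numeric(0))
  # connected components of the enclosed voxels
  comp <- integer(length(arr))
  sizes <- integer(0)
  for (v in enclosed) {
    if (comp[v] != 0L) next
    id <- length(sizes) + 1L
    q <- v; comp[v] <- id; size <- 0L
    while (length(q) > 0) {
      size <- size + length(q)
      i <- (q - 1) %% nx; j <- ((q - 1) %/% nx) %% ny; k <- (q - 1) %/% (nx * ny)
      nxt <- integer(0)
      for (o in 1:6) {
        valid <- switch(o, i > 0, i < nx - 1, j > 0, j < ny - 1, k > 0, k < nz - 1)
        nb <- q[valid] + offs[o]
        nb <- nb[!arr[nb] & lab[nb] == 0L & comp[nb] == 0L]
        nxt <- c(nxt, nb)
      }
      nxt <- unique(nxt)
      comp[nxt] <- id
      q <- nxt
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# Independent Needleman-Wunsch (affine gaps, BLOSUM62) returning aligned
# strings; used as the oracle for the Biostrings-backed baseline.
oracle_nw <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  A <- strsplit(a, "")[[1]]; Bs <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(Bs)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 2) * gap_ext
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 2) * gap_ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- B[A[i - 1], Bs[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open, X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}
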