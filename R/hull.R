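# Convex-hull volume of a 3D point set, used as the fallback volume
# estimate for binding pockets when no cavity voxels are available.
#
# Faces are found by the O(n^4) supporting-plane test (every triplet whose
# plane has all points on one side).  A tiny deterministic jitter breaks
# exact coplanarity so that coplanar facets do not get double-counted; the
# induced volume error is far below any use of this quantity (pocket size
# ranking).
convex_hull_volume <- function(points) {
  pts <- as.matrix(points)
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 4) return(0)
  s <- svd(scale(pts, scale = FALSE))$d
  if (s[3] < 1e-8 * max(s[1], 1)) return(0)  # degenerate (planar/collinear)
  jit <- 1e-6 * max(1, max(abs(pts)))
  set <- seq_len(n)
  pts <- pts + jit * sin(outer(set, 1:3, function(i, j) i * j * 2.399963))
  cen <- colMeans(pts)
  tri <- utils::combn(n, 3)
  vol <- 0
  for (k in seq_len(ncol(tri))) {
    i <- tri[1, k]; j <- tri[2, k]; l <- tri[3, k]
    p1 <- pts[i, ]; e1 <- pts[j, ] - p1; e2 <- pts[l, ] - p1
    nv <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    nn <- sqrt(sum(nv^2))
    if (nn < 1e-10) next
    d <- (pts[-c(i, j, l), , drop = FALSE] %*% nv - sum(nv * p1)) / nn
    if (all(d <= 1e-9) || all(d >= -1e-9)) {
      # hull face: tetrahedron against the centroid
      vol <- vol + abs(sum(nv * (p1 - cen))) / 6
    }
  }
  vol
}
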