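# Pocket detection: a grid-based cavity finder standing in for alpha-shape
# pocket servers.  Voxels within (vdW + probe) of a heavy atom are solvent
# excluded; remaining empty voxels are flooded from the box boundary through
# "open" (low-burial) space, and whatever empty space cannot be reached that
# way forms the cavities.  Exact alpha-shape volume equivalence is a
# non-goal; the finder reproduces "largest pockets" semantics.

new_pocket <- function(structure, atom_indices, volume, rank,
                       centroid = NULL, n_voxels = NA_integer_,
                       voxel_centers = NULL) {
  stopifnot(length(atom_indices) > 0, !anyDuplicated(atom_indices))
  a <- structure$atoms[atom_indices, , drop = FALSE]
  atoms <- data.frame(
    element = a$element, residue_name = a$residue_name,
    residue = aa_three_to_one(a$residue_name),
    x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE
  )
  if (is.null(centroid)) centroid <- colMeans(as.matrix(atoms[, c("x", "y", "z")]))
  structure(list(
    structure_id = structure$id,
    atom_indices = as.integer(atom_indices),
    atom_serials = a$serial,
    atoms = atoms,
    volume = volume, rank = as.integer(rank),
    centroid = as.numeric(centroid),
    n_voxels = n_voxels, voxel_centers = voxel_centers
  ), class = "pocket")
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("<pocket> %s rank %d: %d atoms, volume %.1f A^3\n",
              x$structure_id, x$rank, nrow(x$atoms), x$volume))
  invisible(x)
}

pocket_coords <- function(pocket) {
  as.matrix(pocket$atoms[, c("x", "y", "z")])
}

#' Detect surface pockets and interior cavities of a structure
#'
#' Grid-based cavity detection over the heavy, non-hetero atoms.  A voxel is
#' solvent-excluded when its centre lies within `vdw_radius + probe_radius`
#' of a heavy atom.  Empty voxels reachable from the box boundary through
#' low-burial space are open solvent; the remaining empty voxels form
#' cavities (6-connected components).  A voxel counts as buried when at
#' least `burial_threshold` of `burial_rays` rays of length
#' `burial_ray_length` hit protein.  Each pocket's atoms are the heavy atoms
#' within `contact_cutoff` of its voxels (capped at `max_pocket_atoms`,
#' ranked by cavity contact); pockets with fewer than `min_pocket_atoms`
#' lining atoms are discarded.  Volume is voxel count times spacing cubed.
#' Deterministic for fixed inputs.
#'
#' @param structure A `protein_structure` with at least 20 heavy atoms.
#' @param params A [scoring_params()] list.
#' @param grid_spacing,probe_radius Optional overrides of the corresponding
#'   `params` entries (Angstrom).
#' @return List of `pocket` objects sorted by decreasing volume, with ranks
#'   1..k.  Degenerate (collinear) geometry yields an empty list with a
#'   warning.
#' @export
detect_pockets <- function(structure, params = scoring_params(),
                           grid_spacing = NULL, probe_radius = NULL) {
  params <- as_scoring_params(params)
  s <- grid_spacing %||% params$grid_spacing
  probe <- probe_radius %||% params$probe_radius
  idx <- heavy_atom_indices(structure)
  if (length(idx) < 20)
    stopf("pocket detection needs >= 20 heavy atoms (found %d)", length(idx))
  xyz <- as.matrix(structure$atoms[idx, c("x", "y", "z")])
  sv <- svd(scale(xyz, scale = FALSE))$d
  if (sv[2] < 1e-6 * max(sv[1], 1)) {
    warnf("degenerate (collinear) geometry in %s; no pockets", structure$id)
    return(list())
  }

  margin <- 2.0
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  dims <- pmax(as.integer(floor((hi - lo) / s)) + 1L, 3L)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nvox <- nx * ny * nz

  # solvent-excluded occupancy
  rex <- params$vdw_radius + probe
  excluded <- rep(FALSE, nvox)
  ax <- (xyz[, 1] - lo[1]) / s; ay <- (xyz[, 2] - lo[2]) / s; az <- (xyz[, 3] - lo[3]) / s
  reach <- ceiling(rex / s)
  for (a in seq_len(nrow(xyz))) {
    ir <- max(0L, floor(ax[a]) - reach):min(nx - 1L, ceiling(ax[a]) + reach)
    jr <- max(0L, floor(ay[a]) - reach):min(ny - 1L, ceiling(ay[a]) + reach)
    kr <- max(0L, floor(az[a]) - reach):min(nz - 1L, ceiling(az[a]) + reach)
    dx2 <- (ir - ax[a])^2; dy2 <- (jr - ay[a])^2; dz2 <- (kr - az[a])^2
    within <- outer(outer(dx2, dy2, "+"), dz2, "+") <= (rex / s)^2
    if (!any(within)) next
    w <- which(within, arr.ind = TRUE)
    lin <- (ir[w[, 1]]) + nx * (jr[w[, 2]]) + nx * ny * (kr[w[, 3]]) + 1L
    excluded[lin] <- TRUE
  }

  empty <- which(!excluded)
  if (length(empty) == 0) return(list())
  ei <- (empty - 1L) %% nx
  ej <- ((empty - 1L) %/% nx) %% ny
  ek <- (empty - 1L) %/% (nx * ny)

  # burial: fraction of rays (voxel-space lookups along 32 directions) that
  # hit the solvent-excluded region within the ray length
  dirs <- fibonacci_sphere(params$burial_rays)
  steps <- seq(s, params$burial_ray_length, by = s)
  offs <- do.call(rbind, lapply(seq_len(nrow(dirs)), function(d) {
    o <- unique(round(outer(steps / s, dirs[d, ])))
    cbind(d, o)
  }))
  storage.mode(offs) <- "integer"
  hits <- .burial_counts_cpp(excluded, c(nx, ny, nz), empty, offs)
  buried <- hits / nrow(dirs) >= params$burial_threshold

  # flood open solvent from the box boundary through low-burial empty space
  allowed <- rep(FALSE, nvox)
  allowed[empty[!buried]] <- TRUE
  on_boundary <- ei == 0L | ei == nx - 1L | ej == 0L | ej == ny - 1L |
    ek == 0L | ek == nz - 1L
  frontier <- empty[on_boundary & !buried]
  reached <- rep(FALSE, nvox)
  reached[frontier] <- TRUE
  offsets <- c(-1L, 1L, -nx, nx, -nx * ny, nx * ny)
  while (length(frontier) > 0) {
    fi <- (frontier - 1L) %% nx
    fj <- ((frontier - 1L) %/% nx) %% ny
    fk <- (frontier - 1L) %/% (nx * ny)
    nbrs <- integer(0)
    for (o in 1:6) {
      valid <- switch(o,
        fi > 0L, fi < nx - 1L, fj > 0L, fj < ny - 1L, fk > 0L, fk < nz - 1L)
      nb <- frontier[valid] + offsets[o]
      nbrs <- c(nbrs, nb[allowed[nb] & !reached[nb]])
    }
    nbrs <- unique(nbrs)
    reached[nbrs] <- TRUE
    frontier <- nbrs
  }

  pocketvox <- empty[!reached[empty]]
  if (length(pocketvox) == 0) return(list())

  # 6-connected components of the pocket voxels
  inpocket <- rep(FALSE, nvox)
  inpocket[pocketvox] <- TRUE
  comp <- rep(0L, nvox)
  ncomp <- 0L
  for (v in pocketvox) {
    if (comp[v] != 0L) next
    ncomp <- ncomp + 1L
    frontier <- v
    comp[v] <- ncomp
    while (length(frontier) > 0) {
      fi <- (frontier - 1L) %% nx
      fj <- ((frontier - 1L) %/% nx) %% ny
      fk <- (frontier - 1L) %/% (nx * ny)
      nbrs <- integer(0)
      for (o in 1:6) {
        valid <- switch(o,
          fi > 0L, fi < nx - 1L, fj > 0L, fj < ny - 1L, fk > 0L, fk < nz - 1L)
        nb <- frontier[valid] + offsets[o]
        nbrs <- c(nbrs, nb[inpocket[nb] & comp[nb] == 0L])
      }
      nbrs <- unique(nbrs)
      comp[nbrs] <- ncomp
      frontier <- nbrs
    }
  }

  vox_center <- function(v) {
    cbind(lo[1] + ((v - 1L) %% nx) * s,
          lo[2] + (((v - 1L) %/% nx) %% ny) * s,
          lo[3] + ((v - 1L) %/% (nx * ny)) * s)
  }

  pockets <- list()
  for (cid in seq_len(ncomp)) {
    vv <- pocketvox[comp[pocketvox] == cid]
    if (length(vv) * s^3 < params$min_pocket_volume) next
    V <- vox_center(vv)
    # cavity-contact count per heavy atom (vectorised over voxels)
    cc2 <- params$contact_cutoff^2
    counts <- integer(nrow(xyz))
    for (a in seq_len(nrow(xyz))) {
      d2 <- (V[, 1] - xyz[a, 1])^2 + (V[, 2] - xyz[a, 2])^2 + (V[, 3] - xyz[a, 3])^2
      counts[a] <- sum(d2 <= cc2)
    }
    lining <- which(counts > 0L)
    if (length(lining) < params$min_pocket_atoms) next
    centroid <- colMeans(V)
    if (length(lining) > params$max_pocket_atoms) {
      dcen <- sqrt(rowSums((xyz[lining, , drop = FALSE] -
                              matrix(centroid, length(lining), 3, byrow = TRUE))^2))
      ord <- order(-counts[lining], dcen, lining)
      lining <- lining[ord[seq_len(params$max_pocket_atoms)]]
      lining <- sort(lining)
    }
    pockets[[length(pockets) + 1L]] <- list(
      atom_indices = idx[lining], volume = length(vv) * s^3,
      centroid = centroid, n_voxels = length(vv), voxel_centers = V,
      first_vox = min(vv)
    )
  }
  if (length(pockets) == 0) return(list())
  ord <- order(-vapply(pockets, `[[`, numeric(1), "volume"),
               vapply(pockets, `[[`, numeric(1), "first_vox"))
  pockets <- pockets[ord]
  lapply(seq_along(pockets), function(r) {
    p <- pockets[[r]]
    new_pocket(structure, p$atom_indices, p$volume, r, p$centroid,
               p$n_voxels, p$voxel_centers)
  })
}

#' Extract the binding pocket of a co-crystal structure
#'
#' The binding pocket is the set of heavy protein atoms within
#' `contact_cutoff` of any heavy atom of the named ligand.  Volume is taken
#' from the detected cavity voxels near those atoms when available,
#' otherwise from the convex hull of the pocket atoms.
#'
#' @param structure A `protein_structure` containing the ligand as a hetero
#'   group.
#' @param ligand_code Residue name of the ligand (e.g. `"STI"`).
#' @param contact_cutoff Heavy-atom contact distance in Angstrom.
#' @param params A [scoring_params()] list.
#' @return A `pocket` (rank 1).
#' @export
binding_pocket <- function(structure, ligand_code,
                           contact_cutoff = NULL,
                           params = scoring_params()) {
  params <- as_scoring_params(params)
  cutoff <- contact_cutoff %||% params$contact_cutoff
  a <- structure$atoms
  lig_rows <- which(a$is_hetero & a$residue_name == toupper(ligand_code) &
                      !(a$element %in% c("H", "D")))
  if (length(lig_rows) == 0) {
    codes <- unique(a$residue_name[a$is_hetero])
    stopf("ligand '%s' not found; hetero codes present: %s", ligand_code,
          if (length(codes)) paste(codes, collapse = ", ") else "(none)")
  }
  lig <- as.matrix(a[lig_rows, c("x", "y", "z")])
  idx <- heavy_atom_indices(structure)
  xyz <- as.matrix(a[idx, c("x", "y", "z")])
  mind2 <- rep(Inf, nrow(xyz))
  for (r in seq_len(nrow(lig))) {
    d2 <- (xyz[, 1] - lig[r, 1])^2 + (xyz[, 2] - lig[r, 2])^2 +
      (xyz[, 3] - lig[r, 3])^2
    mind2 <- pmin(mind2, d2)
  }
  sel <- which(mind2 <= cutoff^2)
  if (length(sel) == 0) stopf("empty binding pocket at cutoff %.2f A", cutoff)
  atom_indices <- idx[sel]

  vol <- NA_real_
  nvox <- NA_integer_
  pk <- tryCatch(detect_pockets(structure, params),
                 error = function(e) list(), warning = function(w) list())
  if (length(pk) > 0) {
    pxyz <- xyz[sel, , drop = FALSE]
    nv <- 0L
    for (p in pk) {
      V <- p$voxel_centers
      if (is.null(V)) next
      keep <- rep(FALSE, nrow(V))
      for (r in seq_len(nrow(pxyz))) {
        d2 <- (V[, 1] - pxyz[r, 1])^2 + (V[, 2] - pxyz[r, 2])^2 +
          (V[, 3] - pxyz[r, 3])^2
        keep <- keep | d2 <= cutoff^2
      }
      nv <- nv + sum(keep)
    }
    if (nv > 0) { vol <- nv * params$grid_spacing^3; nvox <- nv }
  }
  if (is.na(vol)) {
    vol <- convex_hull_volume(xyz[sel, , drop = FALSE])
    nvox <- NA_integer_
  }
  new_pocket(structure, atom_indices, vol, 1L, n_voxels = nvox)
}

#' Keep the top-k pockets by rank
#'
#' @param pockets List of pockets sorted by rank.
#' @param k Number to keep (`k >= 1`); fewer are returned without error if
#'   fewer exist.
#' @return List of at most `k` pockets, ranks preserved.
#' @export
top_pockets <- function(pockets, k) {
  if (k < 1) stopf("k must be >= 1")
  if (length(pockets) == 0) return(list())
  ranks <- vapply(pockets, `[[`, integer(1), "rank")
  pockets[order(ranks)][seq_len(min(k, length(pockets)))]
}
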