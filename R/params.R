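#' Scoring and pipeline parameters
#'
#' Bundles every tunable parameter of the pocket-signature pipeline into a
#' single validated list.  The defaults encode the published operating point
#' of the method: score weight `alpha = 1.2`, signature positions preserved
#' in at least 50% of member structures, at most 100 signature positions,
#' the 0.85 positive-only score cutoff, the top 3 largest pockets per query,
#' and 100 random docking scores for empirical significance.
#'
#' @param alpha Weight of the sequence score in the combined score
#'   (`Score = StructuralScore + alpha * SequenceScore`).  Must be > 0.
#' @param match_distance Maximum post-superposition distance (in Angstrom)
#'   for an atom/position correspondence to be accepted.
#' @param min_aligned Minimum number of aligned positions for an alignment
#'   to count; below this an alignment is reported as "no alignment" with
#'   infinite score.  Must be >= 3.
#' @param positive_only_cutoff Score threshold for positive-signature-only
#'   classification (a protein is called a target when its best positive
#'   score is strictly below this cutoff).
#' @param top_k_pockets Number of largest pockets scored per query protein.
#' @param n_random_significance Minimum number of random-structure docking
#'   scores required by [empirical_significance()] validation helpers.
#' @param seed Integer seed used by stochastic helpers unless overridden.
#' @param min_preservation Baseline preservation-ratio cutoff for signature
#'   positions (fraction of member structures contributing an atom).
#' @param max_positions Cap on the number of signature positions; the
#'   preservation cutoff is raised in `cutoff_step` increments until the
#'   signature fits.
#' @param cutoff_step Increment used when raising the preservation cutoff.
#' @param grid_spacing Pocket-finder grid spacing (Angstrom).
#' @param probe_radius Solvent probe radius (Angstrom).
#' @param vdw_radius Uniform heavy-atom van der Waals radius (Angstrom).
#' @param burial_threshold Fraction of rays that must hit protein for a grid
#'   voxel to count as buried.
#' @param burial_rays Number of uniformly distributed rays per voxel.
#' @param burial_ray_length Ray length (Angstrom) for the burial test.
#' @param contact_cutoff Heavy-atom contact distance (Angstrom) used both to
#'   collect pocket-lining atoms and for binding-pocket extraction.
#' @param min_pocket_atoms Detected pockets with fewer lining atoms are
#'   discarded (they cannot support an alignment).
#' @param min_pocket_volume Minimum pocket volume in cubic Angstrom;
#'   smaller cavities are grid noise and are discarded.
#' @param max_pocket_atoms Detected pockets keep at most this many lining
#'   atoms (ranked by cavity contact, see [detect_pockets()]).
#' @param max_seed_pairs Maximum number of triangle seed pairs explored per
#'   alignment.
#' @param max_iter Maximum matching/superposition iterations per seed.
#' @param exhaustive_limit Pockets with at most this many atoms on both
#'   sides are aligned by exhaustive correspondence enumeration.
#' @param tie_tol Combined-score tolerance under which candidate alignments
#'   are treated as tied (ties go to larger N, then lexicographic order).
#' @param max_polish Number of top candidate alignments refined with optimal
#'   bipartite assignment.
#'
#' @return A named list of class `scoring_params`.
#' @export
scoring_params <- function(alpha = 1.2,
                           match_distance = 2.0,
                           min_aligned = 8L,
                           positive_only_cutoff = 0.85,
                           top_k_pockets = 3L,
                           n_random_significance = 100L,
                           seed = 1L,
                           min_preservation = 0.5,
                           max_positions = 100L,
                           cutoff_step = 0.05,
                           grid_spacing = 1.0,
                           probe_radius = 1.4,
                           vdw_radius = 1.7,
                           burial_threshold = 0.55,
                           burial_rays = 32L,
                           burial_ray_length = 8.0,
                           contact_cutoff = 4.5,
                           min_pocket_atoms = 8L,
                           min_pocket_volume = 50,
                           max_pocket_atoms = 30L,
                           max_seed_pairs = 48L,
                           max_iter = 12L,
                           exhaustive_limit = 7L,
                           tie_tol = 1e-9,
                           max_polish = 8L) {
  p <- list(
    alpha = alpha, match_distance = match_distance,
    min_aligned = as.integer(min_aligned),
    positive_only_cutoff = positive_only_cutoff,
    top_k_pockets = as.integer(top_k_pockets),
    n_random_significance = as.integer(n_random_significance),
    seed = as.integer(seed),
    min_preservation = min_preservation,
    max_positions = as.integer(max_positions),
    cutoff_step = cutoff_step,
    grid_spacing = grid_spacing, probe_radius = probe_radius,
    vdw_radius = vdw_radius, burial_threshold = burial_threshold,
    burial_rays = as.integer(burial_rays),
    burial_ray_length = burial_ray_length,
    contact_cutoff = contact_cutoff,
    min_pocket_atoms = as.integer(min_pocket_atoms),
    min_pocket_volume = min_pocket_volume,
    max_pocket_atoms = as.integer(max_pocket_atoms),
    max_seed_pairs = as.integer(max_seed_pairs),
    max_iter = as.integer(max_iter),
    exhaustive_limit = as.integer(exhaustive_limit),
    tie_tol = tie_tol, max_polish = as.integer(max_polish)
  )
  if (!is.numeric(p$alpha) || p$alpha <= 0) stopf("alpha must be > 0")
  if (p$match_distance <= 0) stopf("match_distance must be > 0")
  if (p$min_aligned < 3L) stopf("min_aligned must be >= 3")
  if (p$top_k_pockets < 1L) stopf("top_k_pockets must be >= 1")
  if (p$min_preservation <= 0 || p$min_preservation > 1)
    stopf("min_preservation must be in (0, 1]")
  if (p$grid_spacing <= 0) stopf("grid_spacing must be > 0")
  class(p) <- "scoring_params"
  p
}

as_scoring_params <- function(params) {
  if (is.null(params)) return(scoring_params())
  if (inherits(params, "scoring_params")) return(params)
  do.call(scoring_params, params)
}

#' @export
print.scoring_params <- function(x, ...) {
  cat("<scoring_params>\n")
  cat(sprintf("  alpha=%g  match_distance=%g A  min_aligned=%d\n",
              x$alpha, x$match_distance, x$min_aligned))
  cat(sprintf("  positive_only_cutoff=%g  top_k_pockets=%d\n",
              x$positive_only_cutoff, x$top_k_pockets))
  cat(sprintf("  preservation >= %g (cap %d positions, step %g)\n",
              x$min_preservation, x$max_positions, x$cutoff_step))
  invisible(x)
}
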