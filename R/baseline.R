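# Sequence-similarity nearest-neighbour baseline and identity-based
# redundancy reduction.  Global alignments use Needleman-Wunsch with
# BLOSUM62, gap opening 10 and gap extension 0.5 (community defaults; the
# method itself prescribes none), via Biostrings.

global_alignment_strings <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  list(p = strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]],
       s = strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]])
}

#' Global pairwise sequence similarity and identity
#'
#' `global_similarity()` is the fraction of aligned positions whose
#' substitution score is positive; `global_identity()` is the fraction of
#' identical aligned positions.  Both are normalised by the length of the
#' shorter sequence, so values lie in `[0, 1]` and fragments are penalised
#' symmetrically.
#'
#' @param seq_a,seq_b Non-empty 1-letter amino-acid strings.
#' @return Fraction in `[0, 1]`.
#' @export
global_similarity <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0)
    stopf("sequences must be non-empty")
  al <- global_alignment_strings(seq_a, seq_b)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  ok <- al$p != "-" & al$s != "-" & al$p %in% rownames(B) & al$s %in% colnames(B)
  pos <- sum(B[cbind(al$p[ok], al$s[ok])] > 0)
  pos / min(nchar(seq_a), nchar(seq_b))
}

#' @rdname global_similarity
#' @export
global_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0)
    stopf("sequences must be non-empty")
  al <- global_alignment_strings(seq_a, seq_b)
  ok <- al$p != "-" & al$s != "-"
  sum(al$p[ok] == al$s[ok]) / min(nchar(seq_a), nchar(seq_b))
}

#' Leave-one-out nearest-neighbour label assignment
#'
#' Each left-out protein is assigned the label of the protein with the
#' strictly maximal global sequence similarity to it, provided that
#' similarity exceeds the cutoff (strict `> cutoff`); ties at the maximum
#' or maxima at or below the cutoff leave the protein unassigned.
#' Evaluation is reported both over the assigned subset and over all
#' proteins (unassigned counted as misclassified).
#'
#' @param sequences Named character vector of 1-letter sequences
#'   (at least two).
#' @param labels Logical vector (`TRUE` = interacting), same length; both
#'   labels must be present.
#' @param cutoff Similarity cutoff (default 0.6).
#' @param sim_matrix Optional pre-computed symmetric similarity matrix.
#' @return List with `assignments` (data frame: id, label, assigned,
#'   nn_id, similarity), `assigned_fraction`, `eval_assigned` and
#'   `eval_all` (`eval_result`s).
#' @export
loo_assign <- function(sequences, labels, cutoff = 0.6, sim_matrix = NULL) {
  n <- length(sequences)
  labels <- as.logical(labels)
  if (n < 2 || length(labels) != n)
    stopf("need >= 2 labelled sequences")
  if (!any(labels) || all(labels))
    stopf("both labels must be present")
  ids <- names(sequences) %||% paste0("seq", seq_len(n))
  S <- sim_matrix
  if (is.null(S)) {
    S <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        S[i, j] <- S[j, i] <- global_similarity(sequences[[i]], sequences[[j]])
      }
    }
  }
  diag(S) <- -Inf
  assigned <- logical(n)
  nn_id <- rep(NA_character_, n)
  nn_sim <- rep(NA_real_, n)
  pred <- rep(NA, n)
  for (i in seq_len(n)) {
    best <- max(S[i, ])
    nn_sim[i] <- best
    if (best <= cutoff) next                        # strict > cutoff required
    winners <- which(S[i, ] >= best - 1e-12)
    if (length(winners) > 1) next                   # tied maximum
    assigned[i] <- TRUE
    nn_id[i] <- ids[winners]
    pred[i] <- labels[winners]
  }
  assignments <- data.frame(
    id = ids, label = labels, assigned = assigned,
    predicted = pred, nn_id = nn_id, similarity = nn_sim,
    stringsAsFactors = FALSE)
  eval_assigned <- if (any(assigned))
    evaluate(pred[assigned], labels[assigned]) else NULL
  pred_all <- ifelse(is.na(pred), !labels, pred)    # unassigned = wrong
  list(assignments = assignments,
       assigned_fraction = mean(assigned),
       eval_assigned = eval_assigned,
       eval_all = evaluate(as.logical(pred_all), labels))
}

#' Identity-based redundancy reduction
#'
#' Greedy representative selection: mandatory sequences are kept first
#' (regardless of identity), then the remaining sequences are visited in
#' decreasing length order and kept only if their global identity to every
#' kept sequence is below the cutoff.
#'
#' @param sequences Named character vector.
#' @param identity_cutoff Identity cutoff in `(0, 1]` (e.g. 0.7 for the
#'   positive set, 0.6 for the negative set).
#' @param mandatory_ids Ids always kept (e.g. co-crystallised structures).
#' @return Character vector of kept ids.
#' @export
reduce_redundancy <- function(sequences, identity_cutoff,
                              mandatory_ids = character(0)) {
  if (identity_cutoff <= 0 || identity_cutoff > 1)
    stopf("identity_cutoff must be in (0, 1]")
  ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
  names(sequences) <- ids
  kept <- intersect(ids, mandatory_ids)
  rest <- setdiff(ids, kept)
  rest <- rest[order(-nchar(sequences[rest]), rest)]
  for (id in rest) {
    ok <- TRUE
    for (k in kept) {
      if (global_identity(sequences[[id]], sequences[[k]]) >= identity_cutoff) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, id)
  }
  kept
}
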