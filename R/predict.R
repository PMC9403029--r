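# Target prediction: score query proteins against the positive and negative
# signatures, apply the score-difference decision rule, rank with external
# docking scores, and evaluate with cross-validation.

#' Score a query protein against both signatures
#'
#' Each of the query's top-k largest pockets is aligned to the positive and
#' negative signatures; the score difference `delta = score_pos - score_neg`
#' is computed on the same pocket, and the pocket with the minimum delta is
#' reported.  The protein is predicted as a target when that delta is
#' strictly negative.  Unalignable pockets get infinite scores; when no
#' pocket aligns the prediction is a non-target with a `+Inf` delta
#' sentinel.
#'
#' @param structure A `protein_structure`.
#' @param pos_sig,neg_sig Positive and negative `structural_signature`s.
#' @param params A [scoring_params()] list.
#' @param pockets Optional pre-computed pocket list for `structure`.
#' @return One-row data frame with columns id, pocket_rank, score_pos,
#'   score_neg, delta, predicted, docking_score, significance.
#' @export
score_protein <- function(structure, pos_sig, neg_sig,
                          params = scoring_params(), pockets = NULL) {
  params <- as_scoring_params(params)
  pk <- pockets %||% tryCatch(detect_pockets(structure, params),
                              error = function(e) list())
  pk <- top_pockets(pk, params$top_k_pockets)
  if (length(pk) == 0) {
    warnf("no detectable pockets in %s; reported as non-target", structure$id)
    return(prediction_row(structure$id, NA_integer_, Inf, Inf, Inf, FALSE))
  }
  best <- NULL
  for (p in pk) {
    sp <- align_to_signature(p, pos_sig, params)$combined_score
    sn <- align_to_signature(p, neg_sig, params)$combined_score
    d <- score_difference_rule(sp, sn)$delta
    if (is.null(best) || d < best$delta) {
      best <- list(rank = p$rank, sp = sp, sn = sn, delta = d)
    }
  }
  prediction_row(structure$id, best$rank, best$sp, best$sn, best$delta,
                 best$delta < 0)
}

#' The score-difference decision rule
#'
#' A protein passes when its positive-signature score beats (is lower than)
#' its negative-signature score: `score_pos - score_neg < 0` (strict).
#' `NaN` differences (both scores infinite) are treated as `+Inf`.
#'
#' @param score_pos,score_neg Combined alignment scores against the
#'   positive and negative signatures (may be infinite).
#' @return Data frame with `delta` and logical `predicted`.
#' @export
score_difference_rule <- function(score_pos, score_neg) {
  delta <- score_pos - score_neg
  delta[is.nan(delta)] <- Inf
  data.frame(delta = delta, predicted = delta < 0)
}

prediction_row <- function(id, rank, sp, sn, delta, predicted,
                           docking = NA_real_, signif = NA_real_) {
  structure(data.frame(
    id = id, pocket_rank = rank, score_pos = sp, score_neg = sn,
    delta = delta, predicted = predicted, docking_score = docking,
    significance = signif, stringsAsFactors = FALSE
  ), class = c("target_predictions", "data.frame"))
}

#' Positive-signature-only classification
#'
#' The single-signature operating mode: a protein is called a target when
#' its best positive score is strictly below the cutoff (default 0.85).
#' The negative signature plays no role in this mode.
#'
#' @param score_positive Combined score against the positive signature
#'   (may be `Inf` for unalignable proteins, which are never targets).
#' @param cutoff Score threshold.
#' @return Logical.
#' @export
classify_positive_only <- function(score_positive, cutoff = 0.85) {
  is.finite(score_positive) & score_positive < cutoff
}

#' Rank predicted targets by docking score
#'
#' Two-step ranking: first keep only the proteins passing the
#' score-difference rule (`delta < 0`), then sort them in ascending order
#' of docking score (more negative = stronger predicted binding).  Targets
#' without a docking score are placed after the scored ones and flagged.
#' Ties are broken by ascending delta, then id.
#'
#' @param predictions A data frame of predictions (one row per protein).
#' @param docking_scores Named numeric vector of docking scores (e.g. from
#'   [read_score_table()]).
#' @return The predicted targets, ranked, with `docking_score` filled in.
#' @export
rank_targets <- function(predictions, docking_scores = NULL) {
  df <- as.data.frame(predictions)
  df <- df[df$predicted %in% TRUE, , drop = FALSE]
  if (nrow(df) == 0) return(df)
  if (!is.null(docking_scores)) {
    hit <- match(df$id, names(docking_scores))
    df$docking_score <- as.numeric(docking_scores[hit])
  }
  missing <- is.na(df$docking_score)
  if (any(missing))
    warnf("no docking score for predicted target(s): %s",
          paste(df$id[missing], collapse = ", "))
  ord <- order(missing, df$docking_score, df$delta, df$id)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Empirical significance of a docking score
#'
#' Fraction of random-structure docking scores at least as good (as low)
#' as the target's score.  A target that beats all random scores gets 0,
#' conventionally reported as "<1%" when 100 random scores are used.
#'
#' @param target_docking_score Numeric docking score of the candidate.
#' @param random_scores Numeric vector of docking scores of random
#'   structures (at least one).
#' @return Fraction in `[0, 1]`.
#' @export
empirical_significance <- function(target_docking_score, random_scores) {
  if (length(random_scores) == 0)
    stopf("empirical significance needs at least one random score")
  mean(random_scores <= target_docking_score)
}

#' Confusion-matrix evaluation
#'
#' @param predicted Logical vector of predictions.
#' @param truth Logical vector of true labels (same length).
#' @return List of class `eval_result` with tp, fp, tn, fn, sensitivity
#'   (`tp/(tp+fn)`) and specificity (`tn/(tn+fp)`).
#' @export
evaluate <- function(predicted, truth) {
  if (length(predicted) != length(truth) || anyNA(predicted) || anyNA(truth))
    stopf("need complete predicted/truth labels of equal length")
  tp <- sum(predicted & truth); fn <- sum(!predicted & truth)
  tn <- sum(!predicted & !truth); fp <- sum(predicted & !truth)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> tp=%d fp=%d tn=%d fn=%d  sensitivity=%.3f specificity=%.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity))
  invisible(x)
}

#' Cross-validated evaluation of the signature pipeline
#'
#' Stratified k-fold cross-validation: per fold, the positive signature is
#' built from the training positives' binding pockets, the reference
#' binding pocket is the medoid of the training positive pockets, the
#' negative signature is built from the training negatives' selected
#' pockets, and the held-out proteins are scored and classified with the
#' score-difference rule.  Confusion counts are pooled over folds.  With
#' `mode = "positive_only"` the negative signature is skipped and the
#' fixed positive-score cutoff is used instead.
#'
#' @param structures List of `protein_structure` objects.
#' @param labels Logical vector: `TRUE` for known targets.
#' @param folds Number of folds (default 5); each class must have at least
#'   `folds` members.
#' @param seed Integer seed for the fold assignment.
#' @param params A [scoring_params()] list.
#' @param mode `"difference"` (positive + negative signatures) or
#'   `"positive_only"`; both can be requested at once, sharing the
#'   signature builds.
#' @param binding_pockets Optional list (parallel to `structures`) of
#'   binding pockets for the positives; by default each positive's rank-1
#'   detected pocket is used.
#' @return For a single mode, an `eval_result` with `$folds` (fold
#'   assignment) and `$seed`; for two modes, a named list of them.
#' @export
cross_validate <- function(structures, labels, folds = 5L, seed = 1L,
                           params = scoring_params(),
                           mode = "difference",
                           binding_pockets = NULL) {
  params <- as_scoring_params(params)
  mode <- match.arg(mode, c("difference", "positive_only"),
                    several.ok = TRUE)
  labels <- as.logical(labels)
  n <- length(structures)
  stopifnot(length(labels) == n)
  if (sum(labels) < folds || sum(!labels) < folds)
    stopf("need at least %d structures per class for %d folds", folds, folds)

  # fold assignment, stratified by label
  fold <- integer(n)
  with_local_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })

  # pockets are fold-independent; compute once
  all_pockets <- lapply(structures, function(s)
    tryCatch(detect_pockets(s, params), error = function(e) list()))
  if (is.null(binding_pockets)) {
    binding_pockets <- lapply(seq_len(n), function(i) {
      if (!labels[i]) return(NULL)
      pk <- all_pockets[[i]]
      if (length(pk) == 0) NULL else pk[[1]]
    })
  }

  pooled <- list()
  for (m in mode) pooled[[m]] <- list(pred = logical(0), truth = logical(0))

  for (f in seq_len(folds)) {
    train <- which(fold != f)
    test <- which(fold == f)
    tr_pos <- train[labels[train]]
    tr_neg <- train[!labels[train]]
    pos_pk <- Filter(Negate(is.null), binding_pockets[tr_pos])
    if (length(pos_pk) < 2)
      stopf("fold %d: fewer than 2 positive training pockets", f)
    pos_sig <- build_positive_signature(pos_pk, params, drug_id = "cv")
    need_neg <- "difference" %in% mode
    if (need_neg) {
      M <- attr(pos_sig, "score_matrix")
      Mf <- M
      Mf[!is.finite(Mf)] <- NA
      medoid <- which.min(rowMeans(Mf, na.rm = TRUE))
      ref_pocket <- pos_pk[[medoid]]
      neg_sig <- build_negative_signature(
        structures[tr_neg], ref_pocket, params, drug_id = "cv",
        pockets = all_pockets[tr_neg])
    }
    for (i in test) {
      pk <- top_pockets(all_pockets[[i]], params$top_k_pockets)
      if ("difference" %in% mode) {
        pr <- if (length(pk) == 0) {
          prediction_row(structures[[i]]$id, NA_integer_, Inf, Inf, Inf, FALSE)
        } else {
          suppressWarnings(score_protein(structures[[i]], pos_sig, neg_sig,
                                         params, pockets = pk))
        }
        pooled$difference$pred <- c(pooled$difference$pred, pr$predicted)
        pooled$difference$truth <- c(pooled$difference$truth, labels[i])
      }
      if ("positive_only" %in% mode) {
        sp <- Inf
        for (p in pk) {
          s <- align_to_signature(p, pos_sig, params)$combined_score
          if (s < sp) sp <- s
        }
        pooled$positive_only$pred <-
          c(pooled$positive_only$pred,
            classify_positive_only(sp, params$positive_only_cutoff))
        pooled$positive_only$truth <- c(pooled$positive_only$truth, labels[i])
      }
    }
  }

  out <- lapply(pooled, function(po) {
    ev <- evaluate(po$pred, po$truth)
    ev$folds <- fold
    ev$seed <- seed
    ev
  })
  if (length(mode) == 1) out[[mode]] else out
}
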