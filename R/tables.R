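#' Read a docking-score table
#'
#' Reads a two-column tab-separated table of protein identifier and numeric
#' docking score (more negative = stronger predicted binding).  Docking
#' scores are external inputs to this package; they are never computed here.
#'
#' @param path TSV file.  A header line is detected automatically (first
#'   line whose second field is non-numeric).
#' @return Named numeric vector of docking scores.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (length(readLines(path, n = 1, warn = FALSE)) == 0)
    return(stats::setNames(numeric(0), character(0)))
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) == 0) return(stats::setNames(numeric(0), character(0)))
  if (ncol(raw) < 2) stopf("score table must have two columns (id, score)")
  first_num <- suppressWarnings(as.numeric(raw[1, 2]))
  if (is.na(first_num)) raw <- raw[-1, , drop = FALSE]   # header
  if (nrow(raw) == 0) return(stats::setNames(numeric(0), character(0)))
  ids <- raw[[1]]
  sc <- suppressWarnings(as.numeric(raw[[2]]))
  if (any(is.na(sc)))
    stopf("non-numeric docking score for id '%s'", ids[which(is.na(sc))[1]])
  if (anyDuplicated(ids))
    stopf("duplicate id in score table: '%s'", ids[duplicated(ids)][1])
  stats::setNames(sc, ids)
}

#' Write a prediction table
#'
#' Writes predictions as TSV with columns id, pocket_rank, score_pos,
#' score_neg, delta, predicted, docking_score, significance.
#'
#' @param predictions A data frame as returned by [score_protein()] /
#'   [rank_targets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("id", "pocket_rank", "score_pos", "score_neg", "delta",
            "predicted", "docking_score", "significance")
  df <- as.data.frame(predictions)
  for (cl in setdiff(cols, names(df))) df[[cl]] <- NA
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read pockets as TSV
#'
#' The pocket table (structure_id, rank, volume, atom serials) lets users
#' substitute pockets from an external pocket finder (e.g. genuine
#' alpha-shape output) for the built-in grid finder.
#'
#' @param pockets List of `pocket` objects.
#' @param path TSV path.
#' @return `path` invisibly for the writer; for the reader, a list of
#'   `pocket` objects resolved against `structure`.
#' @export
write_pockets <- function(pockets, path) {
  rows <- lapply(pockets, function(p) {
    data.frame(structure_id = p$structure_id, rank = p$rank,
               volume = p$volume,
               atom_serials = paste(p$atom_serials, collapse = ","),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pockets
#' @param structure A `protein_structure` whose serials resolve the pocket
#'   atom lists.
#' @export
read_pockets <- function(path, structure) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    serials <- as.integer(strsplit(df$atom_serials[i], ",")[[1]])
    idx <- match(serials, structure$atoms$serial)
    if (anyNA(idx))
      stopf("pocket references serial(s) absent from structure %s",
            structure$id)
    new_pocket(structure, idx, volume = df$volume[i], rank = df$rank[i])
  })
}
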