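SIGNATURE_SCHEMA_VERSION <- 1L

#' Write / read a structural signature as JSON
#'
#' Signatures are persisted as structured JSON with an explicit schema
#' version.  Coordinates are stored in the signature's own reference frame;
#' the round trip is lossless (positions, frequency tables, preservation
#' ratios, polarity, parameters).
#'
#' @param signature A `structural_signature`.
#' @param path Output / input path.
#' @return `write_signature()` returns `path` invisibly; `read_signature()`
#'   returns a validated `structural_signature`.
#' @export
write_signature <- function(signature, path) {
  validate_signature(signature)
  p <- signature$positions
  positions <- lapply(seq_len(nrow(p)), function(i) {
    af <- signature$atom_freq[i, ]
    rf <- signature$res_freq[i, ]
    list(x = p$x[i], y = p$y[i], z = p$z[i],
         preservation = p$preservation[i], support = p$support[i],
         atom_freqs = as.list(af[af > 0]),
         res_freqs = as.list(rf[rf > 0]))
  })
  obj <- list(
    schema_version = SIGNATURE_SCHEMA_VERSION,
    drug_id = signature$drug_id,
    polarity = signature$polarity,
    n_structures = signature$n_structures,
    preservation_cutoff = signature$preservation_cutoff,
    params = signature$params,
    positions = positions
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- obj$schema_version
  if (is.null(ver) || !identical(as.integer(ver), SIGNATURE_SCHEMA_VERSION))
    stopf("signature schema version mismatch: file has %s, expected %d",
          ver %||% "none", SIGNATURE_SCHEMA_VERSION)
  if (is.null(obj$polarity))
    stopf("signature file missing required field 'polarity'")
  pos <- obj$positions
  if (length(pos) == 0) stopf("signature file has no positions")
  elements <- sort(unique(unlist(lapply(pos, function(p) names(p$atom_freqs)))))
  residues <- sort(unique(unlist(lapply(pos, function(p) names(p$res_freqs)))))
  P <- length(pos)
  af <- matrix(0, P, length(elements), dimnames = list(NULL, elements))
  rf <- matrix(0, P, length(residues), dimnames = list(NULL, residues))
  df <- data.frame(index = seq_len(P), x = NA_real_, y = NA_real_,
                   z = NA_real_, preservation = NA_real_,
                   support = NA_integer_)
  for (i in seq_len(P)) {
    p <- pos[[i]]
    df$x[i] <- p$x; df$y[i] <- p$y; df$z[i] <- p$z
    df$preservation[i] <- p$preservation
    df$support[i] <- as.integer(p$support)
    if (length(p$atom_freqs))
      af[i, names(p$atom_freqs)] <- unlist(p$atom_freqs)
    if (length(p$res_freqs))
      rf[i, names(p$res_freqs)] <- unlist(p$res_freqs)
  }
  sig <- structure(list(
    drug_id = obj$drug_id %||% "drug",
    polarity = obj$polarity,
    positions = df, atom_freq = af, res_freq = rf,
    n_structures = as.integer(obj$n_structures),
    preservation_cutoff = as.numeric(obj$preservation_cutoff),
    params = obj$params
  ), class = "structural_signature")
  validate_signature(sig)
  sig
}
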