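FINGERPRINT_FORMAT_VERSION <- 1L

#' Serialize fingerprints to JSON
#'
#' Writes a versioned JSON document holding the sample id, the panel hash,
#' the model parameters and the per-SNP counts and log-evidence triples.
#' Numbers are written at full precision so that log values round-trip
#' exactly.
#'
#' @param fp a `fingerprint` object.
#' @param destination,source file paths.
#' @param params the [model_params()] the fingerprint was computed with.
#' @return `write_fingerprint()` returns the path invisibly;
#'   `read_fingerprint()` returns a `fingerprint` object.
#' @export
write_fingerprint <- function(fp, destination, params = model_params()) {
  stopifnot(inherits(fp, "fingerprint"))
  doc <- list(
    format_version = FINGERPRINT_FORMAT_VERSION,
    sample_id = fp$sample_id,
    panel_hash = fp$panel_hash,
    params = list(alpha = unname(params$alpha), beta = unname(params$beta),
                  prior_same = params$prior_same,
                  keep_binomial = params$keep_binomial),
    m = fp$m, n = fp$n,
    logq = list(WW = unname(fp$logq[, "WW"]),
                WA = unname(fp$logq[, "WA"]),
                AA = unname(fp$logq[, "AA"])))
  # I(17) significant digits: enough for doubles to round-trip bit-exactly
  jsonlite::write_json(doc, destination, auto_unbox = TRUE, digits = I(17))
  invisible(destination)
}

#' @rdname write_fingerprint
#' @export
read_fingerprint <- function(source) {
  doc <- jsonlite::read_json(source, simplifyVector = TRUE)
  if (is.null(doc$format_version) || doc$format_version > FINGERPRINT_FORMAT_VERSION)
    stop("unsupported fingerprint format version in '", source, "'")
  m <- as.integer(doc$m)
  logq <- cbind(WW = as.numeric(doc$logq$WW),
                WA = as.numeric(doc$logq$WA),
                AA = as.numeric(doc$logq$AA))
  structure(
    list(sample_id = doc$sample_id,
         panel_hash = doc$panel_hash,
         m = m, n = as.integer(doc$n),
         logq = logq,
         covered = (m + as.integer(doc$n)) > 0L),
    class = "fingerprint")
}
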