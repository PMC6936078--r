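#' All-vs-all comparison of sample fingerprints
#'
#' Computes the identity posterior for every unordered pair of samples.
#' Pairs with no SNP covered in both samples are reported as NOTEST and
#' should be excluded from downstream evaluation.
#'
#' @param fingerprints list of `fingerprint` objects sharing one panel hash;
#'   at least two.
#' @param panel the `snp_panel` the fingerprints were computed against.
#' @param params a [model_params()] object.
#' @param threshold posterior cutoff used for the `call` column.
#' @return a data frame of class `comparison_results` with one row per pair
#'   in lexicographic sample-id order: `sample_a`, `sample_b`, `posterior`
#'   (NA for NOTEST), `log10_bf`, `log_odds`, `n_co_covered`, `call`.
#' @export
compare_all <- function(fingerprints, panel, params = model_params(),
                        threshold = 0.95) {
  stopifnot(is.list(fingerprints))
  if (length(fingerprints) < 2L)
    stop("at least two fingerprints are required")
  hashes <- vapply(fingerprints, `[[`, character(1), "panel_hash")
  if (length(unique(hashes)) != 1L)
    stop("fingerprints carry mixed panel hashes; they were not computed ",
         "against the same panel")
  ids <- vapply(fingerprints, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids among fingerprints")
  fingerprints <- fingerprints[order(ids)]
  ids <- sort(ids)
  if (!identical(hashes[[1L]], panel_hash(panel)))
    stop("fingerprints were not computed against the supplied panel ",
         "(panel hash mismatch)")
  nfp <- length(fingerprints)
  lv <- log_hw_matrix(panel$q)
  pre <- lapply(fingerprints, precompute_pair_terms, lv = lv)
  log_prior_odds <- log(params$prior_same) - log1p(-params$prior_same)
  pairs <- utils::combn(nfp, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    keep <- pre[[i]]$covered & pre[[j]]$covered
    n_co <- sum(keep)
    if (n_co == 0L) {
      posterior <- NA_real_; log10_bf <- NA_real_; log_odds <- NA_real_
    } else {
      log_lr <- pair_log_lr(pre[[i]], pre[[j]], lv, keep)
      log_odds <- log_prior_odds + log_lr
      posterior <- posterior_from_log_lr(log_lr, params$prior_same)
      log10_bf <- log_lr / log(10)
    }
    data.frame(sample_a = ids[i], sample_b = ids[j],
               posterior = posterior, log10_bf = log10_bf,
               log_odds = log_odds, n_co_covered = as.integer(n_co),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$call <- vapply(seq_len(nrow(out)), function(i)
    classify_posterior(out$posterior[i], threshold), character(1))
  rownames(out) <- NULL
  class(out) <- c("comparison_results", "data.frame")
  out
}

classify_posterior <- function(posterior, threshold = 0.95) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.na(posterior)) return("notest")
  if (posterior >= threshold) "same" else "different"
}

#' Classify a comparison at a posterior threshold
#'
#' A pair is called `"same"` when the posterior reaches the threshold,
#' `"different"` below it; NOTEST passes through unchanged. The default
#' cutoff 0.95 calls a pair the same individual unless the probability of
#' different individuals exceeds 0.05.
#'
#' @param result one row of a `comparison_results` data frame, or a list
#'   with a `posterior` element (NA meaning NOTEST).
#' @param threshold posterior cutoff in (0, 1).
#' @return `"same"`, `"different"` or `"notest"`.
#' @export
classify <- function(result, threshold = 0.95) {
  classify_posterior(result$posterior, threshold)
}

#' Write comparison results
#'
#' The long-format TSV is the canonical machine output: one row per pair
#' with the posterior printed to 10 significant digits (enough to separate
#' 0.9999995 from 1), the log10 Bayes factor, the co-covered SNP count and
#' the call; NOTEST pairs carry the literal string `NOTEST` in the posterior
#' column. `write_comparison_matrix()` additionally writes a symmetric
#' sample-by-sample posterior matrix for human reading.
#'
#' @param results a `comparison_results` data frame.
#' @param destination output path.
#' @return the path, invisibly.
#' @export
write_comparisons <- function(results, destination) {
  df <- data.frame(
    sample_a = results$sample_a, sample_b = results$sample_b,
    posterior = ifelse(is.na(results$posterior), "NOTEST",
                       formatC(results$posterior, digits = 10,
                               format = "g")),
    log10_BF = ifelse(is.na(results$log10_bf), "NA",
                      formatC(results$log10_bf, digits = 10, format = "g")),
    n_co_covered = results$n_co_covered,
    call = results$call, stringsAsFactors = FALSE)
  utils::write.table(df, destination, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(destination)
}

#' @rdname write_comparisons
#' @export
write_comparison_matrix <- function(results, destination) {
  ids <- sort(unique(c(results$sample_a, results$sample_b)))
  mat <- matrix("NOTEST", length(ids), length(ids),
                dimnames = list(ids, ids))
  diag(mat) <- "1"
  for (i in seq_len(nrow(results))) {
    v <- if (is.na(results$posterior[i])) "NOTEST"
         else formatC(results$posterior[i], digits = 10, format = "g")
    mat[results$sample_a[i], results$sample_b[i]] <- v
    mat[results$sample_b[i], results$sample_a[i]] <- v
  }
  utils::write.table(mat, destination, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(destination)
}

#' @rdname write_comparisons
#' @export
read_comparisons <- function(source) {
  df <- utils::read.table(source, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "character",
                                         "integer", "character"))
  df$log10_bf <- suppressWarnings(as.numeric(df$log10_BF))
  df$log10_BF <- NULL
  df$posterior <- suppressWarnings(
    ifelse(df$posterior == "NOTEST", NA_real_, as.numeric(df$posterior)))
  class(df) <- c("comparison_results", "data.frame")
  df
}
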