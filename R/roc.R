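#' Truth labels for ROC evaluation
#'
#' @param sample_id,individual_id equal-length character vectors mapping each
#'   sample to the individual it came from.
#' @return an object of class `truth_labels`.
#' @export
truth_labels <- function(sample_id, individual_id) {
  sample_id <- as.character(sample_id)
  individual_id <- as.character(individual_id)
  stopifnot(length(sample_id) == length(individual_id))
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in truth labels")
  structure(list(sample_id = sample_id, individual_id = individual_id),
            class = "truth_labels")
}

#' @rdname truth_labels
#' @param source path to a two-column TSV with header `sample_id`,
#'   `individual_id`.
#' @export
read_truth_labels <- function(source) {
  df <- utils::read.table(source, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  truth_labels(df$sample_id, df$individual_id)
}

# logical: does each result row pair two samples of one individual
pair_is_positive <- function(results, truth) {
  ind <- stats::setNames(truth$individual_id, truth$sample_id)
  a <- ind[results$sample_a]
  b <- ind[results$sample_b]
  if (anyNA(a) || anyNA(b)) {
    missing <- unique(c(results$sample_a[is.na(a)], results$sample_b[is.na(b)]))
    stop("sample(s) missing from truth labels: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  unname(a == b)
}

#' ROC curve over labeled pairwise comparisons
#'
#' Sweeps the distinct posterior values as cutoffs. At each cutoff p the
#' true positive rate is the fraction of same-individual pairs with
#' posterior >= p and the false positive rate the fraction of
#' different-individual pairs with posterior >= p; tied pairs therefore move
#' together. NOTEST pairs are excluded from both numerator and denominator.
#' The AUC is the trapezoidal integral over the (FPR, TPR) polyline
#' augmented with the (0,0) and (1,1) endpoints, which equals the
#' Mann-Whitney rank statistic with half-credit for ties.
#'
#' @param results a `comparison_results` data frame from [compare_all()].
#' @param truth a [truth_labels()] object covering every compared sample.
#' @return an object of class `roc_curve`: a list with `cutoffs` (decreasing),
#'   `tpr`, `fpr`, `auc`, `n_positive`, `n_negative`, `n_notest`.
#' @export
roc_curve <- function(results, truth) {
  stopifnot(inherits(truth, "truth_labels"))
  pos <- pair_is_positive(results, truth)
  use <- !is.na(results$posterior)
  n_notest <- sum(!use)
  p <- results$posterior[use]
  pos <- pos[use]
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L)
    stop("no same-individual pair among the evaluable comparisons")
  if (n_neg == 0L)
    stop("no different-individual pair among the evaluable comparisons")
  cutoffs <- sort(unique(p), decreasing = TRUE)
  tpr <- vapply(cutoffs, function(cut) sum(pos & p >= cut) / n_pos,
                numeric(1))
  fpr <- vapply(cutoffs, function(cut) sum(!pos & p >= cut) / n_neg,
                numeric(1))
  fx <- c(0, fpr, 1)
  fy <- c(0, tpr, 1)
  auc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  structure(list(cutoffs = cutoffs, tpr = tpr, fpr = fpr, auc = auc,
                 n_positive = n_pos, n_negative = n_neg,
                 n_notest = as.integer(n_notest)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "ROC over %d positive / %d negative pairs (%d NOTEST excluded): AUC %.4f\n",
    x$n_positive, x$n_negative, x$n_notest, x$auc))
  invisible(x)
}

#' Operating point of a ROC curve at a posterior threshold
#'
#' Returns the (FPR, TPR) realized when pairs with posterior >= `threshold`
#' are called the same individual, i.e. the curve point at the smallest
#' cutoff >= `threshold` (or (0, 0) when the threshold exceeds every
#' posterior).
#'
#' @param curve a `roc_curve`.
#' @param threshold posterior cutoff, default 0.95.
#' @return named numeric vector `c(fpr = ..., tpr = ...)`.
#' @export
operating_point <- function(curve, threshold = 0.95) {
  stopifnot(inherits(curve, "roc_curve"))
  ok <- which(curve$cutoffs >= threshold)
  if (length(ok) == 0L) return(c(fpr = 0, tpr = 0))
  i <- max(ok)  # cutoffs are decreasing: the smallest cutoff >= threshold
  c(fpr = curve$fpr[i], tpr = curve$tpr[i])
}

#' Write a ROC curve as TSV
#'
#' Columns cutoff, tpr, fpr, with the AUC and counts in `#` header comments.
#'
#' @param curve a `roc_curve`.
#' @param destination output path.
#' @return the path, invisibly.
#' @export
write_roc <- function(curve, destination) {
  con <- file(destination, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#auc=%.*g", 15, curve$auc),
               sprintf("#n_positive=%d\t#n_negative=%d\t#n_notest=%d",
                       curve$n_positive, curve$n_negative, curve$n_notest),
               "cutoff\ttpr\tfpr"), con)
  utils::write.table(
    data.frame(curve$cutoffs, curve$tpr, curve$fpr), con, sep = "\t",
    quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(destination)
}
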