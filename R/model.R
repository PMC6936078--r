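#' @importFrom stats lbeta setNames median rpois rnbinom rbinom runif
NULL

GENOTYPES <- c("WW", "WA", "AA")

#' Model parameters for the identity test
#'
#' Bundles the beta hyperparameters of the per-genotype apparent-allele-
#' frequency priors and the prior probability that two samples share an
#' individual. The beta shapes encode the expectation that the alternate-read
#' fraction sits near 0 for homozygous wild type (WW), near 1 for homozygous
#' alternate (AA), and near 1/2 for heterozygotes (WA); the Beta(1, 30) shape
#' for WW tolerates a sequencing-error fraction of a few percent.
#'
#' @param alpha,beta numeric length-3 vectors of beta shape parameters in
#'   genotype order (WW, WA, AA). Defaults Beta(1,30), Beta(2,2), Beta(30,1).
#' @param prior_same prior probability that two samples derive from the same
#'   individual; the posterior is insensitive to this value once any
#'   informative SNP is covered in both samples.
#' @param keep_binomial keep the binomial coefficient choose(m+n, n) inside
#'   the stored log-evidence values. It cancels between the two hypotheses,
#'   so the posterior is unchanged; kept only for debugging.
#' @return an object of class `model_params`.
#' @export
model_params <- function(alpha = c(WW = 1, WA = 2, AA = 30),
                         beta = c(WW = 30, WA = 2, AA = 1),
                         prior_same = 0.01,
                         keep_binomial = FALSE) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  stopifnot(length(alpha) == 3L, length(beta) == 3L,
            all(alpha > 0), all(beta > 0),
            is.numeric(prior_same), length(prior_same) == 1L,
            prior_same > 0, prior_same < 1)
  structure(
    list(alpha = setNames(alpha, GENOTYPES),
         beta = setNames(beta, GENOTYPES),
         prior_same = prior_same,
         keep_binomial = isTRUE(keep_binomial)),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("identity-test model parameters\n")
  for (g in GENOTYPES)
    cat(sprintf("  %s: Beta(%g, %g)\n", g, x$alpha[[g]], x$beta[[g]]))
  cat(sprintf("  prior same individual: %g\n", x$prior_same))
  invisible(x)
}

#' Log evidence of read counts under one genotype
#'
#' Integrates the binomial read-count likelihood over the latent alternate-
#' allele fraction f under a Beta(alpha, beta) prior, giving
#' Q(m, n | h) = choose(m+n, n) * B(alpha + n, beta + m) / B(alpha, beta),
#' returned on the natural-log scale via log-gamma, stable for depths well
#' beyond 1e6. The binomial coefficient cancels in the identity posterior and
#' is omitted unless `keep_binomial`.
#'
#' @param m,n non-negative integer vectors: reads matching / not matching the
#'   reference base.
#' @param alpha,beta beta-prior shapes (> 0), recycled against m and n.
#' @param keep_binomial include the log binomial coefficient.
#' @return numeric vector of log Q values.
#' @export
log_evidence <- function(m, n, alpha, beta, keep_binomial = FALSE) {
  if (any(m < 0) || any(n < 0)) stop("read counts must be non-negative")
  out <- lbeta(alpha + n, beta + m) - lbeta(alpha, beta)
  if (isTRUE(keep_binomial)) out <- out + lchoose(m + n, n)
  out
}

#' Hardy-Weinberg genotype-pair matrices
#'
#' `same_individual_matrix()` returns the diagonal matrix of Hardy-Weinberg
#' genotype frequencies ((1-q)^2, 2q(1-q), q^2): under the same-individual
#' hypothesis both samples carry one genotype drawn from these proportions.
#' `different_individuals_matrix()` returns its outer product with itself:
#' two independent Hardy-Weinberg draws.
#'
#' @param q population alternate-allele frequency, strictly inside (0, 1).
#' @return a 3x3 matrix indexed (WW, WA, AA) in both dimensions.
#' @export
same_individual_matrix <- function(q) {
  v <- hw_probs(q)
  m <- diag(unname(v))
  dimnames(m) <- list(GENOTYPES, GENOTYPES)
  m
}

#' @rdname same_individual_matrix
#' @export
different_individuals_matrix <- function(q) {
  v <- hw_probs(q)
  m <- outer(unname(v), unname(v))
  dimnames(m) <- list(GENOTYPES, GENOTYPES)
  m
}

hw_probs <- function(q) {
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stop("allele frequency q must lie strictly inside (0, 1)")
  c(WW = (1 - q)^2, WA = 2 * q * (1 - q), AA = q^2)
}

# n_snps x 3 matrix of log HW proportions for a panel
log_hw_matrix <- function(q) {
  if (any(q <= 0 | q >= 1))
    stop("allele frequency q must lie strictly inside (0, 1)")
  cbind(WW = 2 * log1p(-q), WA = log(2) + log(q) + log1p(-q), AA = 2 * log(q))
}

#' Compute a sample fingerprint
#'
#' Converts one sample's per-SNP allele counts into the three log evidence
#' values log Q(m, n | h), h in (WW, WA, AA). This triple per SNP is a
#' sufficient summary of the sample for every future pairwise comparison, so
#' fingerprints can be stored (see [write_fingerprint()]) and compared without
#' revisiting the alignment. The fingerprint is bound to its panel by a hash
#' so that fingerprints computed against different panels cannot be mixed.
#'
#' @param counts an `allele_counts` object from [count_alleles()],
#'   [simulate_counts()] or [read_counts()].
#' @param panel the `snp_panel` the counts are aligned to.
#' @param params a [model_params()] object.
#' @return an object of class `fingerprint` with fields `sample_id`,
#'   `panel_hash`, `m`, `n`, `logq` (n_snps x 3 matrix) and `covered`.
#' @export
fingerprint <- function(counts, panel, params = model_params()) {
  stopifnot(inherits(counts, "allele_counts"), inherits(panel, "snp_panel"))
  if (length(counts$m) != nrow(panel))
    stop("counts length (", length(counts$m),
         ") does not match panel size (", nrow(panel), ")")
  m <- counts$m
  n <- counts$n
  logq <- vapply(GENOTYPES, function(g)
    log_evidence(m, n, params$alpha[[g]], params$beta[[g]],
                 keep_binomial = params$keep_binomial),
    numeric(length(m)))
  if (length(m) == 1L) logq <- matrix(logq, nrow = 1L,
                                      dimnames = list(NULL, GENOTYPES))
  structure(
    list(sample_id = counts$sample_id,
         panel_hash = panel_hash(panel),
         m = m, n = n,
         logq = logq,
         covered = (m + n) > 0L),
    class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint of sample '%s': %d SNPs, %d covered\n",
              x$sample_id, length(x$m), sum(x$covered)))
  invisible(x)
}

# posterior = pi_I / (pi_I + (1 - pi_I) exp(-log_lr)); this form returns the
# prior bit-exactly at log_lr = 0 and degrades gracefully to 0/1 when
# exp(-log_lr) over- or underflows
posterior_from_log_lr <- function(log_lr, prior_same) {
  prior_same / (prior_same + (1 - prior_same) * exp(-log_lr))
}

# elementwise log(exp(a) + exp(b) + exp(c)), vectorized
lse3 <- function(a, b, c) {
  mx <- pmax(a, b, c)
  mx + log(exp(a - mx) + exp(b - mx) + exp(c - mx))
}

# per-pair work shared across comparisons: raw logq columns and the
# different-individuals per-SNP factor log sum_h Q(h) v_h
precompute_pair_terms <- function(fp, lv) {
  list(covered = fp$covered,
       l1 = fp$logq[, 1L], l2 = fp$logq[, 2L], l3 = fp$logq[, 3L],
       d = lse3(fp$logq[, 1L] + lv[, 1L],
                fp$logq[, 2L] + lv[, 2L],
                fp$logq[, 3L] + lv[, 3L]))
}

# log likelihood ratio (identity over non-identity) from precomputed terms;
# all additions arranged so that swapping a and b is bit-identical
pair_log_lr <- function(a, b, lv, keep) {
  log_tr_same <- lse3(lv[keep, 1L] + (a$l1[keep] + b$l1[keep]),
                      lv[keep, 2L] + (a$l2[keep] + b$l2[keep]),
                      lv[keep, 3L] + (a$l3[keep] + b$l3[keep]))
  sum(log_tr_same) - (sum(a$d[keep]) + sum(b$d[keep]))
}

#' Posterior probability that two samples share an individual
#'
#' Combines two fingerprints over the SNPs covered in both samples. Per SNP
#' the evidence triples are contracted with the Hardy-Weinberg genotype-pair
#' matrices: under the same-individual hypothesis the per-SNP factor is
#' sum_h Qa(h) Qb(h) v_h, under different individuals it factorizes into
#' (sum_h Qa(h) v_h)(sum_h Qb(h) v_h), with v the Hardy-Weinberg proportions
#' at that SNP's population allele frequency. All accumulation is in natural
#' log space: real cohorts produce likelihood ratios spanning hundreds of
#' orders of magnitude, far beyond double range in probability space.
#'
#' SNPs covered in only one sample contribute identical factors to both
#' hypotheses (the uncovered sample's evidence triple is (1, 1, 1)) and are
#' skipped. If no SNP is covered in both samples the comparison is reported
#' as NOTEST rather than a number; `allow_notest = FALSE` bypasses the gate,
#' in which case the posterior equals the prior exactly.
#'
#' @param fp_a,fp_b `fingerprint` objects sharing one panel hash.
#' @param panel the `snp_panel` both fingerprints were computed against.
#' @param params a [model_params()] object.
#' @param allow_notest report NOTEST when no SNP is co-covered (default);
#'   set FALSE to return the prior instead.
#' @return a list with elements `posterior` (probability, or NA for NOTEST),
#'   `notest` (logical), `log10_bf` (log10 likelihood ratio, identity over
#'   non-identity, prior excluded; NA for NOTEST), `log_odds` (natural-log
#'   posterior odds, prior included) and `n_co_covered`.
#' @export
posterior_same <- function(fp_a, fp_b, panel, params = model_params(),
                           allow_notest = TRUE) {
  stopifnot(inherits(fp_a, "fingerprint"), inherits(fp_b, "fingerprint"))
  ph <- panel_hash(panel)
  if (!identical(fp_a$panel_hash, ph) || !identical(fp_b$panel_hash, ph))
    stop("fingerprints were not computed against the supplied panel ",
         "(panel hash mismatch)")
  keep <- fp_a$covered & fp_b$covered
  n_co <- sum(keep)
  if (n_co == 0L && allow_notest) {
    return(list(posterior = NA_real_, notest = TRUE, log10_bf = NA_real_,
                log_odds = NA_real_, n_co_covered = 0L))
  }
  if (n_co == 0L) {
    log_lr <- 0
  } else {
    lv <- log_hw_matrix(panel$q)
    a <- precompute_pair_terms(fp_a, lv)
    b <- precompute_pair_terms(fp_b, lv)
    log_lr <- pair_log_lr(a, b, lv, keep)
  }
  log_prior_odds <- log(params$prior_same) - log1p(-params$prior_same)
  log_odds <- log_prior_odds + log_lr
  posterior <- posterior_from_log_lr(log_lr, params$prior_same)
  list(posterior = posterior, notest = FALSE,
       log10_bf = log_lr / log(10),
       log_odds = log_odds,
       n_co_covered = as.integer(n_co))
}
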