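# Independent oracles used across the suite. These deliberately avoid the
# package's log-space code paths: the evidence integral is evaluated by
# adaptive quadrature and the posterior by literal 3x3 matrix products.

# log of integral_0^1 f^n (1-f)^m Beta(f; alpha, beta) df by scaled
# adaptive quadrature
quad_log_evidence <- function(m, n, alpha, beta) {
  lg <- function(f) n * log(f) + m * log1p(-f) +
    stats::dbeta(f, alpha, beta, log = TRUE)
  grid <- seq(1e-9, 1 - 1e-9, length.out = 2001)
  M <- max(lg(grid))
  val <- stats::integrate(function(f) exp(lg(f) - M), 0, 1,
                          rel.tol = 1e-12, abs.tol = 0,
                          subdivisions = 2000L)$value
  log(val) + M
}

# direct (non-log) evidence value; safe for small total depth
direct_Q <- function(m, n, alpha, beta) {
  beta(alpha + n, beta + m) / beta(alpha, beta)
}

# posterior odds of identity by literal per-SNP 3x3 matrix arithmetic;
# per-SNP traces in plain double (depths must stay moderate), log odds
# accumulated across SNPs
brute_posterior <- function(ma, na, mb, nb, q, prior_same = 0.01,
                            alpha = c(1, 2, 30), beta = c(30, 2, 1)) {
  stopifnot(length(ma) == length(q))
  log_tr_I <- numeric(length(q))
  log_tr_D <- numeric(length(q))
  for (s in seq_along(q)) {
    Qa <- vapply(1:3, function(h) direct_Q(ma[s], na[s], alpha[h], beta[h]),
                 numeric(1))
    Qb <- vapply(1:3, function(h) direct_Q(mb[s], nb[s], alpha[h], beta[h]),
                 numeric(1))
    Qhat <- outer(Qa, Qb)
    v <- c((1 - q[s])^2, 2 * q[s] * (1 - q[s]), q[s]^2)
    I_mat <- diag(v)
    D_mat <- outer(v, v)
    log_tr_I[s] <- log(sum(diag(Qhat %*% I_mat)))
    log_tr_D[s] <- log(sum(diag(Qhat %*% D_mat)))
  }
  log_odds <- log(prior_same) - log(1 - prior_same) +
    sum(log_tr_I) - sum(log_tr_D)
  list(log_odds = log_odds, posterior = stats::plogis(log_odds))
}

rel_diff <- function(x, y) {
  d <- abs(x - y)
  ifelse(d == 0, 0, d / pmax(abs(x), abs(y)))
}

# small panel over one synthetic chromosome with given frequencies
tiny_panel <- function(q, spacing = 2e5) {
  n <- length(q)
  snp_panel(chrom = rep("sim1", n),
            pos = seq(1e5, by = spacing, length.out = n),
            ref = rep("A", n), alt = rep("G", n), q = q,
            id = sprintf("t%03d", seq_len(n)))
}

counts_fp <- function(m, n, panel, params = model_params(),
                      sample_id = "s") {
  fingerprint(allele_counts(sample_id, m, n), panel, params)
}

# rank-statistic AUC: fraction of (positive, negative) pairs with the
# positive scored higher, ties counted half
mann_whitney_auc <- function(scores_pos, scores_neg) {
  cmp <- outer(scores_pos, scores_neg, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# relationship of two samples in a simulated family cohort
cohort_relationship <- function(cohort, sample_a, sample_b) {
  ind <- stats::setNames(cohort$truth$individual_id, cohort$truth$sample_id)
  ia <- ind[[sample_a]]; ib <- ind[[sample_b]]
  if (ia == ib) return("self")
  ped <- cohort$pedigree
  if (!is.null(ped)) {
    pc <- function(x, y) any(ped$child == x & (ped$mother == y | ped$father == y))
    if (pc(ia, ib) || pc(ib, ia)) return("parent_child")
    sib <- function(x, y) {
      rx <- ped[ped$child == x, ]; ry <- ped[ped$child == y, ]
      nrow(rx) > 0 && nrow(ry) > 0 && rx$mother[1] == ry$mother[1] &&
        rx$father[1] == ry$father[1]
    }
    if (sib(ia, ib)) return("sibling")
  }
  "unrelated"
}
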