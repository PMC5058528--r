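#' Null (absence) allele frequency from dominant phenotype counts
#'
#' At a dominant biallelic locus in HWE only the recessive homozygote is
#' observable as band absence, so the absence-allele frequency `q` is
#' inferred from `n_absent ~ Binomial(n, q^2)`.
#'
#' Methods: `sqrt` is the naive `sqrt(n_absent/n)`; `lynch_milligan` applies
#' the square-root bias correction `sqrt(x) / (1 - Var(x)/(8 x^2))`;
#' `zhivotovsky` is the Bayesian posterior mean of `q` under a uniform prior
#' on `q`, which has the closed form `Beta(k+1, n-k+1) / Beta(k+1/2, n-k+1)`
#' for `k = n_absent` (never exactly 0 or 1, which stabilises downstream
#' variance components).
#'
#' @param n_absent number of band-absent individuals (vectorised).
#' @param n number of scored individuals.
#' @param method one of `"sqrt"`, `"lynch_milligan"`, `"zhivotovsky"`.
#' @return estimated absence-allele frequency/frequencies in `[0,1]`.
#' @export
estimate_allele_freq <- function(n_absent, n,
                                 method = c("zhivotovsky", "sqrt",
                                            "lynch_milligan")) {
  method <- match.arg(method)
  if (any(n < 1)) stop("n must be >= 1")
  if (any(n_absent < 0 | n_absent > n)) stop("require 0 <= n_absent <= n")
  x <- n_absent / n
  switch(method,
    sqrt = sqrt(x),
    lynch_milligan = {
      nn <- rep_len(n, length(x))
      q <- sqrt(x)
      pos <- x > 0
      corr <- 1 - (x[pos] * (1 - x[pos]) / nn[pos]) / (8 * x[pos]^2)
      # guard against the correction overshooting at tiny x
      q[pos] <- ifelse(corr > 0.5, q[pos] / corr, q[pos])
      pmin(q, 1)
    },
    zhivotovsky = {
      k <- n_absent
      exp(lbeta(k + 1, n - k + 1) - lbeta(k + 0.5, n - k + 1))
    })
}

# delta-method sampling variance of the square-root estimator of q,
# used as the common sampling-variance approximation for all methods
qhat_sampling_var <- function(q, n) (1 - q^2) / (4 * n)

# per-group band-absence counts: returns list(k = r x L matrix, n = sizes)
group_absent_counts <- function(calls, groups) {
  groups <- as.factor(groups)
  absent <- 1L - calls
  G <- stats::model.matrix(~ groups - 1)
  k <- t(G) %*% absent
  rownames(k) <- levels(groups)
  list(k = k, n = as.vector(table(groups)))
}

# locus-wise variance components from group counts.
# Returns list(num, den): among-group variance estimate and total-variance
# estimate per locus (method-of-moments, sampling-variance corrected).
fst_components <- function(k, n, method = "zhivotovsky") {
  r <- nrow(k)
  L <- ncol(k)
  q <- matrix(estimate_allele_freq(as.vector(k), rep(n, L), method), r, L,
              dimnames = list(rownames(k), NULL))
  v <- qhat_sampling_var(q, matrix(rep(n, L), r, L))
  qbar <- colMeans(q)
  s2 <- colSums(sweep(q, 2, qbar)^2) / (r - 1)
  num <- s2 - colMeans(v)
  den <- qbar * (1 - qbar) + s2 / r
  list(num = num, den = den, q = q, qbar = qbar)
}

#' Locus and global FST for dominant markers, with permutation test
#'
#' Estimates allele frequencies per group (see [estimate_allele_freq()]) and
#' forms method-of-moments variance components per locus: the among-group
#' variance of estimated allele frequencies corrected for their sampling
#' variance, over an estimate of the total variance `p(1-p)` at the
#' ancestral frequency. The global FST is the ratio of summed numerators to
#' summed denominators over loci (ratio-of-sums, as in Weir-Cockerham
#' multilocus estimators). Significance is assessed by permuting individuals
#' among groups (group sizes preserved) and recomputing the global FST, with
#' `p = (1 + #{FST_perm >= FST_obs}) / (1 + n_perm)`.
#'
#' @param m a [marker_matrix()] (replicate rows are ignored).
#' @param grouping a metadata column name (e.g. `"host"`) or a vector of
#'   group labels over the primary samples.
#' @param n_perm permutations for the test (0 skips the test).
#' @param seed RNG seed for the permutations.
#' @param method allele-frequency estimator.
#' @return list with `fst` (global), `per_locus` (data.frame `locus, q_*,
#'   He, fst`), `p` (permutation p-value or NA), `n_perm`.
#' @export
fst_dominant <- function(m, grouping, n_perm = 5000L, seed = NULL,
                         method = "zhivotovsky") {
  pr <- primary_rows(m)
  calls <- m$calls[pr, , drop = FALSE]
  groups <- resolve_grouping(m, grouping)
  if (length(unique(groups)) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 samples")
  if (n_perm > 0 && n_perm < 100)
    warning("fewer than 100 permutations gives a coarse p-value")

  gc <- group_absent_counts(calls, groups)
  comp <- fst_components(gc$k, gc$n, method)
  fst_locus <- ifelse(comp$den > 0, comp$num / comp$den, NA_real_)
  global <- sum(comp$num) / sum(comp$den)

  # pooled-frequency He per locus (reported alongside)
  pooled_q <- estimate_allele_freq(colSums(1L - calls), nrow(calls), method)
  he <- 2 * pooled_q * (1 - pooled_q)

  per_locus <- data.frame(locus = m$loci$locus, stringsAsFactors = FALSE)
  for (g in rownames(gc$k)) per_locus[[paste0("q_", g)]] <- comp$q[g, ]
  per_locus$He <- he
  per_locus$fst <- fst_locus

  p <- NA_real_
  if (n_perm > 0) {
    local_seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      gp <- sample(groups)
      gcp <- group_absent_counts(calls, gp)
      cp <- fst_components(gcp$k, gcp$n, method)
      if (sum(cp$num) / sum(cp$den) >= global) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
  }
  list(fst = global, per_locus = per_locus, p = p, n_perm = n_perm)
}

# grouping argument -> label vector over primary rows
resolve_grouping <- function(m, grouping) {
  pr <- primary_rows(m)
  if (is.character(grouping) && length(grouping) == 1L &&
      grouping %in% names(m$meta))
    return(m$meta[[grouping]][pr])
  if (length(grouping) == length(pr)) return(grouping)
  if (length(grouping) == nrow(m$calls)) return(grouping[pr])
  stop("grouping must be a metadata column name or a per-sample vector")
}

#' Gene diversity for dominant markers
#'
#' Per-locus expected heterozygosity `2q(1-q)` from estimated allele
#' frequencies. `HJ` (Nei's gene diversity) uses the mean of the
#' per-population allele-frequency estimates (Nei's total-diversity
#' convention, so two populations fixed for alternative alleles contribute
#' 0.5); `HS` (average gene diversity within populations) averages the
#' per-population heterozygosities over populations, then loci.
#'
#' @param m a [marker_matrix()].
#' @param grouping populations (metadata column name or label vector).
#' @param method allele-frequency estimator.
#' @return list with `HJ`, `HS`, `n_polymorphic`, `n_loci`, `n` (samples).
#' @export
gene_diversity <- function(m, grouping, method = "zhivotovsky") {
  pr <- primary_rows(m)
  calls <- m$calls[pr, , drop = FALSE]
  groups <- resolve_grouping(m, grouping)
  if (length(groups) == 0 || all(is.na(groups))) stop("empty grouping")
  if (!any(table(groups) >= 2)) stop("need >= 1 population with >= 2 samples")
  gc <- group_absent_counts(calls, groups)
  L <- ncol(calls)
  q <- matrix(estimate_allele_freq(as.vector(gc$k), rep(gc$n, L), method),
              nrow(gc$k), L)
  qbar <- colMeans(q)
  HJ <- mean(2 * qbar * (1 - qbar))
  he_pop <- 2 * q * (1 - q)
  HS <- mean(colMeans(he_pop))
  pres <- colSums(calls)
  n_poly <- sum(pres > 0 & pres < nrow(calls))
  list(HJ = HJ, HS = HS, n_polymorphic = n_poly, n_loci = L,
       n = nrow(calls))
}

#' Trimmed mean of locus FST values
#'
#' Mean of the central mass of sorted per-locus FST estimates after
#' discarding the highest and lowest `trim` fraction, used to seed the
#' neutral envelope simulation so outlier loci do not inflate the null.
#' Negative estimates are retained (the trimming handles the tails); NAs are
#' dropped first.
#'
#' @param per_locus_fst numeric vector of locus FST estimates.
#' @param trim fraction (< 0.5) discarded from each tail; default 0.30.
#' @return the trimmed mean.
#' @export
trimmed_mean_fst <- function(per_locus_fst, trim = 0.30) {
  if (trim < 0 || trim >= 0.5) stop("trim must lie in [0, 0.5)")
  x <- sort(per_locus_fst[!is.na(per_locus_fst)])
  n <- length(x)
  if (n < 4 / (1 - 2 * trim)) stop("too few loci for this trim fraction")
  k <- floor(n * trim)
  mean(x[(k + 1):(n - k)])
}
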