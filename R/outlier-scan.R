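# simulate one neutral (He, FST) cloud at Balding-Nichols parameter F
sim_fst_cloud <- function(F, sample_sizes, n_loci, method = "zhivotovsky") {
  p0 <- stats::runif(n_loci, 0.01, 0.99)
  p1 <- rbn(n_loci, p0, F)
  p2 <- rbn(n_loci, p0, F)
  k1 <- stats::rbinom(n_loci, sample_sizes[1], (1 - p1)^2)
  k2 <- stats::rbinom(n_loci, sample_sizes[2], (1 - p2)^2)
  comp <- fst_components(rbind(k1, k2), sample_sizes, method)
  fst <- ifelse(comp$den > 0, comp$num / comp$den, NA_real_)
  pooled_q <- estimate_allele_freq(k1 + k2, sum(sample_sizes), method)
  data.frame(He = 2 * pooled_q * (1 - pooled_q), fst = fst)
}

#' Calibrate the neutral-simulation parameter to a trimmed-mean FST
#'
#' The per-locus FST estimates that feed the empirical trimmed mean are
#' biased at finite sample sizes, so the divergence parameter of the
#' neutral simulation cannot be set to the trimmed mean directly. This
#' bisects on the Balding-Nichols `F` until the trimmed mean of the
#' simulated per-locus estimates (computed with the same estimator and
#' sample sizes) matches the observed trimmed mean.
#'
#' @param trimmed_target observed trimmed-mean locus FST.
#' @param sample_sizes length-2 individuals per group.
#' @param trim trimming fraction used for the target.
#' @param n_pilot loci per pilot simulation.
#' @param seed RNG seed.
#' @param method allele-frequency estimator.
#' @return the calibrated `F` (always within (0, 0.95]).
#' @export
calibrate_envelope_seed <- function(trimmed_target, sample_sizes,
                                    trim = 0.30, n_pilot = 20000L,
                                    seed = NULL, method = "zhivotovsky") {
  local_seed(seed)
  lo <- 1e-4
  hi <- 0.95
  if (trimmed_target <= 0) return(1e-3)
  sim_tm <- function(F)
    trimmed_mean_fst(sim_fst_cloud(F, sample_sizes, n_pilot,
                                   method)$fst, trim)
  for (it in 1:12) {
    mid <- sqrt(lo * hi)
    if (sim_tm(mid) > trimmed_target) hi <- mid else lo <- mid
  }
  sqrt(lo * hi)
}

#' Simulate a neutral (He, FST) envelope for an outlier scan
#'
#' FDist-style null distribution: each simulated locus draws an ancestral
#' presence-allele frequency from Uniform(0.01, 0.99), gives each of two
#' sampled demes a frequency from the Balding-Nichols beta with
#' `F = target_fst` (the trimmed-mean seed), samples dominant phenotypes at
#' the empirical sample sizes, and computes (He, FST) with the same
#' estimators as [fst_dominant()]. The cloud is reduced to conditional
#' quantile curves: equal-occupancy He bins with per-bin 50/95/99% FST
#' quantiles.
#'
#' The Balding-Nichols draw stands in for a coalescent island simulation;
#' it has the matching stationary frequency distribution for the purpose of
#' conditional-quantile envelopes. `n_demes` records the nominal island
#' count of the model the seed FST refers to; the sampled demes are the two
#' compared.
#'
#' @param target_fst trimmed-mean FST seeding the null (0 < F < 1).
#' @param sample_sizes length-2 individuals per compared group.
#' @param n_sim_loci simulated loci (default 50000).
#' @param n_demes nominal deme count (metadata; see Details).
#' @param seed RNG seed; envelopes are deterministic given the seed.
#' @param n_bins He bins (default adaptive, >= 20); at least 50 simulated
#'   loci per bin are required.
#' @param method allele-frequency estimator.
#' @param keep_cloud retain the raw (He, FST) points.
#' @return object of class `neutral_envelope`: `bins` (data.frame `he_lo,
#'   he_hi, q50, q95, q99, n`), `params`, optional `cloud`.
#' @export
simulate_neutral_envelope <- function(target_fst, sample_sizes,
                                      n_sim_loci = 50000L, n_demes = 100L,
                                      seed = NULL, n_bins = NULL,
                                      method = "zhivotovsky",
                                      keep_cloud = FALSE) {
  if (!(target_fst > 0 && target_fst < 1))
    stop("target_fst must lie in (0,1)")
  if (length(sample_sizes) != 2L || any(sample_sizes < 2))
    stop("two sample sizes >= 2 required")
  if (is.null(n_bins))
    n_bins <- max(20L, min(50L, floor(n_sim_loci / 1000L)))
  if (n_sim_loci < 50L * n_bins)
    stop("n_sim_loci too small for ", n_bins, " bins at >= 50 loci per bin")
  local_seed(seed)
  cloud <- sim_fst_cloud(target_fst, sample_sizes, n_sim_loci, method)
  ok <- !is.na(cloud$fst)
  he <- cloud$He[ok]
  fst <- cloud$fst[ok]
  br <- unique(stats::quantile(he, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(he, br, include.lowest = TRUE, labels = FALSE)
  qs <- function(i, p) unname(stats::quantile(fst[bin == i], p, type = 7))
  bins <- data.frame(
    he_lo = br[-length(br)], he_hi = br[-1],
    q50 = vapply(seq_along(br[-1]), qs, 0, p = 0.50),
    q95 = vapply(seq_along(br[-1]), qs, 0, p = 0.95),
    q99 = vapply(seq_along(br[-1]), qs, 0, p = 0.99),
    n = as.vector(table(factor(bin, seq_along(br[-1])))))
  rownames(bins) <- NULL
  out <- list(bins = bins,
              params = list(target_fst = target_fst,
                            sample_sizes = sample_sizes,
                            n_sim_loci = n_sim_loci, n_demes = n_demes,
                            seed = seed, method = method))
  if (keep_cloud) out$cloud <- data.frame(He = he, fst = fst)
  class(out) <- "neutral_envelope"
  out
}

#' @export
print.neutral_envelope <- function(x, ...) {
  cat(sprintf("neutral_envelope: %d bins from %d simulated loci (seed FST %.4f)\n",
              nrow(x$bins), x$params$n_sim_loci, x$params$target_fst))
  invisible(x)
}

# bin index for empirical He values (nearest bin outside the covered range)
envelope_bin <- function(env, he) {
  lo <- env$bins$he_lo; hi <- env$bins$he_hi
  idx <- findInterval(he, c(lo, hi[length(hi)]), all.inside = TRUE)
  pmin(pmax(idx, 1L), nrow(env$bins))
}

#' Classify empirical loci against a neutral envelope
#'
#' Assigns each locus the outlier level `"none"`, `"95"` or `"99"` by
#' comparing its FST to the conditional quantiles of its He bin.
#'
#' @param locus_stats data.frame with columns `locus`, `He`, `fst` (e.g. the
#'   `per_locus` element of [fst_dominant()]).
#' @param envelope a [simulate_neutral_envelope()] result.
#' @param comparison label recorded on each call (e.g. `"combined"`,
#'   `"NC"`).
#' @return data.frame `locus, comparison, He, fst, level`.
#' @export
classify_outliers <- function(locus_stats, envelope, comparison = "combined") {
  stopifnot(inherits(envelope, "neutral_envelope"))
  if (nrow(locus_stats) == 0) stop("empty locus stats")
  b <- envelope_bin(envelope, locus_stats$He)
  q95 <- envelope$bins$q95[b]
  q99 <- envelope$bins$q99[b]
  fst <- locus_stats$fst
  level <- ifelse(is.na(fst), "none",
           ifelse(fst > q99, "99", ifelse(fst > q95, "95", "none")))
  data.frame(locus = locus_stats$locus, comparison = comparison,
             He = locus_stats$He, fst = fst, level = level,
             stringsAsFactors = FALSE)
}

#' Consensus outliers across independent comparisons
#'
#' Loci flagged at the 95% level or above in at least `min_comparisons`
#' independent comparisons; repeated identification across locations is
#' treated as the robustness criterion.
#'
#' @param calls row-bound output of [classify_outliers()] over >= 2
#'   comparisons.
#' @param min_comparisons minimum number of flagging comparisons.
#' @return character vector of locus ids.
#' @export
consensus_outliers <- function(calls, min_comparisons = 2L) {
  if (length(unique(calls$comparison)) < 2)
    stop("need calls from >= 2 comparisons")
  sig <- calls[calls$level %in% c("95", "99"), , drop = FALSE]
  tab <- tapply(sig$comparison, sig$locus,
                function(x) length(unique(x)))
  sort(names(tab)[tab >= min_comparisons])
}

#' Nested outlier counts for a scan report
#'
#' Exposes the four nested counts a multi-comparison scan reports: loci
#' flagged anywhere, flagged in multiple comparisons, flagged in the
#' combined (all-populations) comparison, and the robust set (combined and
#' multiple).
#'
#' @param calls row-bound [classify_outliers()] output.
#' @param combined label of the combined comparison.
#' @return list `n_any, n_multiple, n_combined, n_robust` plus the locus id
#'   sets.
#' @export
outlier_report <- function(calls, combined = "combined") {
  sig <- calls[calls$level %in% c("95", "99"), , drop = FALSE]
  any_ids <- sort(unique(sig$locus))
  tab <- tapply(sig$comparison, sig$locus, function(x) length(unique(x)))
  multi_ids <- sort(names(tab)[tab >= 2])
  comb_ids <- sort(unique(sig$locus[sig$comparison == combined]))
  robust_ids <- intersect(comb_ids, multi_ids)
  list(n_any = length(any_ids), n_multiple = length(multi_ids),
       n_combined = length(comb_ids), n_robust = length(robust_ids),
       any = any_ids, multiple = multi_ids, combined = comb_ids,
       robust = robust_ids)
}

#' Plot an outlier scan (cloud and envelope curves)
#'
#' @param calls [classify_outliers()] output for one comparison.
#' @param envelope the [simulate_neutral_envelope()] used.
#' @param ... passed to [plot()].
#' @return invisibly, NULL.
#' @export
plot_outlier_scan <- function(calls, envelope, ...) {
  mid <- (envelope$bins$he_lo + envelope$bins$he_hi) / 2
  col <- ifelse(calls$level == "99", "red",
         ifelse(calls$level == "95", "orange", "grey40"))
  plot(calls$He, calls$fst, col = col, pch = 16,
       xlab = "expected heterozygosity (He)", ylab = "locus FST", ...)
  graphics::lines(mid, envelope$bins$q95, lty = 2)
  graphics::lines(mid, envelope$bins$q99, lty = 3)
  graphics::legend("topright", c("95% envelope", "99% envelope"),
                   lty = c(2, 3), bty = "n")
  invisible(NULL)
}
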