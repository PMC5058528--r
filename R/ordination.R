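#' Jaccard distance matrix between dominant genotypes
#'
#' `d(i,j) = 1 - |presence_i intersect presence_j| / |presence_i union
#' presence_j|`: the distance is based only on shared band presence, the
#' appropriate choice for dominant markers. Sample pairs with an empty
#' union are undefined and raise an error (all-zero samples should be
#' filtered upstream).
#'
#' @param m a [marker_matrix()] (replicate rows excluded).
#' @return a `dist` object labelled by sample id, with attribute
#'   `metric = "jaccard"`.
#' @export
jaccard_matrix <- function(m) {
  calls <- m$calls[primary_rows(m), , drop = FALSE]
  if (any(rowSums(calls) == 0))
    stop("all-zero sample row(s): ",
         paste(rownames(calls)[rowSums(calls) == 0], collapse = ", "))
  d <- vegan::vegdist(calls, method = "jaccard", binary = TRUE)
  attr(d, "metric") <- "jaccard"
  d
}

#' Nonmetric multidimensional scaling with Kruskal stress
#'
#' Monotone-regression NMDS minimising Kruskal stress-1, taking the best of
#' several random restarts (the first start is a classical metric-scaling
#' configuration). Stress is reported as a fraction.
#'
#' @param d a `dist` object (e.g. [jaccard_matrix()]).
#' @param k embedding dimension.
#' @param n_restarts random restarts.
#' @param max_iter iteration cap per restart.
#' @param seed RNG seed.
#' @return list of class `ordination_result`: `scores` (n x k, centred),
#'   `stress` (fraction), `converged`, `k`, `n_restarts`.
#' @export
nmds <- function(d, k = 2L, n_restarts = 20L, max_iter = 200L,
                 seed = NULL) {
  n <- attr(d, "Size")
  if (n < k + 2) stop("need at least k + 2 samples")
  local_seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                        maxit = max_iter, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  scores <- scale(fit$points, center = TRUE, scale = FALSE)
  structure(list(scores = scores, stress = fit$stress,
                 converged = isTRUE(fit$converged) || fit$converged > 0,
                 k = k, n_restarts = n_restarts),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("NMDS: k = %d, Kruskal stress-1 = %.4f (%.1f%%)\n",
              x$k, x$stress, 100 * x$stress))
  invisible(x)
}

#' Fit a categorical factor to ordination scores by permutation
#'
#' Goodness of fit `R^2 = 1 - SS_within-centroids / SS_total` on the score
#' matrix, with the p-value from permutations of the factor labels.
#'
#' @param ord an [nmds()] result (or any list with a `scores` matrix).
#' @param fac factor (or vector) over the ordinated samples.
#' @param n_perm label permutations.
#' @param seed RNG seed.
#' @return list `r2, p, n_perm`.
#' @export
fit_factor <- function(ord, fac, n_perm = 5000L, seed = NULL) {
  X <- ord$scores
  fac <- as.factor(fac)
  if (length(fac) != nrow(X)) stop("factor length must match sample count")
  if (nlevels(droplevels(fac)) < 2) stop("factor needs >= 2 levels")
  r2_of <- function(f) {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    ss_tot <- sum(Xc^2)
    ss_w <- 0
    for (lv in levels(f)) {
      rows <- which(f == lv)
      if (length(rows) == 0) next
      cen <- colMeans(X[rows, , drop = FALSE])
      ss_w <- ss_w + sum(sweep(X[rows, , drop = FALSE], 2, cen)^2)
    }
    1 - ss_w / ss_tot
  }
  obs <- r2_of(fac)
  local_seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (r2_of(sample(fac)) >= obs) exceed <- exceed + 1L
  }
  list(r2 = obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

#' Distance-based permutational MANOVA (adonis)
#'
#' Sequential partitioning of squared inter-point distances among factor
#' terms via the Gower-centred distance matrix (McArdle-Anderson), with
#' pseudo-F significance from permutations of the raw observations --
#' restricted to within-stratum permutations when `strata` is given (the
#' permutation scheme for nested designs such as host within location).
#'
#' @param d a `dist` object over the samples.
#' @param data data.frame of sample covariates (rows match `d`).
#' @param rhs model right-hand side as a character string, e.g.
#'   `"location + host"` or `"location/host"` for nesting.
#' @param strata optional column name in `data`; permutations are then
#'   performed freely within each stratum.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return the `adonis2` table (`Df, SumOfSqs, R2, F, Pr(>F)`) with one row
#'   per term plus residual and total; term and residual `R2` sum to 1.
#' @export
adonis_partition <- function(d, data, rhs, strata = NULL, n_perm = 5000L,
                             seed = NULL) {
  local_seed(seed)
  perm <- if (is.null(strata)) n_perm
          else permute::how(blocks = as.factor(data[[strata]]),
                            nperm = n_perm)
  f <- stats::as.formula(paste("d ~", rhs))
  env <- list2env(list(d = d))
  environment(f) <- env
  vegan::adonis2(f, data = data, permutations = perm, by = "terms")
}
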