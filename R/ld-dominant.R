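# Two-locus gametic disequilibrium from dominant phenotypes.
#
# At two dominant biallelic loci only four phenotype classes are observable
# (band present/absent at A x present/absent at B). Under random union of
# gametes with haplotype frequencies h = (hAB, hAb, haB, hab) (uppercase =
# band-presence allele), the class probabilities are
#   P(absent, absent)  = hab^2
#   P(absent, present) = (haB + hab)^2 - hab^2
#   P(present, absent) = (hAb + hab)^2 - hab^2
#   P(present, present) = 1 - qa^2 - qb^2 + hab^2,
# with qa = haB + hab, qb = hAb + hab the null-allele frequencies. The MLE
# of h is found by EM over the latent gamete pairs.

# class probabilities for a batch: h is an m x 4 matrix (hAB,hAb,haB,hab)
ld_class_probs <- function(h) {
  qa <- h[, 3] + h[, 4]
  qb <- h[, 2] + h[, 4]
  p_aa <- h[, 4]^2
  p_ap <- qa^2 - p_aa
  p_pa <- qb^2 - p_aa
  p_pp <- 1 - qa^2 - qb^2 + p_aa
  cbind(pp = p_pp, pa = p_pa, ap = p_ap, aa = p_aa)
}

# multinomial log-likelihood (no combinatorial constant); counts m x 4
# in column order (n_pp, n_pa, n_ap, n_aa)
ld_loglik <- function(h, counts) {
  pr <- pmax(ld_class_probs(h), 1e-300)
  rowSums(counts * log(pr))
}

# one EM step for a batch of tables; returns updated h
ld_em_step <- function(h, counts) {
  hAB <- h[, 1]; hAb <- h[, 2]; haB <- h[, 3]; hab <- h[, 4]
  qa <- haB + hab
  qb <- hAb + hab
  p_aa <- hab^2
  p_ap <- pmax(qa^2 - p_aa, 1e-300)
  p_pa <- pmax(qb^2 - p_aa, 1e-300)
  p_pp <- pmax(1 - qa^2 - qb^2 + p_aa, 1e-300)
  n <- rowSums(counts)
  # expected haplotype counts per individual within each phenotype class
  # (derived by restricting the iid gamete pair to the class support)
  e_ap_aB <- 2 * (haB + hab) / (haB + 2 * hab + 1e-300) # class (a-, B+)
  e_ap_ab <- 2 - e_ap_aB
  e_pa_Ab <- 2 * (hAb + hab) / (hAb + 2 * hab + 1e-300) # class (A+, b-)
  e_pa_ab <- 2 - e_pa_Ab
  e_pp_AB <- 2 * hAB / p_pp
  e_pp_Ab <- 2 * hAb * (1 - qb) / p_pp
  e_pp_aB <- 2 * haB * (1 - qa) / p_pp
  e_pp_ab <- 2 * hab * (1 - qa - qb + hab) / p_pp
  cAB <- counts[, 1] * e_pp_AB
  cAb <- counts[, 1] * e_pp_Ab + counts[, 2] * e_pa_Ab
  caB <- counts[, 1] * e_pp_aB + counts[, 3] * e_ap_aB
  cab <- counts[, 1] * e_pp_ab + counts[, 2] * e_pa_ab +
         counts[, 3] * e_ap_ab + counts[, 4] * 2
  hn <- cbind(cAB, cAb, caB, cab) / (2 * n)
  hn / rowSums(hn)
}

# independence-model fit for a batch: h0, lnL0 (closed form)
ld_independence_fit <- function(counts) {
  n <- rowSums(counts)
  qa <- sqrt((counts[, 3] + counts[, 4]) / n)
  qb <- sqrt((counts[, 2] + counts[, 4]) / n)
  pA <- 1 - qa; pB <- 1 - qb
  h0 <- cbind(pA * pB, pA * qb, qa * pB, qa * qb)
  list(h0 = h0, lnL0 = ld_loglik(h0, counts))
}

# batched multi-start EM; counts is m x 4 (pp, pa, ap, aa).
# Returns list(h, lnL, converged, h0, lnL0).
ld_em_batch <- function(counts, tol = 1e-10, max_iter = 10000L,
                        starts = 5L) {
  counts <- matrix(as.numeric(counts), ncol = 4)
  m <- nrow(counts)
  ind <- ld_independence_fit(counts)
  corners <- diag(4)
  best_h <- ind$h0
  best_l <- rep(-Inf, m)
  conv <- rep(FALSE, m)
  for (s in seq_len(max(1L, starts))) {
    h <- if (s == 1L) ind$h0
         else 0.2 * ind$h0 +
              0.8 * matrix(corners[((s - 2L) %% 4L) + 1L, ], m, 4,
                           byrow = TRUE)
    h <- pmax(h, 1e-9)
    h <- h / rowSums(h)
    l <- ld_loglik(h, counts)
    active <- rep(TRUE, m)
    this_conv <- rep(FALSE, m)
    for (it in seq_len(max_iter)) {
      ia <- which(active)
      if (length(ia) == 0) break
      hn <- ld_em_step(h[ia, , drop = FALSE], counts[ia, , drop = FALSE])
      ln <- ld_loglik(hn, counts[ia, , drop = FALSE])
      done <- abs(ln - l[ia]) < tol
      h[ia, ] <- hn
      l[ia] <- ln
      this_conv[ia[done]] <- TRUE
      active[ia[done]] <- FALSE
    }
    better <- l > best_l
    best_h[better, ] <- h[better, , drop = FALSE]
    best_l[better] <- l[better]
    conv <- conv | this_conv
  }
  list(h = best_h, lnL = best_l, converged = conv,
       h0 = ind$h0, lnL0 = ind$lnL0)
}

#' ML haplotype frequencies and D for two dominant loci
#'
#' Fits the four gamete frequencies by multi-start EM (independence start
#' plus corner-biased starts, since the dominant-data likelihood can be flat
#' or multimodal at small n), together with the constrained independence fit
#' (D = 0), whose MLE is closed-form from the marginal absence counts. The
#' EM likelihood is non-decreasing at every step.
#'
#' @param table named counts `c(n_pp, n_pa, n_ap, n_aa)`: individuals with
#'   band present/absent at locus A x locus B (in that order), or an unnamed
#'   length-4 vector in that order.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per start.
#' @param starts number of EM starts.
#' @return list of class `ld_result`: `h` (named MLE frequencies `hAB, hAb,
#'   haB, hab`), `D`, `lnL`, `lnL0` (independence fit), `converged`, `n`.
#' @export
em_haplotype_freqs_dominant <- function(table, tol = 1e-10,
                                        max_iter = 10000L, starts = 5L) {
  cn <- c("n_pp", "n_pa", "n_ap", "n_aa")
  if (!is.null(names(table)) && all(cn %in% names(table)))
    table <- table[cn]
  if (length(table) != 4L || any(table < 0)) stop("need 4 non-negative counts")
  n <- sum(table)
  if (n < 2) stop("need n >= 2 individuals")
  fit <- ld_em_batch(matrix(table, 1, 4), tol, max_iter, starts)
  h <- as.vector(fit$h)
  names(h) <- c("hAB", "hAb", "haB", "hab")
  D <- h[["hAB"]] - (h[["hAB"]] + h[["hAb"]]) * (h[["hAB"]] + h[["haB"]])
  structure(list(h = h, D = D, lnL = fit$lnL, lnL0 = fit$lnL0,
                 converged = fit$converged, n = n),
            class = "ld_result")
}

#' Likelihood-ratio test of gametic disequilibrium
#'
#' The statistic `2 (lnL_MLE - lnL_{D=0})` is referred to a chi-square
#' distribution with one degree of freedom (an approximation that is also
#' used when the MLE sits on the frequency-simplex boundary).
#'
#' @param result an `ld_result` from [em_haplotype_freqs_dominant()].
#' @return list with `statistic` and `p`.
#' @export
ld_test <- function(result) {
  if (!isTRUE(result$converged))
    stop("LD test requires a converged EM fit")
  stat <- 2 * (result$lnL - result$lnL0)
  if (stat < -1e-8)
    stop("likelihood-ratio statistic negative beyond tolerance: EM ascent failure")
  stat <- max(stat, 0)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' False discovery rate adjustment
#'
#' `bh` is the Benjamini-Hochberg step-up adjustment. `pike_robust` is the
#' adaptive variant recommended for ecological multiple-testing: the number
#' of true nulls `m0` is first estimated by the lowest-slope method
#' (slopes `(1 - p_(i)) / (m + 1 - i)` scanned until they first decrease),
#' and the step-up adjustment then uses `m0` in place of `m`.
#'
#' @param pvals numeric p-values in `[0,1]`.
#' @param method `"bh"` or `"pike_robust"`.
#' @return monotone adjusted q-values, same length/order as `pvals`.
#' @export
fdr_adjust <- function(pvals, method = c("bh", "pike_robust")) {
  method <- match.arg(method)
  if (length(pvals) == 0) stop("empty p-value list")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0,1]")
  if (method == "bh") return(stats::p.adjust(pvals, method = "BH"))
  m <- length(pvals)
  ps <- sort(pvals)
  sl <- (1 - ps) / (m + 1 - seq_len(m))
  j <- which(diff(sl) < 0)
  m0 <- if (length(j) == 0) m else min(m, ceiling(1 / sl[j[1] + 1]) + 1)
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m0 * pvals[o] / rank(pvals, ties.method = "max")[o]))[ro]
  q
}

#' Pairwise LD scan over a marker matrix
#'
#' Fits the dominant-phenotype LD model to locus pairs and reports D, the
#' likelihood-ratio statistic, p, and FDR-adjusted q per pair.
#'
#' @param m a [marker_matrix()] (replicate rows excluded).
#' @param pairs `"all"` for every pair, or `"same_size_cross_primer"` for
#'   the duplicate-marker candidates used by QC rule 3 (equal fragment size,
#'   different primer pair).
#' @param fdr_method passed to [fdr_adjust()].
#' @param tol,max_iter,starts EM controls.
#' @return data.frame `locusA, locusB, D, LR, p, q, converged`.
#' @export
ld_scan <- function(m, pairs = c("all", "same_size_cross_primer"),
                    fdr_method = "bh", tol = 1e-10, max_iter = 10000L,
                    starts = 5L) {
  pairs <- match.arg(pairs)
  calls <- m$calls[primary_rows(m), , drop = FALSE]
  L <- ncol(calls)
  if (pairs == "all") {
    idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  } else {
    idx <- NULL
    sz <- m$loci$size_bp
    for (s in unique(sz[duplicated(sz)])) {
      grp <- which(sz == s)
      cand <- which(upper.tri(matrix(0, length(grp), length(grp))),
                    arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ab <- cbind(grp[cand[, 1]], grp[cand[, 2]])
        keep <- m$loci$primer[ab[, 1]] != m$loci$primer[ab[, 2]]
        if (any(keep)) idx <- rbind(idx, ab[keep, , drop = FALSE])
      }
    }
    if (is.null(idx) || nrow(idx) == 0)
      return(data.frame(locusA = character(), locusB = character(),
                        D = numeric(), LR = numeric(), p = numeric(),
                        q = numeric(), converged = logical()))
  }
  A <- calls[, idx[, 1], drop = FALSE]
  B <- calls[, idx[, 2], drop = FALSE]
  n_pp <- colSums(A == 1 & B == 1)
  n_pa <- colSums(A == 1 & B == 0)
  n_ap <- colSums(A == 0 & B == 1)
  n_aa <- colSums(A == 0 & B == 0)
  counts <- cbind(n_pp, n_pa, n_ap, n_aa)
  fit <- ld_em_batch(counts, tol, max_iter, starts)
  D <- fit$h[, 1] - (fit$h[, 1] + fit$h[, 2]) * (fit$h[, 1] + fit$h[, 3])
  LR <- pmax(2 * (fit$lnL - fit$lnL0), 0)
  p <- stats::pchisq(LR, df = 1, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  ok <- fit$converged
  if (any(ok)) q[ok] <- fdr_adjust(p[ok], fdr_method)
  data.frame(locusA = m$loci$locus[idx[, 1]],
             locusB = m$loci$locus[idx[, 2]],
             D = D, LR = LR, p = p, q = q, converged = ok,
             stringsAsFactors = FALSE)
}
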