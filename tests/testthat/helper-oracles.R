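# Independent oracles and small fixture builders used across test files.
# Everything here is deliberately written by brute force / first principles,
# separate from the package's implementation paths.

# --- small marker-matrix builder -------------------------------------------
toy_matrix <- function(calls, host = NULL, location = "loc1",
                       sex = NULL, replicate_of = NULL, sizes = NULL,
                       primer = NULL) {
  n <- nrow(calls)
  L <- ncol(calls)
  meta <- data.frame(
    sample_id = sprintf("T%02d", seq_len(n)),
    host = host %||% rep(c("glabra", "coriacea"), length.out = n),
    location = rep(location, length.out = n),
    sex = sex %||% rep(c("F", "M"), length.out = n),
    year = 2008L,
    replicate_of = replicate_of %||% rep(NA_character_, n),
    stringsAsFactors = FALSE)
  sizes <- sizes %||% (100 + seq_len(L))
  loci <- data.frame(locus = sprintf("L%d_%d", sizes, seq_len(L)),
                     size_bp = sizes,
                     primer = primer %||% rep("P1", L),
                     stringsAsFactors = FALSE)
  m <- marker_matrix(calls, meta, loci)
  m$log <- data.frame(rule = "scored", removed = 0L, retained = L)
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# --- grid-search oracle for the dominant two-locus LD likelihood ----------
# profiles the 3 free parameters (qa, qb, hab) on a nested refined grid;
# independent of the package's EM path
ld_grid_oracle <- function(counts) {
  loglik <- function(qa, qb, hab) {
    p_aa <- hab^2
    p_ap <- qa^2 - p_aa
    p_pa <- qb^2 - p_aa
    p_pp <- 1 - qa^2 - qb^2 + p_aa
    pr <- cbind(p_pp, p_pa, p_ap, p_aa)
    pr[pr < 1e-300] <- 1e-300
    as.vector(log(pr) %*% counts)
  }
  best <- c(0.5, 0.5, 0.25)
  bl <- -Inf
  step <- 0.02
  for (lev in 1:4) {
    qa_grid <- seq(max(0, best[1] - 25 * step),
                   min(1, best[1] + 25 * step), by = step)
    qb_grid <- seq(max(0, best[2] - 25 * step),
                   min(1, best[2] + 25 * step), by = step)
    for (a in qa_grid) for (b in qb_grid) {
      hlo <- max(0, a + b - 1)
      hhi <- min(a, b)
      if (lev > 1) {
        hlo <- max(hlo, best[3] - 25 * step)
        hhi <- min(hhi, best[3] + 25 * step)
      }
      if (hhi < hlo) next
      hs <- if (lev == 1) seq(hlo, hhi, length.out = 51)
            else seq(hlo, hhi, by = step)
      if (length(hs) == 0) next
      ll <- loglik(rep(a, length(hs)), rep(b, length(hs)), hs)
      j <- which.max(ll)
      if (ll[j] > bl) {
        bl <- ll[j]
        best <- c(a, b, hs[j])
      }
    }
    step <- step / 10
  }
  qa <- best[1]; qb <- best[2]; hab <- best[3]
  D <- (1 - qa - qb + hab) - (1 - qa) * (1 - qb)
  list(lnL = bl, qa = qa, qb = qb, hab = hab, D = D)
}

# random dominant phenotype table drawn from random haplotype frequencies
random_ld_table <- function(n = 100) {
  h <- as.vector(stats::rmultinom(1, 40, rep(1, 4))) / 40 + 0.01
  h <- h / sum(h)
  qa <- h[3] + h[4]
  qb <- h[2] + h[4]
  pr <- c(1 - qa^2 - qb^2 + h[4]^2, qb^2 - h[4]^2, qa^2 - h[4]^2, h[4]^2)
  as.vector(stats::rmultinom(1, n, pr))
}

# --- brute-force sequence statistics ---------------------------------------
# mean pairwise difference per site over haplotype copies (strings)
oracle_pi <- function(copies, L) {
  n <- length(copies)
  if (n < 2) return(0)
  tot <- 0
  cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(copies[i], "")[[1]]
    b <- strsplit(copies[j], "")[[1]]
    tot <- tot + sum(a != b)
    cnt <- cnt + 1
  }
  tot / cnt / L
}

oracle_hd <- function(copies) {
  n <- length(copies)
  fr <- as.vector(table(copies)) / n
  n / (n - 1) * (1 - sum(fr^2))
}

# F84 distance closed form (PHYLIP dnadist parameterisation), base
# frequencies estimated from the sequence pair, pairwise deletion
oracle_f84 <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  freq <- table(factor(c(a, b), levels = c("A", "C", "G", "T"))) / (2 * n)
  pa <- freq[["A"]]; pc <- freq[["C"]]; pg <- freq[["G"]]; pt <- freq[["T"]]
  pr <- pa + pg; py <- pc + pt
  diff <- a != b
  ts <- sum(diff & ((a %in% c("A", "G") & b %in% c("A", "G")) |
                    (a %in% c("C", "T") & b %in% c("C", "T"))))
  P <- ts / n
  Q <- (sum(diff) - ts) / n
  A <- pc * pt / py + pa * pg / pr
  B <- pc * pt + pa * pg
  C <- pr * py
  -2 * A * log(1 - P / (2 * A) - (A - B) * Q / (2 * A * C)) +
    2 * (A - B - C) * log(1 - Q / (2 * C))
}

# brute-force AMOVA Phi_ST from a squared-distance matrix (explicit sums)
oracle_phi <- function(d2, groups) {
  N <- nrow(d2)
  ss_t <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) ss_t <- ss_t + d2[i, j]
  ss_t <- ss_t / N
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    s <- 0
    if (length(idx) > 1) {
      for (i in 1:(length(idx) - 1)) for (j in (i + 1):length(idx))
        s <- s + d2[idx[i], idx[j]]
    }
    ss_w <- ss_w + s / length(idx)
  }
  G <- length(unique(groups))
  sw <- ss_w / (N - G)
  msa <- (ss_t - ss_w) / (G - 1)
  n0 <- (N - sum(table(groups)^2) / N) / (G - 1)
  sa <- (msa - sw) / n0
  sa / (sa + sw)
}

# brute-force McArdle-Anderson pseudo-F for a one-factor design
oracle_pseudo_f <- function(d, groups) {
  D <- as.matrix(d)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  X <- stats::model.matrix(~ as.factor(groups))
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  ss_a <- sum(diag(H %*% G %*% H))
  ss_r <- sum(diag((diag(n) - H) %*% G %*% (diag(n) - H)))
  dfa <- length(unique(groups)) - 1
  dfr <- n - length(unique(groups))
  (ss_a / dfa) / (ss_r / dfr)
}

# small diploid alignment builder from explicit haplotype pairs
toy_alignment <- function(pairs, host = NULL, frame_offset = 0L) {
  n <- length(pairs)
  seqs <- vapply(pairs, function(p) {
    a <- strsplit(p[1], "")[[1]]
    b <- strsplit(p[2], "")[[1]]
    paste(hostscan:::iupac_code(a, b), collapse = "")
  }, "")
  meta <- data.frame(sample_id = sprintf("A%02d", seq_len(n)),
                     host = host %||% rep(c("glabra", "coriacea"),
                                          length.out = n),
                     location = "loc1", stringsAsFactors = FALSE)
  diploid_alignment(seqs, meta, frame_offset)
}

# --- # haplotypes evolved under an infinite-sites (perfect phylogeny) process:
# each polymorphic site arises once, so pairwise distances are tree-additive
random_perfect_phylogeny <- function(n_haps = 8, n_sites = 24) {
  M <- matrix("A", 1, n_sites)
  free <- seq_len(n_sites)
  while (nrow(M) < n_haps && length(free) >= 1) {
    parent <- M[sample.int(nrow(M), 1), ]
    k <- min(length(free), sample.int(3, 1))
    mut <- sample(free, k)
    free <- setdiff(free, mut)
    parent[mut] <- "G"
    M <- rbind(M, parent)
  }
  haps <- unique(apply(M, 1, paste, collapse = ""))
  setNames(haps, paste0("h", seq_along(haps)))
}
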