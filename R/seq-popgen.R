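#' Call SNPs from a diploid IUPAC alignment
#'
#' Scans alignment columns, expanding two-base IUPAC codes into both
#' alleles. Columns containing `N` or gaps are excluded. Columns with more
#' than two alleles are reported but flagged (`biallelic = FALSE`) and are
#' excluded from phasing and haplotype statistics.
#'
#' @param aln a [diploid_alignment()].
#' @return data.frame `position, a1, a2, n1, n2, codon_pos, biallelic`
#'   (alleles ordered by descending count; `a2`/`n2` are NA for flagged
#'   columns, whose allele set is in `alleles`).
#' @export
call_snps <- function(aln) {
  stopifnot(inherits(aln, "diploid_alignment"))
  sm <- seq_matrix(aln)
  cp <- codon_positions(aln$length, aln$frame_offset)
  out <- list()
  for (j in seq_len(ncol(sm))) {
    col <- sm[, j]
    if (any(col %in% c("N", "-"))) next
    counts <- table(unlist(lapply(col, iupac_expand)))
    if (length(counts) < 2) next
    counts <- sort(counts, decreasing = TRUE)
    bi <- length(counts) == 2L
    out[[length(out) + 1L]] <- data.frame(
      position = j,
      a1 = names(counts)[1],
      a2 = if (bi) names(counts)[2] else NA_character_,
      n1 = as.integer(counts[1]),
      n2 = if (bi) as.integer(counts[2]) else NA_integer_,
      alleles = paste(names(counts), collapse = "/"),
      codon_pos = cp[j],
      biallelic = bi,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(position = integer(), a1 = character(),
                      a2 = character(), n1 = integer(), n2 = integer(),
                      alleles = character(), codon_pos = integer(),
                      biallelic = logical()))
  do.call(rbind, out)
}

# backbone: full-length consensus with SNP sites and excluded columns marked N
alignment_backbone <- function(aln, snp_pos) {
  sm <- seq_matrix(aln)
  bb <- character(ncol(sm))
  for (j in seq_len(ncol(sm))) {
    col <- unique(sm[, j])
    bb[j] <- if (length(col) == 1L && col %in% c("A", "C", "G", "T"))
      col else "N"
  }
  bb[snp_pos] <- "N"  # filled per haplotype later
  bb
}

#' EM haplotype phasing of diploid sequence genotypes
#'
#' Estimates population haplotype frequencies at the biallelic SNP columns
#' by EM over the latent gametic phase (random pairing of haplotypes), then
#' assigns each individual its most probable haplotype pair. The phasing
#' confidence is the posterior probability of that pair; individuals below
#' `conf_threshold` are marked unphased, as are individuals whose
#' heterozygous-site count exceeds `max_het` (enumeration bound).
#' Individuals with at most one heterozygous site have a unique phase and
#' confidence 1.
#'
#' @param aln a [diploid_alignment()].
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param conf_threshold minimum posterior probability to accept a phase.
#' @param max_het maximum heterozygous sites per individual for pair
#'   enumeration.
#' @return object of class `haplotype_set`: `haplotypes` (named allele
#'   strings over the SNP columns), `full_seqs` (full-length sequences),
#'   `freqs` (EM frequencies), `pairs` (data.frame `sample_id, hap1, hap2,
#'   confidence, phased`), `snp_pos`, `aln_length`, `meta`.
#' @export
em_phase <- function(aln, tol = 1e-8, max_iter = 2000L,
                     conf_threshold = 0.9, max_het = 12L) {
  stopifnot(inherits(aln, "diploid_alignment"))
  if (length(aln$seqs) < 2) stop("need >= 2 individuals")
  snps <- call_snps(aln)
  snps <- snps[snps$biallelic, , drop = FALSE]
  sm <- seq_matrix(aln)
  gt <- sm[, snps$position, drop = FALSE]
  n_ind <- nrow(gt)
  K <- ncol(gt)

  # enumerate compatible (unordered) haplotype pairs per individual;
  # the first heterozygous site is held fixed to kill mirror duplicates
  cand_pairs <- vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    het <- which(!gt[i, ] %in% c("A", "C", "G", "T"))
    if (length(het) > max_het) next
    base1 <- gt[i, ]; base2 <- gt[i, ]
    for (s in het) {
      ab <- iupac_expand(gt[i, s])
      base1[s] <- ab[1]; base2[s] <- ab[2]
    }
    if (length(het) <= 1L) {
      cand_pairs[[i]] <- cbind(paste(base1, collapse = ""),
                               paste(base2, collapse = ""))
    } else {
      flips <- het[-1]
      nf <- length(flips)
      P <- 2L^nf
      A <- matrix(base1, P, K, byrow = TRUE)
      B <- matrix(base2, P, K, byrow = TRUE)
      for (j in seq_len(nf)) {
        sw <- bitwAnd(seq_len(P) - 1L, 2L^(j - 1L)) > 0
        s <- flips[j]
        A[sw, s] <- base2[s]
        B[sw, s] <- base1[s]
      }
      cand_pairs[[i]] <- cbind(
        do.call(paste0, as.data.frame(A, stringsAsFactors = FALSE)),
        do.call(paste0, as.data.frame(B, stringsAsFactors = FALSE)))
    }
  }
  hap_levels <- sort(unique(unlist(cand_pairs)))
  H <- length(hap_levels)
  pair_idx <- lapply(cand_pairs, function(prs) {
    if (is.null(prs)) return(NULL)
    cbind(match(prs[, 1], hap_levels), match(prs[, 2], hap_levels))
  })

  # flatten the pair enumeration for vectorised EM updates
  enum_ind <- which(!vapply(pair_idx, is.null, TRUE))
  flat_ind <- unlist(lapply(enum_ind, function(i)
    rep(i, nrow(pair_idx[[i]]))))
  flat_h1 <- unlist(lapply(enum_ind, function(i) pair_idx[[i]][, 1]))
  flat_h2 <- unlist(lapply(enum_ind, function(i) pair_idx[[i]][, 2]))
  ind_fac <- factor(flat_ind, levels = enum_ind)
  mult <- ifelse(flat_h1 == flat_h2, 1, 2)

  f <- rep(1 / H, H)
  ll_old <- -Inf
  converged <- FALSE
  w <- NULL
  for (it in seq_len(max_iter)) {
    w <- mult * f[flat_h1] * f[flat_h2]
    tw <- rowsum(w, ind_fac)[, 1]
    tw <- pmax(tw, 1e-300)
    ll <- sum(log(tw))
    w <- w / tw[as.integer(ind_fac)]
    num <- rowsum(c(w, w), factor(c(flat_h1, flat_h2), levels = seq_len(H)))[, 1]
    f <- num / sum(num)
    if (abs(ll - ll_old) < tol) { ll_old <- ll; converged <- TRUE; break }
    ll_old <- ll
  }
  if (!converged) warning("phasing EM did not converge in ", max_iter,
                          " iterations")

  # most probable pair and confidence per individual. Confidence uses
  # pseudocount-smoothed frequencies: a resolution supported only by the
  # focal individual must not look certain, so haplotypes with (near-)zero
  # EM frequency keep a floor of `alpha` copies. Genuinely ambiguous
  # individuals then fall below the confidence threshold and are dropped,
  # the conservative analogue of multi-program consensus phasing.
  alpha <- 0.5
  n_copies <- 2 * length(enum_ind)
  fs <- (f * n_copies + alpha) / (n_copies + alpha * H)
  hap1 <- hap2 <- rep(NA_integer_, n_ind)
  confidence <- rep(NA_real_, n_ind)
  w <- mult * fs[flat_h1] * fs[flat_h2]
  tw <- pmax(rowsum(w, ind_fac)[, 1], 1e-300)
  w <- w / tw[as.integer(ind_fac)]
  best_row <- tapply(seq_along(w), ind_fac, function(rows)
    rows[which.max(w[rows])])
  for (k in seq_along(enum_ind)) {
    i <- enum_ind[k]
    r <- best_row[[k]]
    hap1[i] <- flat_h1[r]; hap2[i] <- flat_h2[r]
    confidence[i] <- if (nrow(pair_idx[[i]]) == 1L) 1 else w[r]
  }
  phased <- !is.na(confidence) & confidence >= conf_threshold

  # keep only haplotypes used by phased individuals; relabel by frequency
  used <- sort(unique(c(hap1[phased], hap2[phased])))
  counts <- table(factor(c(hap1[phased], hap2[phased]), levels = used))
  ord <- used[order(-as.vector(counts), hap_levels[used])]
  ids <- stats::setNames(paste0("h", seq_along(ord)), as.character(ord))
  bb <- alignment_backbone(aln, snps$position)
  full <- vapply(ord, function(k) {
    s <- bb
    s[snps$position] <- strsplit(hap_levels[k], "")[[1]]
    paste(s, collapse = "")
  }, "")
  haps <- stats::setNames(hap_levels[ord], ids)
  names(full) <- ids
  pairs <- data.frame(
    sample_id = aln$meta$sample_id,
    hap1 = ifelse(phased, ids[as.character(hap1)], NA_character_),
    hap2 = ifelse(phased, ids[as.character(hap2)], NA_character_),
    confidence = confidence, phased = phased,
    stringsAsFactors = FALSE)
  structure(list(haplotypes = haps, full_seqs = full,
                 freqs = stats::setNames(f[ord], ids),
                 pairs = pairs, snp_pos = snps$position,
                 aln_length = aln$length, meta = aln$meta,
                 loglik = ll_old, em_converged = converged),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes, %d/%d individuals phased\n",
              length(x$haplotypes), sum(x$pairs$phased), nrow(x$pairs)))
  invisible(x)
}

# haplotype copies (ids, 2 per phased individual) for a subset of samples
hap_copies <- function(haps, sample_ids = NULL) {
  p <- haps$pairs[haps$pairs$phased, , drop = FALSE]
  if (!is.null(sample_ids)) p <- p[p$sample_id %in% sample_ids, , drop = FALSE]
  c(p$hap1, p$hap2)
}

# Hudson-Kaplan minimum recombination events from distinct haplotype
# allele strings (four-gamete intervals, reduced then greedily packed)
rm_four_gamete <- function(hap_strings) {
  if (length(hap_strings) < 2) return(0L)
  M <- do.call(rbind, strsplit(hap_strings, ""))
  K <- ncol(M)
  if (K < 2) return(0L)
  iv <- NULL
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      if (length(unique(M[, i])) < 2 || length(unique(M[, j])) < 2) next
      if (length(unique(paste(M[, i], M[, j]))) == 4L)
        iv <- rbind(iv, c(i, j))
    }
  }
  if (is.null(iv)) return(0L)
  # drop intervals containing another incompatible interval
  keep <- rep(TRUE, nrow(iv))
  for (a in seq_len(nrow(iv))) {
    for (b in seq_len(nrow(iv))) {
      if (a != b && iv[b, 1] >= iv[a, 1] && iv[b, 2] <= iv[a, 2] &&
          (iv[b, 1] > iv[a, 1] || iv[b, 2] < iv[a, 2]))
        keep[a] <- FALSE
    }
  }
  iv <- iv[keep, , drop = FALSE]
  iv <- iv[order(iv[, 2]), , drop = FALSE]
  rm_count <- 0L
  last_right <- -Inf
  for (r in seq_len(nrow(iv))) {
    if (iv[r, 1] >= last_right) {
      rm_count <- rm_count + 1L
      last_right <- iv[r, 2]
    }
  }
  rm_count
}

#' Haplotype summary statistics per group
#'
#' For each group of haplotype copies (two per phased individual): `N`
#' phased samples, `H` distinct haplotypes, `p` polymorphic sites, `Sn`
#' singleton haplotypes, haplotype diversity
#' `Hd = n/(n-1) (1 - sum p_i^2)` over haplotype frequencies, nucleotide
#' diversity `pi` (mean pairwise difference per site over the alignment
#' length), and `Rm`, the four-gamete minimum number of recombination
#' events.
#'
#' @param haps a [em_phase()] result.
#' @param grouping metadata column name (default `"host"`) or label vector;
#'   `NULL` for a single total group.
#' @param include_total append a `total` row.
#' @return data.frame with one row per group: `group, N, H, p, Sn, Hd, pi,
#'   Rm`.
#' @export
haplotype_summary <- function(haps, grouping = "host",
                              include_total = TRUE) {
  stopifnot(inherits(haps, "haplotype_set"))
  groups <- if (is.null(grouping)) NULL
            else if (length(grouping) == 1L) haps$meta[[grouping]]
            else grouping
  sets <- list()
  if (!is.null(groups)) {
    for (g in sort(unique(groups)))
      sets[[g]] <- haps$meta$sample_id[groups == g]
  }
  if (include_total || is.null(groups)) sets["total"] <- list(NULL)
  out <- lapply(names(sets), function(g) {
    ids <- hap_copies(haps, sets[[g]])
    if (length(ids) < 2) stop("group '", g, "' has < 2 haplotype copies")
    n <- length(ids)
    tab <- table(ids)
    fr <- as.vector(tab) / n
    strings <- haps$haplotypes[names(tab)]
    M <- do.call(rbind, strsplit(unname(strings), ""))
    poly <- if (ncol(M) == 0) 0L else
      sum(apply(M, 2, function(col) length(unique(col))) > 1)
    # mean pairwise difference per site, over copies
    dm <- hamming_matrix(strings)
    w <- as.vector(tab)
    tot_pairs <- n * (n - 1) / 2
    sum_diff <- 0
    if (length(w) > 1) {
      for (a in seq_len(length(w) - 1)) {
        for (b in (a + 1):length(w)) {
          sum_diff <- sum_diff + w[a] * w[b] * dm[a, b]
        }
      }
    }
    pi_val <- if (tot_pairs == 0) 0 else sum_diff / tot_pairs / haps$aln_length
    data.frame(group = g, N = length(ids) / 2, H = length(tab),
               p = poly, Sn = sum(tab == 1),
               Hd = n / (n - 1) * (1 - sum(fr^2)),
               pi = pi_val,
               Rm = rm_four_gamete(unname(strings)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# pairwise Hamming distances between allele strings
hamming_matrix <- function(strings) {
  M <- do.call(rbind, strsplit(unname(strings), ""))
  k <- nrow(M)
  d <- matrix(0, k, k)
  if (k > 1) {
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        d[a, b] <- d[b, a] <- sum(M[a, ] != M[b, ])
      }
    }
  }
  d
}

#' F84 pairwise distance
#'
#' Maximum-likelihood distance under the F84 substitution model (unequal
#' base frequencies, distinct transition/transversion rates), as used by
#' classic distance programs. Gap or N positions are pairwise-deleted.
#' Saturated pairs (logarithm of a non-positive number) are flagged as
#' `Inf`.
#'
#' @param h1,h2 equal-length nucleotide sequences (character strings).
#' @return the F84 distance (substitutions per site).
#' @export
f84_distance <- function(h1, h2) {
  d <- f84_matrix(c(a = h1, b = h2))[1, 2]
  d
}

# F84 distance matrix for named sequences, via ape
f84_matrix <- function(seqs) {
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(unname(seqs)), "")))
  rownames(bin) <- names(seqs)
  d <- as.matrix(ape::dist.dna(bin, model = "F84",
                               pairwise.deletion = TRUE))
  d[is.nan(d) | is.na(d) | d < 0] <- Inf
  diag(d) <- 0
  d
}

# AMOVA variance components from a squared-distance matrix over copies
amova_phi <- function(d2, groups) {
  N <- nrow(d2)
  gs <- split(seq_len(N), groups)
  G <- length(gs)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in gs) {
    sub <- d2[g, g, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(g)
  }
  df_a <- G - 1
  df_w <- N - G
  sigma_w <- ss_within / df_w
  ms_a <- (ss_total - ss_within) / df_a
  n0 <- (N - sum(lengths(gs)^2) / N) / df_a
  sigma_a <- (ms_a - sigma_w) / n0
  tot <- sigma_a + sigma_w
  list(phi = if (tot <= 0) 0 else sigma_a / tot,
       sigma_a = sigma_a, sigma_w = sigma_w, degenerate = tot <= 0)
}

#' AMOVA-based PhiST with permutation test
#'
#' Partitions squared molecular distances among and within groups of
#' haplotype copies (two per phased individual) and returns
#' `PhiST = sigma2_among / (sigma2_among + sigma2_within)`. Significance is
#' obtained by permuting individuals among groups (each individual's two
#' copies move together).
#'
#' For `distance = "hamming"`, the number of pairwise differences is used
#' directly as the squared distance (the molecular-variance convention);
#' for `"f84"` the model distance is squared.
#'
#' @param haps a [em_phase()] result.
#' @param grouping metadata column name (default `"host"`) or label vector
#'   over individuals.
#' @param n_perm permutations (0 skips the test).
#' @param seed RNG seed.
#' @param distance `"f84"` or `"hamming"`.
#' @return list `phi_st, p, sigma_a, sigma_w, n_perm, degenerate`.
#' @export
phi_st <- function(haps, grouping = "host", n_perm = 1000L, seed = NULL,
                   distance = c("f84", "hamming")) {
  distance <- match.arg(distance)
  stopifnot(inherits(haps, "haplotype_set"))
  p <- haps$pairs[haps$pairs$phased, , drop = FALSE]
  groups <- if (length(grouping) == 1L)
    haps$meta[[grouping]][match(p$sample_id, haps$meta$sample_id)]
  else grouping[haps$pairs$phased]
  if (length(unique(groups)) != 2) stop("PhiST requires exactly 2 groups")
  if (any(table(groups) < 2)) stop("each group needs >= 2 individuals")
  dh <- if (distance == "hamming") hamming_matrix(haps$haplotypes)
        else f84_matrix(haps$full_seqs)^2
  rownames(dh) <- colnames(dh) <- names(haps$haplotypes)
  if (any(!is.finite(dh))) stop("saturated distances; PhiST undefined")
  copy_ids <- c(p$hap1, p$hap2)
  d2 <- dh[copy_ids, copy_ids]
  copy_groups <- rep(groups, 2)
  if (all(d2 == 0)) {
    return(list(phi_st = 0, p = NA_real_, sigma_a = 0, sigma_w = 0,
                n_perm = n_perm, degenerate = TRUE))
  }
  obs <- amova_phi(d2, copy_groups)
  pval <- NA_real_
  if (n_perm > 0) {
    local_seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      gp <- sample(groups)
      if (amova_phi(d2, rep(gp, 2))$phi >= obs$phi) exceed <- exceed + 1L
    }
    pval <- (1 + exceed) / (1 + n_perm)
  }
  list(phi_st = obs$phi, p = pval, sigma_a = obs$sigma_a,
       sigma_w = obs$sigma_w, n_perm = n_perm,
       degenerate = obs$degenerate)
}

#' Annotate SNPs with their codon effect
#'
#' Translates the two codon variants of each biallelic SNP using the
#' standard genetic code and classifies the change as synonymous or
#' nonsynonymous, with the amino-acid pair.
#'
#' @param aln a [diploid_alignment()] (provides the codon context).
#' @param variants optionally, a [call_snps()] table (recomputed otherwise).
#' @return the variant table with added `codon1, codon2, aa1, aa2, effect`.
#' @export
annotate_codon_effect <- function(aln, variants = NULL) {
  if (is.null(variants)) variants <- call_snps(aln)
  variants <- variants[variants$biallelic, , drop = FALSE]
  bb <- alignment_backbone(aln, variants$position)
  bb[variants$position] <- variants$a1
  res <- variants
  res$codon1 <- res$codon2 <- res$aa1 <- res$aa2 <- NA_character_
  res$effect <- NA_character_
  gc_tab <- Biostrings::GENETIC_CODE
  for (r in seq_len(nrow(variants))) {
    pos <- variants$position[r]
    cp <- variants$codon_pos[r]
    start <- pos - (cp - 1L)
    if (start < 1 || start + 2 > aln$length) {
      res$effect[r] <- "incomplete_codon"
      next
    }
    codon <- bb[start:(start + 2)]
    if (any(codon == "N")) {
      res$effect[r] <- "ambiguous_context"
      next
    }
    c1 <- codon; c1[cp] <- variants$a1[r]
    c2 <- codon; c2[cp] <- variants$a2[r]
    aa1 <- gc_tab[[paste(c1, collapse = "")]]
    aa2 <- gc_tab[[paste(c2, collapse = "")]]
    res$codon1[r] <- paste(c1, collapse = "")
    res$codon2[r] <- paste(c2, collapse = "")
    res$aa1[r] <- aa1
    res$aa2[r] <- aa2
    res$effect[r] <- if (aa1 == aa2) "synonymous" else "nonsynonymous"
  }
  res
}

#' Write phased haplotypes as FASTA
#'
#' Two records per phased individual, suffixed `_a` and `_b`.
#'
#' @param haps a [em_phase()] result.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_phased_fasta <- function(haps, path) {
  p <- haps$pairs[haps$pairs$phased, , drop = FALSE]
  seqs <- c(haps$full_seqs[p$hap1], haps$full_seqs[p$hap2])
  names(seqs) <- c(paste0(p$sample_id, "_a"), paste0(p$sample_id, "_b"))
  ord <- order(names(seqs))
  x <- Biostrings::BStringSet(seqs[ord])
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
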