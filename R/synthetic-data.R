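#' Simulation configuration for truth-known fixtures
#'
#' Bundles every parameter of the synthetic study design: two host-associated
#' populations sampled at several locations, a panel of dominant
#' presence/absence loci containing a small planted-outlier subset, replicate
#' genotypings with a known miscall rate, and one nuclear sequence locus with
#' a near-fixed host-associated SNP and host-asymmetric haplotype richness.
#'
#' Population divergence follows the Balding-Nichols parameterization: a
#' locus with ancestral presence-allele frequency `p0` gives each host
#' population a frequency drawn from `Beta(p0(1-F)/F, (1-p0)(1-F)/F)`, so `F`
#' is the expected FST between the host groups. Neutral loci use
#' `background_fst`; planted outliers use `outlier_fst`.
#'
#' @param seed integer seed; all randomness in both simulators derives from
#'   it, so equal configs give identical fixtures.
#' @param n_locations number of collection locations per host.
#' @param hosts character vector of two host labels. The first host carries
#'   the ancestral (richer) haplotype pool at the sequence locus.
#' @param n_per_group_per_location individuals per host per location (>= 2).
#' @param n_neutral_loci,n_outlier_loci,n_sex_loci panel composition. Sex
#'   loci (frequency differing by sex, not host) are off by default.
#' @param background_fst,outlier_fst,sex_fst expected FST between host groups
#'   for neutral and outlier loci, and between sexes for sex loci.
#' @param miscall_rate per-call probability that a genotyping flips the true
#'   band state (applies independently to every genotyping, so replicate
#'   pairs disagree at a rate of `2m(1-m)`).
#' @param n_replicate_pairs individuals genotyped twice.
#' @param seq_length alignment length of the sequence locus, bp.
#' @param n_seq_snps segregating sites at the sequence locus; all are placed
#'   at third codon positions relative to `frame_offset`.
#' @param host_snp_freqs length-2 frequencies of the derived allele of the
#'   host-diagnostic SNP in each host (order matching `hosts`).
#' @param hap_pool_sizes length-2 haplotype-pool richness per host; the
#'   default (36, 15) makes the first host roughly twice as rich.
#' @param frame_offset codon position (0-2) of alignment column 1.
#' @param n_seq_per_host individuals sequenced per host; defaults to the full
#'   marker design (`n_locations * n_per_group_per_location`).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_locations = 3L,
                       hosts = c("glabra", "coriacea"),
                       n_per_group_per_location = 30L,
                       n_neutral_loci = 250L,
                       n_outlier_loci = 15L,
                       n_sex_loci = 0L,
                       background_fst = 0.057,
                       outlier_fst = 0.49,
                       sex_fst = 0.30,
                       miscall_rate = 0.055,
                       n_replicate_pairs = 6L,
                       seq_length = 910L,
                       n_seq_snps = 22L,
                       host_snp_freqs = c(0.007, 0.8755),
                       hap_pool_sizes = c(36L, 15L),
                       frame_offset = 0L,
                       n_seq_per_host = NULL) {
  if (length(hosts) != 2L) stop("exactly two host labels required")
  assert_fraction(background_fst, "background_fst", open = TRUE)
  assert_fraction(outlier_fst, "outlier_fst", open = TRUE)
  assert_fraction(miscall_rate, "miscall_rate")
  assert_fraction(host_snp_freqs, "host_snp_freqs")
  if (length(host_snp_freqs) != 2L) stop("host_snp_freqs must have length 2")
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  if (n_seq_snps > floor(seq_length / 3))
    stop("n_seq_snps exceeds the number of third codon positions")
  if (n_outlier_loci > n_neutral_loci + n_outlier_loci)
    stop("n_outlier_loci exceeds total loci")
  cfg <- list(seed = as.integer(seed), n_locations = as.integer(n_locations),
              hosts = hosts,
              n_per_group_per_location = as.integer(n_per_group_per_location),
              n_neutral_loci = as.integer(n_neutral_loci),
              n_outlier_loci = as.integer(n_outlier_loci),
              n_sex_loci = as.integer(n_sex_loci),
              background_fst = background_fst, outlier_fst = outlier_fst,
              sex_fst = sex_fst, miscall_rate = miscall_rate,
              n_replicate_pairs = as.integer(n_replicate_pairs),
              seq_length = as.integer(seq_length),
              n_seq_snps = as.integer(n_seq_snps),
              host_snp_freqs = host_snp_freqs,
              hap_pool_sizes = as.integer(hap_pool_sizes),
              frame_offset = as.integer(frame_offset),
              n_seq_per_host = if (is.null(n_seq_per_host)) NULL
                               else as.integer(n_seq_per_host))
  class(cfg) <- "sim_config"
  cfg
}

# Balding-Nichols draw of population frequencies around ancestral p0 with
# differentiation F. F ~ 0 degenerates to p0 itself.
rbn <- function(n, p0, F) {
  if (F < 1e-9) return(rep(p0, n))
  stats::rbeta(n, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
}

#' Simulate a dominant-marker matrix with known truth
#'
#' Generates presence/absence calls for two host-associated groups sampled at
#' several locations under HWE within populations: an individual shows the
#' band with probability `1 - (1-p)^2` where `p` is its population's
#' presence-allele frequency. Every genotyping (including the replicate
#' re-genotypings) flips each true call independently with the configured
#' miscall rate. Fragment sizes are drawn uniformly on 78-792 bp.
#'
#' @param config a [sim_config()].
#' @return A list with elements `matrix` (a [marker_matrix()]) and `truth`
#'   (per-locus class and true per-host frequencies, per-individual true
#'   calls, and the miscall rate).
#' @export
simulate_dominant_markers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_per_group_per_location < 2L)
    stop("n_per_group_per_location must be >= 2 (FST undefined downstream)")
  local_seed(derive_seed(config$seed, 1L))

  n_loci <- config$n_neutral_loci + config$n_outlier_loci + config$n_sex_loci
  cls <- c(rep("neutral", config$n_neutral_loci),
           rep("outlier", config$n_outlier_loci),
           rep("sex", config$n_sex_loci))
  cls <- sample(cls)  # interleave classes across the panel
  p0 <- stats::runif(n_loci, 0.05, 0.95)
  Fl <- ifelse(cls == "outlier", config$outlier_fst, config$background_fst)

  # per-host presence-allele frequencies (sex loci share host frequencies)
  p_host <- matrix(NA_real_, 2L, n_loci,
                   dimnames = list(config$hosts, NULL))
  for (l in seq_len(n_loci)) {
    if (cls[l] == "sex") {
      p_host[, l] <- p0[l]
    } else if (cls[l] == "outlier") {
      # divergent selection pushes the hosts toward different alleles: plant
      # outliers whose realized between-host FST sits near the target, by
      # rejection from the Balding-Nichols model (unconditional draws at
      # high F frequently fix both hosts for the same allele)
      p0[l] <- stats::runif(1, 0.2, 0.8)
      best <- NULL; best_gap <- Inf
      for (try in 1:200) {
        pp <- rbn(2L, p0[l], Fl[l])
        vb <- (pp[1] - pp[2])^2 / 2
        pb <- mean(pp)
        fr <- vb / (pb * (1 - pb) + vb / 2)
        gap <- abs(fr - Fl[l])
        if (gap < best_gap) { best <- pp; best_gap <- gap }
        if (gap <= 0.05) break
      }
      p_host[, l] <- best
    } else {
      p_host[, l] <- rbn(2L, p0[l], Fl[l])
    }
  }
  # sex loci: frequencies differ between sexes instead
  p_sex <- matrix(NA_real_, 2L, n_loci, dimnames = list(c("F", "M"), NULL))
  for (l in which(cls == "sex")) p_sex[, l] <- rbn(2L, p0[l], config$sex_fst)

  n_grp <- config$n_per_group_per_location
  design <- expand.grid(k = seq_len(n_grp),
                        host = config$hosts,
                        location = paste0("loc", seq_len(config$n_locations)),
                        stringsAsFactors = FALSE)
  n_ind <- nrow(design)
  meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_ind)),
    host = design$host, location = design$location,
    sex = sample(c("F", "M"), n_ind, replace = TRUE),
    year = sample(c(2008L, 2009L), n_ind, replace = TRUE),
    replicate_of = NA_character_, stringsAsFactors = FALSE)

  p_ind <- p_host[meta$host, , drop = FALSE]
  for (l in which(cls == "sex")) p_ind[, l] <- p_sex[meta$sex, l]
  pr_band <- 1 - (1 - p_ind)^2
  true_calls <- matrix(stats::rbinom(n_ind * n_loci, 1L, pr_band),
                       n_ind, n_loci)

  miscall <- function(x) {
    flip <- matrix(stats::rbinom(length(x), 1L, config$miscall_rate),
                   nrow(x), ncol(x))
    as.integer(abs(x - flip))
  }
  obs <- matrix(miscall(true_calls), n_ind, n_loci)

  # replicate genotypings: fresh observations of the same true calls
  rep_ids <- sample(meta$sample_id, min(config$n_replicate_pairs, n_ind))
  if (length(rep_ids) > 0) {
    ridx <- match(rep_ids, meta$sample_id)
    rep_obs <- matrix(miscall(true_calls[ridx, , drop = FALSE]),
                      length(ridx), n_loci)
    rep_meta <- meta[ridx, ]
    rep_meta$replicate_of <- rep_meta$sample_id
    rep_meta$sample_id <- paste0(rep_meta$sample_id, "r")
    obs <- rbind(obs, rep_obs)
    meta <- rbind(meta, rep_meta)
    rownames(meta) <- NULL
  }

  sizes <- sample(78:792, n_loci, replace = TRUE)
  loci <- data.frame(
    locus = sprintf("L%d_%d", sizes, seq_len(n_loci)),
    size_bp = sizes,
    primer = sample(paste0("P", 1:8), n_loci, replace = TRUE),
    stringsAsFactors = FALSE)

  m <- marker_matrix(obs, meta, loci)
  m$log <- data.frame(rule = "scored", removed = 0L, retained = n_loci)
  truth <- list(locus = loci$locus, class = cls, p0 = p0,
                p_host = p_host, p_sex = p_sex[, cls == "sex", drop = FALSE],
                true_calls = true_calls,
                miscall_rate = config$miscall_rate,
                outlier_loci = loci$locus[cls == "outlier"])
  list(matrix = m, truth = truth)
}

#' Diploid IUPAC-coded alignment
#'
#' @param seqs character vector of equal-length sequences over A/C/G/T plus
#'   the two-base IUPAC codes (R,Y,S,W,K,M); names are sample ids.
#' @param meta data.frame with `sample_id`, `host`, `location` (one row per
#'   sequence, same order).
#' @param frame_offset codon position (0-2) of alignment column 1.
#' @return An object of class `diploid_alignment`.
#' @export
diploid_alignment <- function(seqs, meta, frame_offset = 0L) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must be aligned (equal length)")
  bad <- grepl("[^ACGTRYSWKMN-]", seqs)
  if (any(bad)) stop("non-IUPAC character in sequence(s): ",
                     paste(names(seqs)[bad], collapse = ", "))
  stopifnot(nrow(meta) == length(seqs),
            all(c("sample_id", "host", "location") %in% names(meta)))
  names(seqs) <- meta$sample_id
  structure(list(seqs = seqs, meta = meta, length = unname(lens[1]),
                 frame_offset = as.integer(frame_offset)),
            class = "diploid_alignment")
}

#' @export
print.diploid_alignment <- function(x, ...) {
  cat(sprintf("diploid_alignment: %d individuals x %d bp (frame offset %d)\n",
              length(x$seqs), x$length, x$frame_offset))
  invisible(x)
}

# character matrix view (individuals x columns)
seq_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$seqs), ""))
}

# codon position (1..3) of each alignment column
codon_positions <- function(len, frame_offset) {
  ((seq_len(len) - 1L + frame_offset) %% 3L) + 1L
}

#' Simulate a diploid sequence locus with known phases
#'
#' Builds per-host haplotype pools on a tree-free mutation model: all
#' segregating sites sit at third codon positions; one site is
#' host-diagnostic with per-host derived-allele frequencies from the config;
#' the first host's pool is the richer (ancestral) one, the second host's
#' pool is dominated by one frequent haplotype. Each individual receives two
#' haplotypes drawn independently from its host's pool and is emitted as an
#' IUPAC-coded diploid consensus.
#'
#' @param config a [sim_config()].
#' @return list with `alignment` (a [diploid_alignment()]) and `truth`
#'   (SNP positions, the diagnostic site, per-individual true haplotype
#'   pairs, pool sequences/frequencies, and the ancestral sequence).
#' @export
simulate_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(derive_seed(config$seed, 2L))
  L <- config$seq_length
  k <- config$n_seq_snps
  third <- which(codon_positions(L, config$frame_offset) == 3L)
  sites <- sort(sample(third, k))
  diag_site <- sites[sample.int(k, 1L)]
  other_sites <- setdiff(sites, diag_site)

  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  alt <- vapply(sites, function(s)
    sample(setdiff(c("A", "C", "G", "T"), base[s]), 1L), "")
  names(alt) <- as.character(sites)

  # haplotype backgrounds: subsets of non-diagnostic sites carrying the
  # alternate allele, mutated away from the all-ancestral background
  n_pool <- config$hap_pool_sizes
  make_backgrounds <- function(n, include_ancestral) {
    seen <- character(0)
    out <- list()
    if (include_ancestral) {
      out[[1]] <- integer(0)
      seen <- ""
    }
    while (length(out) < n) {
      # shallow, star-like genealogy: few mutations per haplotype
      nm <- sample.int(min(6L, max(1L, length(other_sites))), 1L)
      sub <- sort(sample(seq_along(other_sites), nm))
      key <- paste(sub, collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- sub
      }
    }
    out
  }
  pools <- list()
  # pool frequencies: one dominant haplotype plus a uniform rare tail,
  # tuned so per-host haplotype diversity sits near 0.79 (ancestral host)
  # and 0.49 (derived host) while the full richness is still observable
  # at study-scale sample sizes
  bg1 <- make_backgrounds(n_pool[1], include_ancestral = TRUE)
  f1 <- c(0.42, rep(0.58 / (n_pool[1] - 1), n_pool[1] - 1))
  bg2 <- make_backgrounds(n_pool[2], include_ancestral = FALSE)
  f2 <- c(0.70, rep(0.30 / (n_pool[2] - 1), n_pool[2] - 1))
  pools[[config$hosts[1]]] <- list(bg = bg1, freq = f1,
                                   p_derived = config$host_snp_freqs[1])
  pools[[config$hosts[2]]] <- list(bg = bg2, freq = f2,
                                   p_derived = config$host_snp_freqs[2])

  build_hap <- function(bg_idx, derived) {
    h <- base
    if (length(bg_idx) > 0) {
      s <- other_sites[bg_idx]
      h[s] <- alt[as.character(s)]
    }
    if (derived) h[diag_site] <- alt[as.character(diag_site)]
    paste(h, collapse = "")
  }

  n_seq <- config$n_seq_per_host %||%
    (config$n_locations * config$n_per_group_per_location)
  meta <- data.frame(
    sample_id = sprintf("Q%03d", seq_len(2L * n_seq)),
    host = rep(config$hosts, each = n_seq),
    location = rep(paste0("loc", seq_len(config$n_locations)),
                   length.out = 2L * n_seq),
    stringsAsFactors = FALSE)

  phases <- vector("list", nrow(meta))
  seqs <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    pool <- pools[[meta$host[i]]]
    pick <- sample.int(length(pool$bg), 2L, replace = TRUE,
                       prob = pool$freq)
    der <- stats::rbinom(2L, 1L, pool$p_derived) == 1L
    h1 <- build_hap(pool$bg[[pick[1]]], der[1])
    h2 <- build_hap(pool$bg[[pick[2]]], der[2])
    phases[[i]] <- c(h1, h2)
    a <- strsplit(h1, "")[[1]]; b <- strsplit(h2, "")[[1]]
    seqs[i] <- paste(iupac_code(a, b), collapse = "")
  }
  names(seqs) <- meta$sample_id
  aln <- diploid_alignment(seqs, meta, config$frame_offset)
  truth <- list(snp_sites = sites, diagnostic_site = diag_site,
                alleles = list(ancestral = base[sites],
                               derived = unname(alt)),
                ancestral_seq = paste(base, collapse = ""),
                phases = stats::setNames(phases, meta$sample_id),
                pools = pools)
  list(alignment = aln, truth = truth)
}

#' Simulate outgroup sequences for network rooting
#'
#' Mutates the ancestral sequence of a simulated locus at additional third
#' codon positions, yielding close relatives suitable for rooting the
#' haplotype network near the ancestral cluster.
#'
#' @param seq_truth the `truth` element returned by [simulate_sequences()].
#' @param n number of outgroup sequences.
#' @param n_mut substitutions per outgroup relative to the ancestor.
#' @param frame_offset codon position (0-2) of column 1.
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
simulate_outgroups <- function(seq_truth, n = 3L, n_mut = 8L,
                               frame_offset = 0L, seed = 1L) {
  local_seed(seed)
  anc <- strsplit(seq_truth$ancestral_seq, "")[[1]]
  third <- setdiff(which(codon_positions(length(anc), frame_offset) == 3L),
                   seq_truth$snp_sites)
  out <- character(n)
  for (i in seq_len(n)) {
    s <- anc
    mut <- sample(third, n_mut)
    s[mut] <- vapply(mut, function(p)
      sample(setdiff(c("A", "C", "G", "T"), anc[p]), 1L), "")
    out[i] <- paste(s, collapse = "")
  }
  names(out) <- paste0("outgroup", seq_len(n))
  out
}

#' Write a fixture set (markers + sequences + truth) to a directory
#'
#' @param matrix a [marker_matrix()].
#' @param alignment a [diploid_alignment()].
#' @param truth list with elements `markers` and `sequences` (the truth
#'   records of the two simulators).
#' @param dir output directory (created if absent).
#' @return named character vector of file paths.
#' @export
write_fixture_set <- function(matrix, alignment, truth, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  paths <- c(markers = file.path(dir, "markers.tsv"),
             sequences = file.path(dir, "sequences.fasta"),
             truth = file.path(dir, "truth.json"))
  write_marker_tsv(matrix, paths[["markers"]])
  write_diploid_fasta(alignment, paths[["sequences"]])
  tr <- truth
  tr$markers$p_host <- as.data.frame(t(tr$markers$p_host))
  tr$markers$true_calls <- NULL  # bulky; calls live in the TSV
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}

#' Write / read diploid alignments as IUPAC FASTA
#'
#' Headers follow `<sample_id>|<host>|<location>` so the metadata
#' round-trips.
#'
#' @param aln a [diploid_alignment()].
#' @param path FASTA file path.
#' @param frame_offset codon position (0-2) of column 1 (read side).
#' @return `write_diploid_fasta`: the path, invisibly;
#'   `read_diploid_fasta`: a [diploid_alignment()].
#' @export
write_diploid_fasta <- function(aln, path) {
  hdr <- paste(aln$meta$sample_id, aln$meta$host, aln$meta$location,
               sep = "|")
  x <- Biostrings::BStringSet(aln$seqs)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_diploid_fasta
#' @export
read_diploid_fasta <- function(path, frame_offset = 0L) {
  x <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(x), "|", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("FASTA headers must follow <sample_id>|<host>|<location>")
  meta <- data.frame(sample_id = vapply(parts, `[`, "", 1L),
                     host = vapply(parts, `[`, "", 2L),
                     location = vapply(parts, `[`, "", 3L),
                     stringsAsFactors = FALSE)
  seqs <- toupper(as.character(x))
  names(seqs) <- meta$sample_id
  diploid_alignment(seqs, meta, frame_offset)
}
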