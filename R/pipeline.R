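#' Validate pipeline inputs
#'
#' Schema checks on a marker TSV and a diploid FASTA: required metadata
#' columns, 0/1 calls, IUPAC-only sequence characters (with positions
#' reported), and host-label agreement for sample ids shared between the
#' two files. Problems are enumerated, not swallowed.
#'
#' @param marker_path marker TSV path (optional).
#' @param fasta_path diploid FASTA path (optional).
#' @return list with `ok` (logical) and `issues` (character vector).
#' @export
validate_inputs <- function(marker_path = NULL, fasta_path = NULL) {
  issues <- character(0)
  m <- aln <- NULL
  if (!is.null(marker_path)) {
    m <- tryCatch(read_marker_tsv(marker_path),
                  error = function(e) {
                    issues <<- c(issues, paste0("marker TSV: ",
                                                conditionMessage(e)))
                    NULL
                  })
  }
  if (!is.null(fasta_path)) {
    aln <- tryCatch({
      x <- Biostrings::readBStringSet(fasta_path)
      sq <- toupper(as.character(x))
      bad <- regexpr("[^ACGTRYSWKMN-]", sq)
      for (i in which(bad > 0))
        issues <- c(issues, sprintf(
          "FASTA record %d (%s): non-IUPAC character at position %d",
          i, names(x)[i], bad[i]))
      if (!any(bad > 0)) read_diploid_fasta(fasta_path) else NULL
    }, error = function(e) {
      issues <<- c(issues, paste0("FASTA: ", conditionMessage(e)))
      NULL
    })
  }
  if (!is.null(m) && !is.null(aln)) {
    shared <- intersect(m$meta$sample_id, aln$meta$sample_id)
    if (length(shared) > 0) {
      hm <- m$meta$host[match(shared, m$meta$sample_id)]
      hf <- aln$meta$host[match(shared, aln$meta$sample_id)]
      bad <- shared[hm != hf]
      if (length(bad) > 0)
        issues <- c(issues, paste0(
          "host label mismatch between marker TSV and FASTA for: ",
          paste(bad, collapse = ", ")))
    }
  }
  list(ok = length(issues) == 0, issues = issues)
}

#' Run the full host-race divergence pipeline
#'
#' Orchestrates the analysis end to end on a simulated fixture or on files:
#' QC (error rate and the four filter rules), dominant-marker FST with a
#' permutation test and gene diversity, the trimmed-mean-seeded neutral
#' envelope and outlier classification per comparison (combined plus each
#' location with at least `min_per_host` individuals per host) with the
#' multi-comparison consensus, sequence phasing and summary statistics with
#' PhiST, the median-joining network, and the Jaccard NMDS ordination with
#' factor fits and a nested permutational MANOVA. Every stochastic stage
#' receives a seed derived deterministically from the global seed, so equal
#' configurations reproduce the report exactly.
#'
#' @param config a [sim_config()] (simulated run), or a list with paths
#'   `markers` and `sequences` (and optional `frame_offset`).
#' @param out_dir optional directory; per-stage tables are written there as
#'   TSV/JSON when given.
#' @param n_perm permutations for FST/PhiST/MANOVA/factor fits.
#' @param n_sim_loci neutral-envelope size.
#' @param n_restarts NMDS restarts.
#' @param min_per_host minimum individuals per host for a location to enter
#'   the per-location comparisons.
#' @param trim trimmed-mean fraction for the envelope seed.
#' @param seed global seed (defaults to the config seed for simulated
#'   runs).
#' @return list of class `hostscan_report` with elements `qc`, `fst`,
#'   `diversity`, `outliers`, `seq`, `network`, `ordination`, `seeds`.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_perm = 5000L,
                         n_sim_loci = 50000L, n_restarts = 20L,
                         min_per_host = 5L, trim = 0.30, seed = NULL) {
  simulated <- inherits(config, "sim_config")
  if (simulated) {
    seed <- seed %||% config$seed
    mk <- simulate_dominant_markers(config)
    sq <- simulate_sequences(config)
    m_raw <- mk$matrix
    aln <- sq$alignment
  } else {
    if (is.null(seed)) stop("seed required for file-based runs")
    diag <- validate_inputs(config$markers, config$sequences)
    if (!diag$ok)
      stop("invalid inputs:\n  ", paste(diag$issues, collapse = "\n  "))
    m_raw <- read_marker_tsv(config$markers)
    aln <- read_diploid_fasta(config$sequences,
                              config$frame_offset %||% 0L)
  }
  seeds <- list(fst = derive_seed(seed, 11L),
                envelope = derive_seed(seed, 12L),
                phist = derive_seed(seed, 13L),
                nmds = derive_seed(seed, 14L),
                envfit = derive_seed(seed, 15L),
                adonis = derive_seed(seed, 16L))

  # --- QC ---------------------------------------------------------------
  qc <- run_qc(m_raw)
  m <- qc$matrix

  # --- dominant-marker popgen -------------------------------------------
  fst_host <- fst_dominant(m, "host", n_perm = n_perm, seed = seeds$fst)
  div <- list(total = gene_diversity(m, "host"))
  for (h in unique(m$meta$host[primary_rows(m)])) {
    sel <- m
    keep <- which(is.na(m$meta$replicate_of) & m$meta$host == h)
    sel$calls <- m$calls[keep, , drop = FALSE]
    sel$meta <- m$meta[keep, , drop = FALSE]
    div[[h]] <- gene_diversity(sel, "location")
  }

  # --- outlier scan ------------------------------------------------------
  pr <- primary_rows(m)
  tmf <- trimmed_mean_fst(fst_host$per_locus$fst, trim = trim)
  sizes <- as.vector(table(m$meta$host[pr]))
  f_cal <- calibrate_envelope_seed(tmf, sizes, trim = trim,
                                   seed = derive_seed(seeds$envelope, 99L))
  env <- simulate_neutral_envelope(f_cal, sizes, n_sim_loci = n_sim_loci,
                                   seed = seeds$envelope)
  calls <- classify_outliers(fst_host$per_locus, env, "combined")
  loc_tab <- table(m$meta$location[pr], m$meta$host[pr])
  eligible <- rownames(loc_tab)[apply(loc_tab >= min_per_host, 1, all)]
  for (loc in eligible) {
    keep <- which(is.na(m$meta$replicate_of) & m$meta$location == loc)
    ml <- m
    ml$calls <- m$calls[keep, , drop = FALSE]
    ml$meta <- m$meta[keep, , drop = FALSE]
    f_loc <- fst_dominant(ml, "host", n_perm = 0)
    tm_loc <- trimmed_mean_fst(f_loc$per_locus$fst, trim = trim)
    sz_loc <- as.vector(table(ml$meta$host))
    f_loc_cal <- calibrate_envelope_seed(
      tm_loc, sz_loc, trim = trim,
      seed = derive_seed(seeds$envelope, 100L + match(loc, eligible)))
    env_loc <- simulate_neutral_envelope(
      f_loc_cal, sz_loc, n_sim_loci = n_sim_loci,
      seed = derive_seed(seeds$envelope, match(loc, eligible)))
    calls <- rbind(calls, classify_outliers(f_loc$per_locus, env_loc, loc))
  }
  consensus <- if (length(unique(calls$comparison)) >= 2)
    consensus_outliers(calls) else character(0)
  outliers <- list(calls = calls, report = outlier_report(calls),
                   consensus = consensus, trimmed_mean_fst = tmf,
                   envelope_seed_fst = f_cal, envelope = env)

  # --- sequence locus ----------------------------------------------------
  haps <- em_phase(aln)
  seq_sum <- haplotype_summary(haps, "host")
  phist <- phi_st(haps, "host", n_perm = min(n_perm, 1000L),
                  seed = seeds$phist)
  codon <- annotate_codon_effect(aln)

  # --- network -----------------------------------------------------------
  network <- build_mj_network(haps)

  # --- ordination --------------------------------------------------------
  d <- jaccard_matrix(m)
  ord <- nmds(d, k = 2, n_restarts = n_restarts, seed = seeds$nmds)
  meta_pr <- m$meta[pr, ]
  fit_host <- fit_factor(ord, meta_pr$host, n_perm = n_perm,
                         seed = seeds$envfit)
  fit_sex <- fit_factor(ord, meta_pr$sex, n_perm = n_perm,
                        seed = seeds$envfit)
  ad <- adonis_partition(d, meta_pr, "location/host", strata = "location",
                         n_perm = n_perm, seed = seeds$adonis)

  report <- structure(list(
    qc = qc$report, filter_log = m$log,
    fst = list(host = fst_host[c("fst", "p", "n_perm")],
               per_locus = fst_host$per_locus),
    diversity = div,
    outliers = outliers,
    seq = list(summary = seq_sum, phi_st = phist, codon = codon,
               n_haplotypes = length(haps$haplotypes)),
    network = network,
    ordination = list(stress = ord$stress, scores = ord$scores,
                      fit_host = fit_host, fit_sex = fit_sex,
                      adonis = as.data.frame(ad)),
    seeds = seeds), class = "hostscan_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.hostscan_report <- function(x, ...) {
  cat("hostscan pipeline report\n")
  cat(sprintf("  QC error rate: %.4f\n", x$qc$error_rate))
  cat(sprintf("  host FST: %.4f (p = %.4g)\n", x$fst$host$fst, x$fst$host$p))
  cat(sprintf("  outliers: %d any / %d multiple / %d combined / %d robust\n",
              x$outliers$report$n_any, x$outliers$report$n_multiple,
              x$outliers$report$n_combined, x$outliers$report$n_robust))
  cat(sprintf("  PhiST (host): %.4f (p = %.4g)\n",
              x$seq$phi_st$phi_st, x$seq$phi_st$p))
  cat(sprintf("  NMDS stress: %.1f%%, host R2 = %.4f, sex R2 = %.4f\n",
              100 * x$ordination$stress, x$ordination$fit_host$r2,
              x$ordination$fit_sex$r2))
  invisible(x)
}

# write the report bundle as TSV/JSON files
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  w(report$filter_log, "qc_log.tsv")
  jsonlite::write_json(report$qc, file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  w(report$fst$per_locus, "locus_stats.tsv")
  jsonlite::write_json(report$fst$host, file.path(out_dir, "fst_host.json"),
                       auto_unbox = TRUE, digits = NA)
  w(report$outliers$calls, "outlier_calls.tsv")
  w(report$outliers$envelope$bins, "envelope.tsv")
  w(report$seq$summary, "seq_summary.tsv")
  w(report$seq$codon, "codon_effects.tsv")
  export_network(report$network, file.path(out_dir, "network"),
                 format = "tsv")
  w(data.frame(sample_id = rownames(report$ordination$scores),
               report$ordination$scores), "nmds_scores.tsv")
  jsonlite::write_json(
    list(stress = report$ordination$stress,
         fit_host = report$ordination$fit_host,
         fit_sex = report$ordination$fit_sex),
    file.path(out_dir, "ordination.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
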