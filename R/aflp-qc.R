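#' Replicate-based genotyping error rate
#'
#' Compares every replicate genotyping against its primary genotyping,
#' locus-wise, and returns the fraction of discordant calls among all
#' compared calls.
#'
#' @param m a [marker_matrix()] containing at least one replicate pair
#'   (rows with non-NA `replicate_of`).
#' @return fraction of mismatching calls in `[0,1]`.
#' @export
estimate_error_rate <- function(m) {
  rep_rows <- which(!is.na(m$meta$replicate_of))
  if (length(rep_rows) == 0)
    stop("no replicate pairs present; error rate requires replicate genotypings")
  orig <- match(m$meta$replicate_of[rep_rows], m$meta$sample_id)
  if (anyNA(orig)) stop("replicate_of refers to unknown sample id(s)")
  a <- m$calls[rep_rows, , drop = FALSE]
  b <- m$calls[orig, , drop = FALSE]
  sum(a != b) / length(a)
}

# logical vector: locus has >= 1 discordant call in >= 1 replicate pair
replicate_mismatch_loci <- function(m) {
  rep_rows <- which(!is.na(m$meta$replicate_of))
  if (length(rep_rows) == 0) return(rep(FALSE, ncol(m$calls)))
  orig <- match(m$meta$replicate_of[rep_rows], m$meta$sample_id)
  a <- m$calls[rep_rows, , drop = FALSE]
  b <- m$calls[orig, , drop = FALSE]
  colSums(a != b) > 0
}

#' Marker filtering rules
#'
#' Applies, in a fixed order, the four panel-cleaning rules used for
#' replicated dominant-marker datasets:
#' \enumerate{
#'   \item drop loci with any discordant call in any replicate pair;
#'   \item drop loci whose fragment size matches a negative-control peak;
#'   \item collapse same-size loci from different primer pairs that are in
#'     significant gametic disequilibrium (nonspecific primer binding),
#'     retaining the lexicographically first locus of each linked cluster;
#'   \item drop singleton loci, where the rarer band state occurs in exactly
#'     one individual.
#' }
#' Each rule appends a row to the provenance log, so the log always
#' reconstructs the initial locus count (`initial = removed + retained` at
#' every step). Filtering is idempotent.
#'
#' @param m a [marker_matrix()].
#' @param negative_control_sizes integer fragment sizes (bp) seen in negative
#'   controls.
#' @param ld_fdr FDR level for rule 3 linkage significance, tested within the
#'   candidate same-size cross-primer pairs.
#' @param fdr_method multiple-testing correction for rule 3 (see
#'   [fdr_adjust()]).
#' @return the filtered [marker_matrix()].
#' @export
filter_markers <- function(m, negative_control_sizes = integer(0),
                           ld_fdr = 0.05, fdr_method = "bh") {
  stopifnot(inherits(m, "marker_matrix"))
  # rule 1: replicate mismatches
  m <- drop_loci(m, !replicate_mismatch_loci(m), "replicate_mismatch")
  # rule 2: negative-control sizes
  m <- drop_loci(m, !(m$loci$size_bp %in% negative_control_sizes),
                 "negative_control_size")
  # rule 3: same-size cross-primer linked duplicates
  drop <- character(0)
  cand <- ld_scan(m, pairs = "same_size_cross_primer",
                  fdr_method = fdr_method)
  if (nrow(cand) > 0) {
    sig <- cand[cand$converged & !is.na(cand$q) & cand$q <= ld_fdr, ,
                drop = FALSE]
    if (nrow(sig) > 0) {
      # linked clusters; keep the lexicographically first member of each
      g <- igraph::graph_from_data_frame(sig[, c("locusA", "locusB")],
                                         directed = FALSE)
      comp <- igraph::components(g)
      for (k in seq_len(comp$no)) {
        members <- sort(names(comp$membership)[comp$membership == k])
        drop <- c(drop, members[-1])
      }
    }
  }
  m <- drop_loci(m, !(m$loci$locus %in% drop), "linked_duplicate")
  # rule 4: singletons among primary genotypings
  pres <- colSums(m$calls[primary_rows(m), , drop = FALSE])
  n <- length(primary_rows(m))
  singleton <- pres == 1L | pres == n - 1L
  m <- drop_loci(m, !singleton, "singleton")
  if (ncol(m$calls) == 0) stop("no loci retained after filtering")
  m
}

#' Fragment size vs band frequency correlation
#'
#' A significant negative Pearson correlation between fragment frequency and
#' fragment size is a warning sign of excessive size homoplasy in dominant
#' marker panels; a small, non-significant `r` supports low homoplasy risk.
#'
#' @param m a [marker_matrix()] with at least 3 loci.
#' @return list with `r` (Pearson correlation) and `p` (two-sided p-value).
#' @export
size_frequency_correlation <- function(m) {
  if (ncol(m$calls) < 3) stop("need >= 3 loci")
  freq <- colMeans(m$calls[primary_rows(m), , drop = FALSE])
  size <- m$loci$size_bp
  if (stats::sd(freq) == 0 || stats::sd(size) == 0)
    stop("zero variance in frequency or size; correlation undefined")
  ct <- stats::cor.test(freq, size, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Run the QC stage and assemble a report
#'
#' @param m a raw [marker_matrix()].
#' @param negative_control_sizes fragment sizes (bp) of negative-control
#'   peaks.
#' @param ld_fdr rule-3 FDR level.
#' @return list with `matrix` (filtered) and `report` (error rate, per-rule
#'   removal counts, size-frequency correlation).
#' @export
run_qc <- function(m, negative_control_sizes = integer(0), ld_fdr = 0.05) {
  err <- estimate_error_rate(m)
  fm <- filter_markers(m, negative_control_sizes, ld_fdr = ld_fdr)
  sf <- size_frequency_correlation(fm)
  report <- list(
    error_rate = err,
    removed_by_rule = stats::setNames(as.list(fm$log$removed), fm$log$rule),
    size_freq_r = sf$r, size_freq_p = sf$p)
  list(matrix = fm, report = report)
}

#' Write a QC report and filter log
#'
#' @param qc result of [run_qc()].
#' @param dir output directory.
#' @return paths of `qc_report.json` and `qc_log.tsv`, invisibly.
#' @export
write_qc_report <- function(qc, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pj <- file.path(dir, "qc_report.json")
  pt <- file.path(dir, "qc_log.tsv")
  jsonlite::write_json(qc$report, pj, auto_unbox = TRUE, digits = NA)
  utils::write.table(qc$matrix$log, pt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pj, pt))
}
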