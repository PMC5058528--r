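#' Dominant marker matrix with sample metadata
#'
#' A `marker_matrix` bundles a 0/1 presence/absence call matrix (samples in
#' rows, loci in columns) with per-sample metadata (host, location, sex, year,
#' replicate linkage) and per-locus attributes (fragment size in bp, primer
#' pair), plus a provenance log of filtering events.
#'
#' @param calls integer/numeric matrix of 0/1 calls; rownames are sample ids,
#'   colnames are locus ids.
#' @param meta data.frame with columns `sample_id`, `host`, `location`, `sex`,
#'   `year`, `replicate_of` (NA for primary genotypings); one row per row of
#'   `calls`, in the same order.
#' @param loci data.frame with columns `locus`, `size_bp`, `primer`; one row
#'   per column of `calls`, in the same order.
#' @param log data.frame recording filter events (`rule`, `removed`,
#'   `retained`); empty for a fresh matrix.
#' @return An object of class `marker_matrix`.
#' @export
marker_matrix <- function(calls, meta, loci, log = NULL) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c(0, 1))) stop("calls must be 0/1")
  storage.mode(calls) <- "integer"
  req_meta <- c("sample_id", "host", "location", "sex", "year", "replicate_of")
  if (!all(req_meta %in% names(meta)))
    stop("meta must have columns: ", paste(req_meta, collapse = ", "))
  req_loci <- c("locus", "size_bp", "primer")
  if (!all(req_loci %in% names(loci)))
    stop("loci must have columns: ", paste(req_loci, collapse = ", "))
  if (nrow(meta) != nrow(calls)) stop("meta rows must match call rows")
  if (nrow(loci) != ncol(calls)) stop("loci rows must match call columns")
  rownames(calls) <- meta$sample_id
  colnames(calls) <- loci$locus
  if (is.null(log))
    log <- data.frame(rule = character(), removed = integer(),
                      retained = integer())
  structure(list(calls = calls, meta = meta, loci = loci, log = log),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d samples x %d loci\n",
              nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  hosts: %s\n",
              paste(sort(unique(x$meta$host)), collapse = ", ")))
  nrep <- sum(!is.na(x$meta$replicate_of))
  cat(sprintf("  replicate genotypings: %d\n", nrep))
  if (nrow(x$log) > 0) {
    cat("  filter log:\n")
    for (i in seq_len(nrow(x$log)))
      cat(sprintf("    %-28s removed %3d, retained %3d\n",
                  x$log$rule[i], x$log$removed[i], x$log$retained[i]))
  }
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$calls)

# Subset loci by a logical/index vector, appending a log row for `rule`.
drop_loci <- function(m, keep, rule) {
  keep <- if (is.logical(keep)) which(keep) else keep
  removed <- ncol(m$calls) - length(keep)
  m$calls <- m$calls[, keep, drop = FALSE]
  m$loci <- m$loci[keep, , drop = FALSE]
  rownames(m$loci) <- NULL
  m$log <- rbind(m$log, data.frame(rule = rule, removed = removed,
                                   retained = ncol(m$calls)))
  m
}

# Rows that are primary genotypings (not replicates).
primary_rows <- function(m) which(is.na(m$meta$replicate_of))

#' Write a marker matrix to TSV
#'
#' One row per sample: metadata columns `sample_id, host, location, sex, year,
#' replicate_of`, then one 0/1 column per locus. Locus ids encode the fragment
#' size (`L<size>_<k>`); primer assignments are stored in a `#primer:` header
#' comment so the file round-trips losslessly.
#'
#' @param m a [marker_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_marker_tsv <- function(m, path) {
  hdr <- paste0("#primer: ",
                paste(m$loci$locus, m$loci$primer, sep = "=", collapse = ","))
  df <- cbind(m$meta, as.data.frame(m$calls))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a marker matrix from TSV
#'
#' @param path file written by [write_marker_tsv()] (or any TSV in the same
#'   dialect). Loci outside the scored fragment-size window are dropped at
#'   read time, with a log entry.
#' @param size_window numeric length-2; retain loci whose fragment size lies
#'   inside the closed window (default 76-800 bp, the scored range).
#' @return a [marker_matrix()].
#' @export
read_marker_tsv <- function(path, size_window = c(76, 800)) {
  first <- readLines(path, n = 1L)
  primer_map <- NULL
  skip <- 0L
  if (startsWith(first, "#primer:")) {
    skip <- 1L
    spec <- strsplit(sub("^#primer:\\s*", "", first), ",", fixed = TRUE)[[1]]
    kv <- strsplit(spec, "=", fixed = TRUE)
    primer_map <- stats::setNames(vapply(kv, `[`, "", 2L),
                                  vapply(kv, `[`, "", 1L))
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  meta_cols <- c("sample_id", "host", "location", "sex", "year",
                 "replicate_of")
  missing <- setdiff(meta_cols, names(df))
  if (length(missing) > 0)
    stop("marker TSV lacks metadata column(s): ",
         paste(missing, collapse = ", "))
  locus_ids <- setdiff(names(df), meta_cols)
  calls <- as.matrix(df[, locus_ids, drop = FALSE])
  meta <- df[, meta_cols]
  meta$replicate_of[meta$replicate_of %in% c("", "NA")] <- NA
  sizes <- as.integer(sub("^L(\\d+)_.*$", "\\1", locus_ids))
  if (anyNA(sizes))
    stop("locus ids must follow the L<size_bp>_<k> convention")
  primer <- if (is.null(primer_map)) rep("P1", length(locus_ids))
            else unname(primer_map[locus_ids])
  loci <- data.frame(locus = locus_ids, size_bp = sizes, primer = primer,
                     stringsAsFactors = FALSE)
  m <- marker_matrix(calls, meta, loci)
  m$log <- data.frame(rule = "scored", removed = 0L,
                      retained = ncol(m$calls))
  in_window <- loci$size_bp >= size_window[1] & loci$size_bp <= size_window[2]
  if (!all(in_window)) m <- drop_loci(m, in_window, "size_window")
  m
}
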