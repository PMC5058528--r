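# Internal helpers shared across modules.

# Set the RNG seed for the duration of the calling function only, restoring
# any pre-existing .Random.seed on exit. A NULL seed leaves the RNG alone.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::local_seed(as.integer(seed %% .Machine$integer.max),
                    .local_envir = envir)
  invisible(NULL)
}

# Deterministic derived seeds for pipeline stages: a simple LCG split keeps
# every derived seed a valid 32-bit integer.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) * 69069 + 12345 * as.double(k)) %% 2147483647
  as.integer(max(1, s))
}

# IUPAC two-base ambiguity codes and their unordered base pairs.
IUPAC2 <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

iupac_code <- function(a, b) {
  # a, b: single bases; returns the IUPAC code for the unordered pair
  stopifnot(length(a) == length(b))
  out <- a
  het <- a != b
  if (any(het)) {
    key <- paste0(pmin(a[het], b[het]), pmax(a[het], b[het]))
    code <- names(IUPAC2)[match(key, IUPAC2)]
    if (anyNA(code)) stop("invalid base pair for IUPAC encoding")
    out[het] <- code
  }
  out
}

iupac_expand <- function(x) {
  # single character -> the two underlying bases (a base expands to itself)
  if (x %in% c("A", "C", "G", "T")) return(c(x, x))
  if (x %in% names(IUPAC2)) return(strsplit(IUPAC2[[x]], "")[[1]])
  stop("non-IUPAC character: ", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_fraction <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) &&
    (if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1))
  if (!ok) stop(sprintf("'%s' must lie in %s", name,
                        if (open) "(0,1)" else "[0,1]"), call. = FALSE)
  invisible(x)
}
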