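# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement DNA strings
#'
#' Vectorized reverse complement over the {A,C,G,T} alphabet.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @examples
#' revcomp(c("ACG", "TTAA"))
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Deterministic per-stream sub-seed derived from one root seed, so that each
# simulation stage (genome, variants, counts, betas, coupling) is individually
# reproducible. Kept below 2^31 - 1.
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(as.numeric(seed)) * 48271 + as.numeric(stream) * 104729) %%
    2147483629
  as.integer(s) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stopf("'%s' must be a probability in [0, 1]", name)
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < min) ||
      any(x != floor(x)))
    stopf("'%s' must be an integer >= %d", name, min)
  invisible(x)
}

is_two_level <- function(groups) {
  length(unique(as.character(groups))) == 2L
}

# Split a two-level label vector into a list of two index vectors, ordered so
# that the first level encountered (or the level named 'a') is group A.
split_groups <- function(groups, a = NULL) {
  g <- as.character(groups)
  lv <- unique(g)
  if (length(lv) != 2L)
    stopf("'groups' must have exactly two levels, got %d", length(lv))
  if (!is.null(a)) {
    if (!a %in% lv) stopf("reference level '%s' not found in groups", a)
    lv <- c(a, setdiff(lv, a))
  }
  list(a = which(g == lv[1]), b = which(g == lv[2]),
       levels = lv)
}
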