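## Hologram algebra: signed difference holograms and the count-Tanimoto
## similarity used for library lookups.

as_hologram <- function(h) {
  if (is.null(names(h)) && length(h) > 0L)
    stop("a hologram must be a named count vector")
  storage.mode(h) <- "integer"
  h[h != 0L]
}

#' Difference hologram
#'
#' Entrywise signed subtraction `unknown - known` over the union of
#' codes; zero entries are dropped, so `hologram_difference(h, h)` is
#' empty. The difference hologram is the basis of the library
#' correction: multiplied through the coefficients it converts a
#' reference compound's experimental logP into a prediction for the
#' query.
#'
#' @param unknown,known named integer count vectors (see
#'   [type_molecule()]).
#' @return named integer vector of signed deltas, sorted by code.
#' @export
hologram_difference <- function(unknown, known) {
  unknown <- as_hologram(unknown); known <- as_hologram(known)
  codes <- sort(union(names(unknown), names(known)))
  u <- ifelse(codes %in% names(unknown), unknown[codes], 0L)
  k <- ifelse(codes %in% names(known), known[codes], 0L)
  d <- as.integer(u - k)
  names(d) <- codes
  d[d != 0L]
}

#' Count-Tanimoto similarity of two holograms
#'
#' A Tanimoto-like measure for count vectors: over the union of codes,
#' the sum of per-code minimum occupancies divided by the sum of
#' per-code maximum occupancies. On 0/1 counts this degenerates to the
#' standard Tanimoto coefficient. Symmetric, bounded in \[0, 1\], equal
#' to 1 exactly when the holograms are identical and 0 when the code
#' sets are disjoint.
#'
#' @param h1,h2 named integer count vectors.
#' @param per_position if `TRUE`, use the alternative reading that
#'   averages the per-code min/max ratios instead of taking the ratio of
#'   sums. Off by default.
#' @return similarity in \[0, 1\].
#' @export
hologram_similarity <- function(h1, h2, per_position = FALSE) {
  h1 <- as_hologram(h1); h2 <- as_hologram(h2)
  if (length(h1) == 0L && length(h2) == 0L)
    stop("similarity of two empty holograms is undefined")
  codes <- union(names(h1), names(h2))
  a <- ifelse(codes %in% names(h1), h1[codes], 0L)
  b <- ifelse(codes %in% names(h2), h2[codes], 0L)
  if (per_position) return(mean(pmin(a, b) / pmax(a, b)))
  sum(pmin(a, b)) / sum(pmax(a, b))
}

#' Hologram text serialization
#'
#' `format_hologram()` renders a hologram as sorted, tab-separated
#' `code:count` pairs; `parse_hologram()` inverts it. Negative counts
#' (difference holograms) round-trip too.
#'
#' @param h named integer vector.
#' @return a single string.
#' @export
format_hologram <- function(h) {
  h <- h[order(names(h))]
  paste(sprintf("%s:%d", names(h), h), collapse = "\t")
}

#' @rdname format_hologram
#' @param text string of `code:count` pairs separated by whitespace.
#' @export
parse_hologram <- function(text) {
  if (!nzchar(trimws(text))) return(structure(integer(0), names = character(0)))
  parts <- strsplit(trimws(text), "\\s+")[[1L]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  h <- vapply(kv, function(x) as.integer(x[2L]), integer(1))
  names(h) <- vapply(kv, `[[`, character(1), 1L)
  h[order(names(h))]
}
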