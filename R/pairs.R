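#' Canonical protein pair
#'
#' Orders two protein identifiers lexicographically after upper-casing, so
#' that an interaction is represented the same way regardless of bait/prey
#' orientation. Self-pairs (homodimers) are valid.
#'
#' @param a,b Character vectors of protein identifiers (systematic ORF
#'   names such as `"YML018C"`). Recycled to a common length.
#' @return A two-column character matrix with columns `a` and `b`, each row
#'   a canonically ordered pair. Idempotent: re-canonicalizing is a no-op.
#' @examples
#' canonical_pair("YBR001C", "YAL002W")
#' @export
canonical_pair <- function(a, b) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  if (length(a) != length(b)) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
  }
  if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b)) {
    stop("protein identifiers must be non-empty and non-missing")
  }
  swap <- b < a
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  cbind(a = lo, b = hi)
}

#' Canonical pair key
#'
#' Collapses a canonical pair into a single string key used for set algebra
#' on interaction datasets.
#'
#' @inheritParams canonical_pair
#' @return Character vector of `"A|B"` keys in canonical order.
#' @export
pair_key <- function(a, b) {
  cp <- canonical_pair(a, b)
  paste(cp[, 1L], cp[, 2L], sep = "|")
}
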