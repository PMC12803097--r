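#' Marine biogeographic realm sets
#'
#' A realm set is the ordered collection of realm codes over which geographic
#' ranges are defined.  The order is canonical: it fixes the bit order used to
#' encode every range state, the row/column order of dispersal multiplier
#' matrices, and the tie-break order wherever a deterministic choice among
#' realms is needed.
#'
#' @param labels character vector of unique realm codes, length >= 2.
#' @return An object of class `realm_set` (a character vector with attributes).
#' @examples
#' realm_set()                # the nine global marine realms
#' realm_set(c("A", "B", "C"))
#' @export
realm_set <- function(labels = c("NC", "CI", "CP", "EA", "EP", "SC", "WA", "WI", "NP")) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("realm labels must be unique")
  if (length(labels) < 2L) stop("a realm set needs at least 2 realms")
  structure(labels, class = "realm_set")
}

#' @export
print.realm_set <- function(x, ...) {
  cat("Realm set (", length(x), " realms): ", paste(unclass(x), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Encode and decode range states
#'
#' A range state is a subset of the realm set stored as an integer bitmask in
#' the realm set's canonical bit order (bit i set means realm `realms[i]`
#' occupied).  The empty range is 0 and is permitted only where a caller
#' explicitly allows it.
#'
#' @param labels character vector of realm codes to occupy.
#' @param realms a [realm_set()].
#' @param bits integer bitmask.
#' @return `range_state()` returns the integer bitmask; `range_labels()` the
#'   occupied realm codes in canonical order; `range_size()` the number of
#'   occupied realms.
#' @examples
#' r <- realm_set(c("A", "B", "C"))
#' range_state(c("A", "C"), r)      # 5
#' range_labels(5L, r)              # "A" "C"
#' range_size(5L)                   # 2
#' @export
range_state <- function(labels, realms) {
  idx <- match(labels, realms)
  if (anyNA(idx)) stop("unknown realm label(s): ", paste(labels[is.na(idx)], collapse = ", "))
  if (anyDuplicated(idx)) stop("duplicated realm label in range")
  as.integer(sum(bitwShiftL(1L, idx - 1L)))
}

#' @rdname range_state
#' @export
range_labels <- function(bits, realms) {
  realms[bit_indices(bits)]
}

#' @rdname range_state
#' @export
range_size <- function(bits) {
  vapply(bits, function(b) length(bit_indices(b)), integer(1))
}

# 1-based indices of set bits
bit_indices <- function(bits) {
  which(bitwAnd(bits, bitwShiftL(1L, 0:30)) != 0L)
}

has_bit <- function(bits, i) bitwAnd(bits, bitwShiftL(1L, i - 1L)) != 0L

#' Enumerate the range state space
#'
#' Enumerates all subsets of the realm set up to a maximum range size, in
#' canonical order: the empty range first, then by increasing size and, within
#' a size, by increasing bitmask value.
#'
#' @param n_realms number of realms.
#' @param max_size cap on range size (defaults to `n_realms`, i.e. uncapped).
#' @return An object of class `state_space`: a list with `bits` (integer
#'   vector, canonical order), `size` (range sizes), `n_realms`, `max_size`,
#'   and `index` (lookup from bitmask to position in `bits`).
#' @examples
#' enumerate_states(2)          # 4 states
#' enumerate_states(9, 4)$bits  # 256 states
#' @export
enumerate_states <- function(n_realms, max_size = n_realms) {
  stopifnot(max_size >= 1L, max_size <= n_realms, n_realms <= 16L)
  bits <- 0:(2L^n_realms - 1L)
  sz <- range_size(bits)
  keep <- sz <= max_size
  bits <- bits[keep]
  sz <- sz[keep]
  ord <- order(sz, bits)
  bits <- bits[ord]
  sz <- sz[ord]
  index <- integer(2L^n_realms)
  index[bits + 1L] <- seq_along(bits)
  structure(list(bits = bits, size = sz, n_realms = n_realms,
                 max_size = max_size, index = index),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("Range state space: ", length(x$bits), " states over ", x$n_realms,
      " realms (max range size ", x$max_size, ")\n", sep = "")
  invisible(x)
}

state_pos <- function(space, bits) {
  p <- space$index[bits + 1L]
  if (any(p == 0L & bits != space$bits[1L])) {
    bad <- bits[p == 0L]
    stop("range state(s) outside the state space cap: ", paste(bad, collapse = ", "))
  }
  p
}
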