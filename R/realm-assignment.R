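#' Occupancy grids and realm assignment
#'
#' Species arrive as sets of occupied grid cells on a global lon/lat grid in
#' which every cell belongs to one realm or to none (land/undefined).  A
#' species is assigned to every realm that holds at least a threshold fraction
#' of its occupied cells; the default threshold 1/9 guarantees that a range
#' spread perfectly evenly over all nine realms is counted in all of them.
#'
#' @param cells data.frame with columns `cell` (id), `lon`, `lat`, and `realm`
#'   (realm code or `NA` for cells in no realm).
#' @return An object of class `occupancy_grid`.
#' @export
occupancy_grid <- function(cells) {
  stopifnot(all(c("cell", "lon", "lat", "realm") %in% names(cells)))
  if (anyDuplicated(cells$cell)) stop("duplicate cell ids")
  structure(list(cells = cells), class = "occupancy_grid")
}

#' Fraction of a species' range in each realm
#'
#' Computes, per realm, the fraction of the species' occupied cells falling in
#' that realm.  Cells outside all realms stay in the denominator (the
#' threshold applies to the whole range, not its in-realm portion), so
#' fractions sum to at most 1.  Set `drop_unassigned_cells = TRUE` to restrict
#' the denominator to in-realm cells instead.
#'
#' @param species_cells vector of occupied cell ids (non-empty).
#' @param grid an [occupancy_grid()].
#' @param realms a [realm_set()].
#' @param drop_unassigned_cells denominator policy (default `FALSE`).
#' @return named numeric vector of fractions over the realm set.
#' @export
realm_fractions <- function(species_cells, grid, realms, drop_unassigned_cells = FALSE) {
  if (!length(species_cells)) stop("species occupies zero cells")
  idx <- match(species_cells, grid$cells$cell)
  if (anyNA(idx)) stop("unknown cell id(s)")
  rl <- grid$cells$realm[idx]
  denom <- if (drop_unassigned_cells) sum(!is.na(rl)) else length(rl)
  if (denom == 0) stop("species occupies zero in-realm cells")
  tab <- table(factor(rl, levels = unclass(realms)))
  fr <- as.numeric(tab) / denom
  names(fr) <- unclass(realms)
  fr
}

#' Assign a species to realms by threshold
#'
#' A realm is included iff its range fraction is at least `threshold`.  If no
#' realm reaches the threshold (but some fraction is positive), the species
#' falls back to the single realm with the largest fraction, ties broken by
#' canonical realm order, and the result is flagged.
#'
#' @param fractions output of [realm_fractions()].
#' @param realms a [realm_set()].
#' @param threshold inclusion threshold (default 1/9).
#' @return integer range-state bitmask with attribute `fallback` (logical).
#' @export
assign_realms <- function(fractions, realms, threshold = 1/9) {
  fractions <- fractions[unclass(realms)]
  if (all(fractions == 0)) stop("unassignable species: zero fraction in every realm")
  inc <- which(fractions >= threshold)
  fallback <- FALSE
  if (!length(inc)) {
    inc <- which.max(fractions)  # first max = canonical order tie-break
    fallback <- TRUE
  }
  bits <- as.integer(sum(bitwShiftL(1L, inc - 1L)))
  attr(bits, "fallback") <- fallback
  bits
}

#' Extant species richness per realm
#'
#' Counts, for each realm, the species whose range state includes it.  Summing
#' richness over realms equals summing range sizes over species (both count
#' presence pairs).
#'
#' @param assignments named integer vector of range-state bitmasks.
#' @param realms a [realm_set()].
#' @return named integer vector of counts.
#' @export
realm_richness <- function(assignments, realms) {
  if (!length(assignments)) stop("empty assignment map")
  n <- length(realms)
  counts <- vapply(seq_len(n), function(i) sum(has_bit(assignments, i)), numeric(1))
  stats::setNames(as.integer(counts), unclass(realms))
}
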