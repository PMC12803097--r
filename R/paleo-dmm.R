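#' Paleogeographic snapshots and water masks
#'
#' A snapshot describes the ocean at one epoch: realm seed points (paleo-
#' rotated coordinates carrying realm labels; rotation itself is an input,
#' produced upstream by a tectonic reconstruction) plus a boolean water mask
#' on a regular lon/lat grid.  Realms with no surviving seed point at an epoch
#' are treated as absent for that epoch.
#'
#' @param age epoch age in Ma.
#' @param seeds data.frame with columns `realm`, `lon`, `lat`.
#' @param mask a [water_mask()].
#' @return object of class `paleo_snapshot`.
#' @export
paleo_snapshot <- function(age, seeds, mask) {
  stopifnot(all(c("realm", "lon", "lat") %in% names(seeds)))
  structure(list(age = age, seeds = seeds, mask = mask), class = "paleo_snapshot")
}

#' @rdname paleo_snapshot
#' @param lon,lat vectors of cell-center coordinates (degrees, ascending).
#' @param water logical matrix, `length(lat)` rows by `length(lon)` columns;
#'   `TRUE` marks ocean.
#' @export
water_mask <- function(lon, lat, water) {
  stopifnot(nrow(water) == length(lat), ncol(water) == length(lon))
  dlon <- if (length(lon) > 1) lon[2] - lon[1] else 360
  wrap <- length(lon) > 1 && (max(lon) - min(lon) + dlon) >= 360 - 1e-6
  structure(list(lon = lon, lat = lat, water = water, wrap = wrap),
            class = "water_mask")
}

#' Extrapolate paleo realms over the water mask
#'
#' Labels every water cell with the realm of its nearest seed point
#' (great-circle distance), i.e. a spherical Voronoi extrapolation of the
#' rotated seed points.  Ties go to the realm earlier in canonical order.
#' Land cells stay unlabeled (`NA`).
#'
#' @param snapshot a [paleo_snapshot()].
#' @param realms a [realm_set()].
#' @return character matrix of realm labels, same shape as the water mask.
#' @export
extrapolate_realms <- function(snapshot, realms) {
  mask <- snapshot$mask
  seeds <- snapshot$seeds
  present <- intersect(unclass(realms), unique(seeds$realm))
  if (!length(present)) stop("no seed points for any realm")
  lab <- matrix(NA_character_, nrow(mask$water), ncol(mask$water))
  wet <- which(mask$water, arr.ind = TRUE)
  if (!nrow(wet)) return(lab)
  pts <- cbind(mask$lon[wet[, 2]], mask$lat[wet[, 1]])
  # distance from every wet cell to every seed; pick nearest, canonical-order tie-break
  dmat <- vapply(seq_len(nrow(seeds)), function(s) {
    geosphere::distHaversine(pts, c(seeds$lon[s], seeds$lat[s]))
  }, numeric(nrow(pts)))
  dmat <- matrix(dmat, nrow = nrow(pts))
  seed_rank <- match(seeds$realm, unclass(realms))
  ord <- order(seed_rank)  # canonical order so ties resolve to earlier realm
  dmat <- dmat[, ord, drop = FALSE]
  nearest <- apply(dmat, 1, which.min)
  lab[wet] <- seeds$realm[ord][nearest]
  lab
}

#' Spherical centroids of labeled realms
#'
#' Unweighted spherical mean (unit-vector averaging) of the cell centers
#' carrying each realm label.  A degenerate mean (antipodal configurations,
#' resultant length ~ 0) is an error.
#'
#' @param labels character matrix from [extrapolate_realms()].
#' @param mask the [water_mask()] the labels live on.
#' @return data.frame with columns `realm`, `lon`, `lat`.
#' @export
realm_centroids <- function(labels, mask) {
  rl <- sort(unique(stats::na.omit(as.vector(labels))))
  out <- lapply(rl, function(r) {
    idx <- which(labels == r, arr.ind = TRUE)
    lon <- mask$lon[idx[, 2]] * pi / 180
    lat <- mask$lat[idx[, 1]] * pi / 180
    v <- c(mean(cos(lat) * cos(lon)), mean(cos(lat) * sin(lon)), mean(sin(lat)))
    len <- sqrt(sum(v^2))
    if (len < 1e-9) stop("undefined centroid for realm ", r, " (degenerate spherical mean)")
    data.frame(realm = r,
               lon = atan2(v[2], v[1]) * 180 / pi,
               lat = asin(v[3] / len) * 180 / pi)
  })
  do.call(rbind, out)
}

#' Over-water shortest-path distance matrix
#'
#' Snaps each realm centroid to its nearest water cell and runs Dijkstra on
#' the 8-connected water-cell lattice with great-circle edge weights
#' (longitude wraparound when the mask spans the globe).  Unreachable pairs
#' are `Inf` and flagged with a warning.
#'
#' @param centroids data.frame `realm`, `lon`, `lat`.
#' @param mask a [water_mask()].
#' @return symmetric matrix of distances in km, zero diagonal, realm-labeled.
#' @export
overwater_distance_matrix <- function(centroids, mask) {
  wet <- which(mask$water, arr.ind = TRUE)
  if (!nrow(wet)) stop("water mask has no water cells")
  nr <- nrow(mask$water); nc <- ncol(mask$water)
  cellid <- matrix(0L, nr, nc)
  cellid[wet] <- seq_len(nrow(wet))
  coords <- cbind(mask$lon[wet[, 2]], mask$lat[wet[, 1]])
  # 8-connected edges among water cells
  offs <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1), dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    i2 <- wet[, 1] + offs[k, 1]
    j2 <- wet[, 2] + offs[k, 2]
    if (mask$wrap) {
      j2 <- ((j2 - 1L) %% nc) + 1L
    }
    ok <- i2 >= 1 & i2 <= nr & j2 >= 1 & j2 <= nc
    nb <- integer(nrow(wet)); nb[!ok] <- 0L
    nb[ok] <- cellid[cbind(i2[ok], j2[ok])]
    keep <- nb > 0L
    from <- c(from, which(keep)); to <- c(to, nb[keep])
  }
  dedup <- from < to
  from <- from[dedup]; to <- to[dedup]
  w <- geosphere::distHaversine(coords[from, , drop = FALSE], coords[to, , drop = FALSE]) / 1000
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(wet) - igraph::vcount(g)))
  snap <- vapply(seq_len(nrow(centroids)), function(i) {
    which.min(geosphere::distHaversine(coords, c(centroids$lon[i], centroids$lat[i])))
  }, integer(1))
  D <- igraph::distances(g, v = snap, to = snap, weights = w, algorithm = "dijkstra")
  dimnames(D) <- list(centroids$realm, centroids$realm)
  diag(D) <- 0
  if (any(!is.finite(D))) {
    warning("unreachable realm pair(s) in over-water distance matrix (landlocked basin?)")
  }
  D
}

#' Dispersal multipliers from a distance matrix
#'
#' Min-max normalizes the pairwise distances to \[0, 1\] and subtracts from
#' one, so near realm pairs get multipliers near 1 and the farthest pair gets
#' 0 (or the floor `eps`).  Because the diagonal is zero, min-max over the
#' matrix reduces to division by the maximum.  Infinite distances are first
#' replaced by `inf_factor` times the largest finite entry (documented
#' policy: unreachable pairs become near-zero multipliers, not undefined
#' ones).  If every off-diagonal distance is equal the matrix carries no
#' information; by default such degenerate inputs map to all-ones multipliers
#' (no information, no penalty), flagged via the `degenerate` attribute.
#'
#' @param D symmetric distance matrix, zero diagonal.
#' @param eps floor applied to off-diagonal zeros after normalization
#'   (default 0; a literal 0 makes the farthest pair's dispersal impossible
#'   in the likelihood, so 0.01 is a common choice).
#' @param inf_factor replacement factor for infinite entries.
#' @param degenerate_to_one policy for all-equal off-diagonal distances.
#' @return multiplier matrix M, entries in \[0, 1\], unit diagonal.
#' @export
multipliers_from_distances <- function(D, eps = 0, inf_factor = 1.5,
                                       degenerate_to_one = TRUE) {
  M <- as.matrix(D)
  off <- M[row(M) != col(M)]
  if (any(!is.finite(off))) {
    mx <- max(off[is.finite(off)], 0)
    M[!is.finite(M)] <- inf_factor * mx
    off <- M[row(M) != col(M)]
  }
  if (length(off) && max(off) == 0) {
    res <- matrix(1, nrow(M), ncol(M), dimnames = dimnames(M))
    return(res)
  }
  if (degenerate_to_one && length(unique(off)) == 1L) {
    res <- matrix(1, nrow(M), ncol(M), dimnames = dimnames(M))
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  res <- 1 - M / max(off)
  diag(res) <- 1
  if (eps > 0) res[res < eps & row(res) != col(res)] <- eps
  res
}

#' Time-stratified dispersal multiplier matrices
#'
#' Container for one multiplier matrix per geologic stratum.  Strata are the
#' half-open intervals `[0, b1), [b1, b2), ...` in Ma; the last boundary must
#' be at least the root age of any tree analyzed (a 360 Ma cap stratum is the
#' convention).
#'
#' @param M list of multiplier matrices (youngest stratum first).
#' @param boundaries ascending vector of stratum upper bounds (Ma).
#' @param realms a [realm_set()].
#' @param D optional list of distance matrices (km), same length as `M`.
#' @return object of class `stratified_dmm`.
#' @export
stratified_dmm <- function(M, boundaries, realms, D = NULL) {
  if (length(M) != length(boundaries)) stop("one matrix per stratum required")
  if (any(diff(boundaries) <= 0) || any(boundaries <= 0)) {
    stop("stratum boundaries must be positive and strictly increasing")
  }
  n <- length(realms)
  for (k in seq_along(M)) {
    m <- M[[k]]
    if (!all(dim(m) == c(n, n))) stop("matrix ", k, " has wrong dimension")
    if (max(abs(m - t(m))) > 1e-9) stop("matrix ", k, " is not symmetric")
    if (any(m < -1e-12 | m > 1 + 1e-12)) stop("matrix ", k, " has entries outside [0,1]")
    if (max(abs(diag(m) - 1)) > 1e-12) stop("matrix ", k, " diagonal must be 1")
    dimnames(M[[k]]) <- list(unclass(realms), unclass(realms))
  }
  structure(list(M = M, boundaries = boundaries, realms = realms, D = D),
            class = "stratified_dmm")
}

#' @export
print.stratified_dmm <- function(x, ...) {
  cat("Stratified DMM: ", length(x$M), " strata over ", length(x$realms),
      " realms; boundaries (Ma): ", paste(x$boundaries, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname stratified_dmm
#' @param realms a [realm_set()].
#' @param cap final boundary in Ma.
#' @export
uniform_dmm <- function(realms, cap = 360) {
  n <- length(realms)
  stratified_dmm(list(matrix(1, n, n)), cap, realms)
}

# stratum index containing an age (Ma); ages beyond the cap go to the last stratum
epoch_at <- function(dmm, age) {
  k <- findInterval(age, c(0, dmm$boundaries))
  pmin(pmax(k, 1L), length(dmm$M))
}

#' Preset stratification boundaries
#'
#' The cetacean preset stratifies every 5 Myr from the present to 45 Ma; the
#' preset for the older groups (seagrasses, corals, fishes) every 10 Myr to
#' 140 Ma.  Both close with a cap stratum ending at 360 Ma, which must exceed
#' the root age of the analyzed trees.
#'
#' @param group `"cetacean"` or `"other"`.
#' @return numeric vector of stratum upper bounds (Ma).
#' @export
dmm_preset_boundaries <- function(group = c("cetacean", "other")) {
  group <- match.arg(group)
  if (group == "cetacean") c(seq(5, 45, by = 5), 360) else c(seq(10, 140, by = 10), 360)
}

#' Build a stratified DMM from paleogeographic snapshots
#'
#' Runs the full per-epoch pipeline — Voronoi extrapolation of the rotated
#' seed points, spherical centroids, over-water shortest paths, min-max
#' normalization — for one snapshot per stratum.  Normalization is per epoch
#' by default; set `normalize = "global"` to normalize by the maximum
#' distance across all epochs instead.
#'
#' @param snapshots list of [paleo_snapshot()], youngest first, one per
#'   stratum.
#' @param boundaries stratum upper bounds (Ma), e.g.
#'   [dmm_preset_boundaries()].
#' @param realms a [realm_set()].
#' @param eps multiplier floor, see [multipliers_from_distances()].
#' @param normalize `"per_epoch"` (default) or `"global"`.
#' @return a [stratified_dmm()] with the distance matrices attached.
#' @export
build_stratified_dmm <- function(snapshots, boundaries, realms, eps = 0,
                                 normalize = c("per_epoch", "global")) {
  normalize <- match.arg(normalize)
  if (length(snapshots) != length(boundaries)) {
    stop("need one snapshot per stratum (", length(boundaries), ")")
  }
  Ds <- lapply(snapshots, function(sn) {
    lab <- extrapolate_realms(sn, realms)
    cen <- realm_centroids(lab, sn$mask)
    full_D(overwater_distance_matrix(cen, sn$mask), realms)
  })
  if (normalize == "global") {
    finite <- unlist(lapply(Ds, function(d) d[is.finite(d) & d > 0]))
    gmax <- max(finite)
    Ms <- lapply(Ds, function(d) {
      d[!is.finite(d)] <- 1.5 * gmax
      m <- 1 - d / max(gmax, max(d))
      diag(m) <- 1
      if (eps > 0) m[m < eps & row(m) != col(m)] <- eps
      m
    })
  } else {
    Ms <- lapply(Ds, multipliers_from_distances, eps = eps)
  }
  stratified_dmm(Ms, boundaries, realms, D = Ds)
}

# expand a distance matrix over present realms to the full realm set
# (absent realms get Inf rows/cols -> near-zero multipliers after replacement)
full_D <- function(D, realms) {
  n <- length(realms)
  out <- matrix(Inf, n, n, dimnames = list(unclass(realms), unclass(realms)))
  diag(out) <- 0
  got <- intersect(rownames(D), unclass(realms))
  out[got, got] <- D[got, got]
  out
}
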