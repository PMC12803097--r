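#' Per-realm phylogenetic diversity metrics
#'
#' Computes, from one dated tree and the realm assignment of its tips:
#'
#' * PD — Faith's phylogenetic diversity: total length of the branches
#'   spanning the realm's species;
#' * PE — phylogenetic endemism: each spanning branch's length divided by
#'   the number of realms occupied by its descendant species (union
#'   convention), summed;
#' * WE — weighted endemism: sum over the realm's species of one over their
#'   range size;
#' * ED — evolutionary distinctiveness by fair proportion (each branch's
#'   length split equally among its descendant tips), summarized per realm
#'   by the median and standard deviation over member species.
#'
#' A root edge (`root.edge`), if present, is treated as a branch spanning
#' all tips.
#'
#' @param tree a `phylo`.
#' @param assignments named bitmask vector covering the tips.
#' @param realms a [realm_set()].
#' @return data.frame, one row per realm: `realm`, `PD`, `PE`, `WE`,
#'   `ED_median`, `ED_sd` (NA for realms with no species).
#' @export
phylo_metrics <- function(tree, assignments, realms) {
  ntip <- ape::Ntip(tree)
  assignments <- assignments[tree$tip.label]
  if (anyNA(assignments)) stop("assignments must cover every tip")
  post <- reorder(tree, "postorder")
  n_node <- ntip + tree$Nnode
  below_bits <- integer(n_node)       # union of descendant tip ranges
  below_tips <- integer(n_node)       # number of descendant tips
  below_bits[seq_len(ntip)] <- assignments
  below_tips[seq_len(ntip)] <- 1L
  for (k in seq_len(nrow(post$edge))) {
    pa <- post$edge[k, 1]; ch <- post$edge[k, 2]
    below_bits[pa] <- bitwOr(below_bits[pa], below_bits[ch])
    below_tips[pa] <- below_tips[pa] + below_tips[ch]
  }
  # per-branch quantities (branch identified by its child node)
  br_child <- post$edge[, 2]
  br_len <- post$edge.length
  br_bits <- below_bits[br_child]
  br_nrealm <- range_size(br_bits)
  br_ntips <- below_tips[br_child]
  if (!is.null(tree$root.edge) && tree$root.edge > 0) {
    br_child <- c(br_child, ntip + 1L)
    br_len <- c(br_len, tree$root.edge)
    br_bits <- c(br_bits, below_bits[ntip + 1L])
    br_nrealm <- c(br_nrealm, range_size(below_bits[ntip + 1L]))
    br_ntips <- c(br_ntips, ntip)
  }
  # fair-proportion ED: accumulate len/ntips down to tips
  ed <- numeric(ntip)
  share <- numeric(n_node)
  for (b in seq_along(br_child)) share[br_child[b]] <- share[br_child[b]] + br_len[b] / br_ntips[b]
  pre <- rev(seq_len(nrow(post$edge)))
  cum <- numeric(n_node)
  cum[ntip + 1L] <- share[ntip + 1L]
  for (k in pre) {
    pa <- post$edge[k, 1]; ch <- post$edge[k, 2]
    cum[ch] <- cum[pa] + share[ch]
  }
  ed <- cum[seq_len(ntip)]
  sizes <- range_size(assignments)
  out <- lapply(seq_along(realms), function(r) {
    members <- has_bit(assignments, r)
    spanning <- has_bit(br_bits, r)
    if (!any(members)) {
      return(data.frame(realm = unclass(realms)[r], PD = NA_real_, PE = NA_real_,
                        WE = NA_real_, ED_median = NA_real_, ED_sd = NA_real_))
    }
    data.frame(realm = unclass(realms)[r],
               PD = sum(br_len[spanning]),
               PE = sum(br_len[spanning] / br_nrealm[spanning]),
               WE = sum(1 / sizes[members]),
               ED_median = stats::median(ed[members]),
               ED_sd = stats::sd(ed[members]))
  })
  do.call(rbind, out)
}

#' @rdname phylo_metrics
#' @return `evol_distinct_fp()` returns the fair-proportion ED of every tip.
#' @export
evol_distinct_fp <- function(tree) {
  ntip <- ape::Ntip(tree)
  post <- reorder(tree, "postorder")
  n_node <- ntip + tree$Nnode
  ntips_below <- integer(n_node); ntips_below[seq_len(ntip)] <- 1L
  for (k in seq_len(nrow(post$edge))) {
    ntips_below[post$edge[k, 1]] <- ntips_below[post$edge[k, 1]] + ntips_below[post$edge[k, 2]]
  }
  share <- numeric(n_node)
  for (k in seq_len(nrow(post$edge))) {
    ch <- post$edge[k, 2]
    share[ch] <- share[ch] + post$edge.length[k] / ntips_below[ch]
  }
  if (!is.null(tree$root.edge) && tree$root.edge > 0) {
    share[ntip + 1L] <- share[ntip + 1L] + tree$root.edge / ntip
  }
  cum <- numeric(n_node)
  cum[ntip + 1L] <- share[ntip + 1L]
  for (k in rev(seq_len(nrow(post$edge)))) {
    cum[post$edge[k, 2]] <- cum[post$edge[k, 1]] + share[post$edge[k, 2]]
  }
  stats::setNames(cum[seq_len(ntip)], tree$tip.label)
}

#' Mean species range size per realm
#'
#' For each realm, the mean number of realms occupied by the species present
#' in it.
#'
#' @param assignments named bitmask vector.
#' @param realms a [realm_set()].
#' @return named numeric vector (NA for empty realms).
#' @export
mean_range_size <- function(assignments, realms) {
  sizes <- range_size(assignments)
  v <- vapply(seq_along(realms), function(r) {
    m <- has_bit(assignments, r)
    if (!any(m)) NA_real_ else mean(sizes[m])
  }, numeric(1))
  stats::setNames(v, unclass(realms))
}

#' Geographic isolation from realm centroids
#'
#' Pairwise centroid distances (great-circle by default, straight chord
#' through the sphere optionally) and the per-realm isolation summary (mean
#' distance to all other realms).
#'
#' @param centroids data.frame `realm`, `lon`, `lat`.
#' @param method `"great_circle"` or `"chord"`.
#' @return list with `distance` (km matrix) and `isolation` (named vector).
#' @export
euclidean_isolation <- function(centroids, method = c("great_circle", "chord")) {
  method <- match.arg(method)
  n <- nrow(centroids)
  D <- matrix(0, n, n, dimnames = list(centroids$realm, centroids$realm))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    gc <- geosphere::distHaversine(c(centroids$lon[a], centroids$lat[a]),
                                   c(centroids$lon[b], centroids$lat[b])) / 1000
    D[a, b] <- if (method == "great_circle") gc else {
      r <- 6378.137
      2 * r * sin(pmin(gc / (2 * r), pi / 2))
    }
  }
  iso <- rowSums(D) / (n - 1)
  list(distance = D, isolation = iso)
}

#' Continental shelf area per realm
#'
#' Sums the area of grid cells whose depth lies within the shelf interval:
#' 0 to 200 m below sea level, the 200 m boundary included.  Depths are
#' negative below sea level; missing depths are excluded.
#'
#' @param depth numeric vector/matrix of cell depths (m; negative = below
#'   sea level).
#' @param realm_labels realm code per cell (same shape).
#' @param cell_area_km2 per-cell area (scalar or same shape).
#' @param realms a [realm_set()].
#' @return named vector of km^2 per realm.
#' @export
shelf_area <- function(depth, realm_labels, cell_area_km2 = 1, realms) {
  depth <- as.vector(depth); realm_labels <- as.vector(realm_labels)
  area <- rep(cell_area_km2, length.out = length(depth))
  shelf <- !is.na(depth) & depth >= -200 & depth < 0
  vapply(unclass(realms), function(r) {
    sum(area[shelf & !is.na(realm_labels) & realm_labels == r])
  }, numeric(1))
}

#' Collinearity screen over a predictor table
#'
#' Iteratively removes predictors until no pair has |Pearson r| above the
#' threshold: at each step the pair with the largest |r| is located and the
#' member with the larger mean |r| against all remaining variables is
#' dropped (ties drop the later column).  Constant columns are dropped first
#' with a warning.
#'
#' @param predictors numeric data.frame/matrix, realms in rows.
#' @param threshold |r| threshold (default 0.7).
#' @return character vector of retained variable names; attribute `dropped`
#'   lists removals in order.
#' @export
collinearity_screen <- function(predictors, threshold = 0.7) {
  X <- as.data.frame(predictors)
  if (ncol(X) < 2L) stop("need at least 2 variables")
  if (nrow(X) < 3L) stop("need at least 3 rows")
  keep <- names(X)
  dropped <- character(0)
  const <- vapply(X, function(v) stats::sd(v, na.rm = TRUE) == 0 || all(is.na(v)), logical(1))
  if (any(const)) {
    warning("dropping constant column(s): ", paste(names(X)[const], collapse = ", "))
    dropped <- names(X)[const]
    keep <- setdiff(keep, dropped)
  }
  repeat {
    if (length(keep) < 2L) break
    C <- abs(stats::cor(X[keep], use = "pairwise.complete.obs"))
    diag(C) <- 0
    mx <- max(C)
    if (mx <= threshold) break
    idx <- which(C == mx, arr.ind = TRUE)[1, ]
    pair <- keep[idx]
    means <- colMeans(C)[pair]
    drop_var <- if (means[1] > means[2]) pair[1]
      else if (means[2] > means[1]) pair[2]
      else pair[which.max(match(pair, keep))]
    dropped <- c(dropped, drop_var)
    keep <- setdiff(keep, drop_var)
  }
  attr(keep, "dropped") <- dropped
  keep
}
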