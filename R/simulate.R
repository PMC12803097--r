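#' Simulate a dated birth-death clade
#'
#' Ultrametric birth-death tree conditioned on the number of extant tips
#' (via [ape::rphylo()]), reproducible per seed.  Branch lengths are in Myr.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param lambda birth rate (/Myr).
#' @param mu death rate (/Myr), `mu < lambda`.
#' @param seed integer seed (optional).
#' @return a validated `phylo` with `root_age` attribute.
#' @export
sim_tree <- function(n_tips, lambda = 1, mu = 0, seed = NULL) {
  stopifnot(n_tips >= 2, lambda > mu, mu >= 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = lambda, death = mu)
  validate_phylogeny(tr)
}

#' Simulate range evolution forward along a tree
#'
#' Forward (Gillespie) simulation of the same generative process the
#' likelihood integrates over: the root range is drawn from a flat prior
#' over non-empty states (or fixed), anagenetic dispersal/extirpation events
#' occur at the epoch-dependent rates of the stratified generator, and a
#' cladogenetic event drawn from the model's event table fires at every
#' node.  The Q and event-table builders are the exact ones used by the
#' likelihood, so simulator and inference share a single source of truth.
#'
#' A lineage whose range hits empty is extinct-in-place; since tip ranges
#' must be non-empty the whole simulation is resampled (up to
#' `max_resample` times) whenever any tip ends empty.
#'
#' @param tree a dated `phylo`.
#' @param realms a [realm_set()].
#' @param dmm a [stratified_dmm()].
#' @param model model name.
#' @param params true [model_params()].
#' @param seed integer seed (optional).
#' @param max_size range-size cap.
#' @param max_resample resampling cap for empty-tip outcomes.
#' @param root_state optional fixed root bitmask.
#' @return list with `clade` (a [clade_data()]) and `history` (a
#'   `bsm_history` ground-truth event log, `map_id = 0`).
#' @export
sim_ranges <- function(tree, realms, dmm, model = "DEC", params, seed = NULL,
                       max_size = NULL, max_resample = 100L, root_state = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(realms)
  if (is.null(max_size)) max_size <- n
  space <- enumerate_states(n, max_size)
  ages <- node_ages(tree)
  if (max(ages) > max(dmm$boundaries) + 1e-9) stop("DMM cap younger than root age")
  Qs <- lapply(dmm$M, function(M) build_Q(params, M, space))
  structs <- lapply(dmm$M, function(M) clado_structure(model, space, M))
  probs <- lapply(structs, clado_probs, params = params)
  ntip <- ape::Ntip(tree)
  n_node <- ntip + tree$Nnode
  post <- reorder(tree, "postorder")
  kids <- split(post$edge[, 2], post$edge[, 1])
  for (attempt in seq_len(max_resample)) {
    node_state <- integer(n_node)
    corner <- integer(n_node)
    events <- list()
    root <- ntip + 1L
    node_state[root] <- if (!is.null(root_state)) root_state else
      sample(space$bits[space$bits != 0L], 1)
    ok <- TRUE
    for (k in rev(seq_len(nrow(post$edge)))) {  # preorder
      pa <- post$edge[k, 1]; ch <- post$edge[k, 2]
      chs <- kids[[as.character(pa)]]
      if (corner[chs[1]] == 0L && corner[chs[2]] == 0L) {
        if (node_state[pa] == 0L) { ok <- FALSE; break }
        ep <- epoch_at(dmm, ages[pa])
        st <- structs[[ep]]
        rows <- which(st$anc == node_state[pa])
        r <- rows[sample.int(length(rows), 1, prob = probs[[ep]][rows])]
        corner[chs[1]] <- st$left[r]; corner[chs[2]] <- st$right[r]
        events[[length(events) + 1L]] <- data.frame(
          node = pa, time_ma = ages[pa], kind = "cladogenetic", type = st$type[r],
          from = node_state[pa], to = NA_integer_,
          left = st$left[r], right = st$right[r], stringsAsFactors = FALSE)
      }
      sim <- gillespie_branch(Qs, dmm, space, corner[ch], ages[pa], ages[ch], ch)
      node_state[ch] <- sim$end_state
      if (nrow(sim$events)) events[[length(events) + 1L]] <- sim$events
      if (ch <= ntip && sim$end_state == 0L) { ok <- FALSE; break }
    }
    if (!ok) next
    ev <- if (length(events)) do.call(rbind, events) else empty_events()
    ev <- ev[order(-ev$time_ma), , drop = FALSE]
    rownames(ev) <- NULL
    history <- structure(list(map_id = 0L, node_state = node_state,
                              corner = corner, events = ev,
                              model = model, params = params),
                         class = "bsm_history")
    ranges <- stats::setNames(node_state[seq_len(ntip)], tree$tip.label)
    return(list(clade = clade_data(tree, ranges, realms), history = history))
  }
  stop("forward simulation produced an empty tip range in every attempt; ",
       "extirpation rate too high for this tree")
}

# Gillespie simulation along one branch from age_old down to age_young,
# with the epoch-dependent generator; returns end state and events
gillespie_branch <- function(Qs, dmm, space, start_bits, age_old, age_young, node_id) {
  cur <- state_pos(space, start_bits)
  a <- age_old
  out <- list()
  repeat {
    ep <- epoch_at(dmm, a - 1e-12)
    # epoch floor (next boundary younger than a)
    lower_bounds <- c(0, dmm$boundaries)
    floor_age <- max(lower_bounds[lower_bounds < a - 1e-12], 0)
    seg_end <- max(age_young, floor_age)
    rate <- -Qs[[ep]][cur, cur]
    if (rate <= 0) {
      a <- seg_end
    } else {
      wait <- stats::rexp(1, rate)
      if (a - wait <= seg_end) {
        a <- seg_end
      } else {
        a <- a - wait
        row <- Qs[[ep]][cur, ]
        row[cur] <- 0
        nxt <- sample.int(length(row), 1, prob = row)
        out[[length(out) + 1L]] <- data.frame(
          node = node_id, time_ma = a, kind = "anagenetic",
          type = if (range_size(space$bits[nxt]) > range_size(space$bits[cur]))
            "dispersal" else "extinction",
          from = space$bits[cur], to = space$bits[nxt],
          left = NA_integer_, right = NA_integer_, stringsAsFactors = FALSE)
        cur <- nxt
        next
      }
    }
    if (a <= age_young + 1e-12) break
  }
  list(end_state = space$bits[cur],
       events = if (length(out)) do.call(rbind, out) else empty_events())
}

#' Simulate a drifting paleogeography
#'
#' Builds one snapshot per stratum: realm seed points drifting linearly in
#' longitude/latitude as epochs get older (emulating plate motion of
#' rotated present-day points) over an all-water global grid, with optional
#' land bars inserted between given longitudes from a given epoch onward
#' (emulating, e.g., a closing seaway).
#'
#' @param realms a [realm_set()].
#' @param boundaries stratum upper bounds (Ma).
#' @param seed integer seed.
#' @param drift_deg_per_ma per-realm drift speed (degrees lon per Myr);
#'   recycled.
#' @param lon_step,lat_step grid resolution in degrees.
#' @param land_bars optional list of lists with elements `from_epoch`
#'   (stratum index), `lon_min`, `lon_max`: columns in that longitude band
#'   become land from that stratum (older strata) onward.
#' @return list of [paleo_snapshot()], youngest first.
#' @export
sim_paleogeography <- function(realms, boundaries, seed = 1L,
                               drift_deg_per_ma = 0.3,
                               lon_step = 10, lat_step = 10,
                               land_bars = NULL) {
  set.seed(seed)
  n <- length(realms)
  lon <- seq(-180 + lon_step / 2, 180 - lon_step / 2, by = lon_step)
  lat <- seq(-80, 80, by = lat_step)
  # present-day seed anchors spread around the globe at mid latitudes
  anchor_lon <- seq(-160, 160, length.out = n)
  anchor_lat <- rep(c(-25, 25), length.out = n)
  drift <- rep(drift_deg_per_ma, length.out = n)
  dir <- rep(c(1, -1), length.out = n)
  mids <- (c(0, boundaries[-length(boundaries)]) + boundaries) / 2
  lapply(seq_along(boundaries), function(k) {
    water <- matrix(TRUE, length(lat), length(lon))
    if (!is.null(land_bars)) {
      for (b in land_bars) {
        if (k >= b$from_epoch) {
          water[, lon >= b$lon_min & lon <= b$lon_max] <- FALSE
        }
      }
    }
    sl <- ((anchor_lon + dir * drift * mids[k] + 180) %% 360) - 180
    seeds <- data.frame(realm = unclass(realms), lon = sl, lat = anchor_lat)
    # keep seeds on water: nudge any seed sitting on a land bar eastward
    for (s in seq_len(nrow(seeds))) {
      tries <- 0
      while (tries < 72) {
        j <- which.min(abs(lon - seeds$lon[s]))
        i <- which.min(abs(lat - seeds$lat[s]))
        if (water[i, j]) break
        seeds$lon[s] <- ((seeds$lon[s] + lon_step + 180) %% 360) - 180
        tries <- tries + 1
      }
    }
    paleo_snapshot(mids[k], seeds, water_mask(lon, lat, water))
  })
}

#' Build a benchmark bundle of simulated clades
#'
#' Desk-scale analogue of a multi-group global analysis: several pseudo-
#' groups, each with a handful of birth-death clades whose tip ranges were
#' evolved forward under known parameters over five realms, plus the
#' stratified DMM used, the pooled realm richness, and a per-realm predictor
#' table.  Everything needed to exercise the full pipeline end to end.
#'
#' @param n_groups number of pseudo-groups (default 4).
#' @param n_clades_per_group clades per group (default 5).
#' @param tip_range clade size bounds (default 10 to 50).
#' @param model generating model for every group.
#' @param params true [model_params()].
#' @param seed master seed.
#' @param n_realms number of realms (default 5, labels from the global nine).
#' @param stratified if `TRUE`, use a drifting paleogeography DMM; otherwise
#'   a uniform DMM.
#' @return list with `clades` (list of lists of [clade_data()]),
#'   `histories` (matching ground-truth logs), `dmm`, `realms`, `richness`,
#'   `params`, `model`, `groups`.
#' @export
make_benchmark_bundle <- function(n_groups = 4L, n_clades_per_group = 5L,
                                  tip_range = c(10L, 50L), model = "DEC",
                                  params = model_params(d = 0.05, e = 0.02),
                                  seed = 1L, n_realms = 5L, stratified = TRUE) {
  set.seed(seed)
  realms <- realm_set(c("NC", "CI", "CP", "EA", "EP", "SC", "WA", "WI", "NP")[seq_len(n_realms)])
  dmm <- if (stratified) {
    snaps <- sim_paleogeography(realms, boundaries = c(20, 40, 360), seed = seed)
    build_stratified_dmm(snaps, c(20, 40, 360), realms, eps = 0.01)
  } else uniform_dmm(realms)
  groups <- paste0("group", seq_len(n_groups))
  clades <- list(); histories <- list()
  for (g in seq_len(n_groups)) {
    clades[[g]] <- list(); histories[[g]] <- list()
    for (c in seq_len(n_clades_per_group)) {
      nt <- sample(tip_range[1]:tip_range[2], 1)
      tr <- sim_tree(nt, lambda = 0.4, mu = 0.1)
      tr$tip.label <- sprintf("g%d_c%d_%s", g, c, tr$tip.label)
      sim <- sim_ranges(tr, realms, dmm, model, params)
      sim$clade$group <- groups[g]
      clades[[g]][[c]] <- sim$clade
      histories[[g]][[c]] <- sim$history
    }
  }
  names(clades) <- groups; names(histories) <- groups
  all_ranges <- unlist(lapply(clades, function(gl) lapply(gl, `[[`, "ranges")))
  richness <- realm_richness(unlist(all_ranges), realms)
  list(clades = clades, histories = histories, dmm = dmm, realms = realms,
       richness = richness, params = params, model = model, groups = groups)
}
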