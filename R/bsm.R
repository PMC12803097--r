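#' Sample one biogeographic stochastic map
#'
#' Draws a full range-evolution history consistent with the fitted model and
#' the tip data: node states are sampled from their conditional posteriors
#' (downpass likelihoods plus the flat non-empty root prior), a cladogenetic
#' event is sampled at each node proportional to its event-table probability
#' times the daughter subtree likelihoods, and anagenetic paths along each
#' branch are sampled conditional on the branch endpoint states by
#' uniformization.  Replaying the returned event log reproduces every branch
#' endpoint state exactly.
#'
#' @param clade a [clade_data()].
#' @param dmm a [stratified_dmm()].
#' @param model model name.
#' @param params a [model_params()] (normally the MLE).
#' @param seed integer seed.
#' @param max_size optional range-size cap.
#' @param map_id replicate id stored in the log.
#' @return An object of class `bsm_history`: list with `map_id`,
#'   `node_state` (bitmask per node), `corner` (branch-top state per child
#'   node), and `events` (data.frame: `node`, `time_ma`, `kind`, `type`,
#'   `from`, `to`, `left`, `right`).
#' @export
sample_history <- function(clade, dmm, model, params, seed = NULL,
                           max_size = NULL, map_id = 1L) {
  if (!is.null(seed)) set.seed(seed)
  ctx <- lik_context(clade, dmm, model, max_size)
  det <- lnL_context(ctx, params, details = TRUE)
  if (!is.finite(det$lnL)) stop("data impossible under these parameters; cannot map")
  space <- ctx$space
  ns <- length(space$bits)
  n_node <- ctx$ntip + length(ctx$kids)
  Qs <- lapply(dmm$M, function(M) build_Q(params, M, space))
  node_state <- integer(n_node)
  corner <- integer(n_node)  # indexed by child node id
  events <- list()
  # root state
  root <- ctx$ntip + 1L
  pri <- as.numeric(space$bits != 0L)
  w <- pri * det$L[root, ]
  node_state[root] <- space$bits[sample.int(ns, 1, prob = w)]
  # preorder: parents before children
  pre <- rev(seq_len(nrow(ctx$edge)))
  # handle nodes: when we first meet a node as parent, sample its clado event
  clado_done <- logical(n_node)
  edge_of_child <- match(seq_len(n_node), ctx$edge[, 2])
  for (k in pre) {
    pa <- ctx$edge[k, 1]
    if (!clado_done[pa]) {
      ev <- sample_clado(ctx, det, pa, node_state[pa])
      chs <- ctx$kids[[as.character(pa)]]
      corner[chs[1]] <- ev$left
      corner[chs[2]] <- ev$right
      events[[length(events) + 1L]] <- data.frame(
        node = pa, time_ma = ctx$ages[pa], kind = "cladogenetic",
        type = ev$type, from = node_state[pa], to = NA_integer_,
        left = ev$left, right = ev$right, stringsAsFactors = FALSE)
      clado_done[pa] <- TRUE
    }
    ch <- ctx$edge[k, 2]
    br <- sample_branch(ctx, det, Qs, k, corner[ch])
    node_state[ch] <- br$end_state
    if (nrow(br$events)) events[[length(events) + 1L]] <- br$events
  }
  ev <- if (length(events)) do.call(rbind, events) else empty_events()
  ev <- ev[order(-ev$time_ma), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(map_id = map_id, node_state = node_state, corner = corner,
                 events = ev, model = model, params = params),
            class = "bsm_history")
}

empty_events <- function() {
  data.frame(node = integer(0), time_ma = numeric(0), kind = character(0),
             type = character(0), from = integer(0), to = integer(0),
             left = integer(0), right = integer(0), stringsAsFactors = FALSE)
}

# sample the cladogenetic event at node nd given its sampled state
sample_clado <- function(ctx, det, nd, state_bits) {
  ep <- ctx$node_epoch[nd]
  st <- ctx$structs[[ep]]
  chs <- ctx$kids[[as.character(nd)]]
  rows <- which(st$anc == state_bits)
  if (!length(rows)) stop("no cladogenetic event available for sampled state")
  w <- det$probs[[ep]][rows] * det$B[chs[1], st$left_pos[rows]] *
    det$B[chs[2], st$right_pos[rows]]
  if (sum(w) <= 0) stop("zero-probability cladogenesis; inconsistent state")
  r <- rows[sample.int(length(rows), 1, prob = w)]
  list(left = st$left[r], right = st$right[r], type = st$type[r])
}

# sample the anagenetic path along edge k given the corner (branch-top) state
sample_branch <- function(ctx, det, Qs, k, corner_bits) {
  ch <- ctx$edge[k, 2]
  space <- ctx$space
  segs <- ctx$segs[[k]]  # youngest first
  K <- nrow(segs)
  # suffix vectors W[[s]] = likelihood of data below, seen from the old end of
  # segment s (forward order = oldest segment first is s = K)
  Lch <- det$L[ch, ]
  if (ch <= ctx$ntip) { Lch <- numeric(length(space$bits)); Lch[ctx$tip_pos[ch]] <- 1 }
  W <- vector("list", K + 1L)
  W[[1L]] <- Lch
  Pseg <- vector("list", K)
  for (s in seq_len(K)) {
    Pseg[[s]] <- det$props[[segs$epoch[s]]](segs$old[s] - segs$young[s])
    W[[s + 1L]] <- as.numeric(Pseg[[s]] %*% W[[s]])
  }
  cur <- state_pos(space, corner_bits)
  out <- list()
  for (s in rev(seq_len(K))) {  # forward in time: oldest segment first
    wts <- Pseg[[s]][cur, ] * W[[s]]
    if (sum(wts) <= 0) stop("endpoint sampling failed (zero mass)")
    nxt <- sample.int(length(wts), 1, prob = wts)
    path <- sample_ctmc_path(Qs[[segs$epoch[s]]], cur, nxt,
                             segs$old[s] - segs$young[s])
    if (nrow(path)) {
      out[[length(out) + 1L]] <- data.frame(
        node = ch, time_ma = segs$old[s] - path$time,
        kind = "anagenetic",
        type = ifelse(range_size(space$bits[path$to]) >
                        range_size(space$bits[path$from]), "dispersal", "extinction"),
        from = space$bits[path$from], to = space$bits[path$to],
        left = NA_integer_, right = NA_integer_, stringsAsFactors = FALSE)
    }
    cur <- nxt
  }
  list(end_state = space$bits[cur],
       events = if (length(out)) do.call(rbind, out) else empty_events())
}

# endpoint-conditioned CTMC path by uniformization; returns real transitions
# as data.frame(time, from, to) with time measured from the segment start
sample_ctmc_path <- function(Q, i, j, t, max_retries = 1000L) {
  ns <- nrow(Q)
  Omega <- max(-diag(Q))
  if (Omega <= 0) {
    if (i != j) stop("impossible endpoints under zero rates")
    return(data.frame(time = numeric(0), from = integer(0), to = integer(0)))
  }
  R <- diag(ns) + Q / Omega
  lam <- Omega * t
  # truncation point for the Poisson jump-count series
  nmax <- max(20L, ceiling(lam + 12 * sqrt(lam + 1)))
  powers <- vector("list", nmax + 1L)
  powers[[1L]] <- diag(ns)
  for (n in seq_len(nmax)) powers[[n + 1L]] <- powers[[n]] %*% R
  wn <- stats::dpois(0:nmax, lam) *
    vapply(0:nmax, function(n) powers[[n + 1L]][i, j], numeric(1))
  if (sum(wn) <= 0) stop("endpoint pair has zero probability")
  for (attempt in seq_len(max_retries)) {
    N <- sample.int(nmax + 1L, 1, prob = wn) - 1L
    states <- integer(N + 1L)
    states[1L] <- i
    ok <- TRUE
    if (N > 0L) {
      for (m in seq_len(N)) {
        rem <- N - m
        wts <- R[states[m], ] * powers[[rem + 1L]][, j]
        if (sum(wts) <= 0) { ok <- FALSE; break }
        states[m + 1L] <- sample.int(ns, 1, prob = wts)
      }
    }
    if (!ok || states[N + 1L] != j) next
    times <- sort(stats::runif(N, 0, t))
    keep <- which(states[-1L] != states[-(N + 1L)])
    return(data.frame(time = times[keep],
                      from = states[keep], to = states[keep + 1L]))
  }
  stop("endpoint-conditioned path sampling failed after ", max_retries, " retries")
}

#' Run a set of biogeographic stochastic maps
#'
#' Draws `n_maps` independent stochastic maps from a fitted model, with
#' per-map seeds derived deterministically from the master seed.
#'
#' @param clade a [clade_data()] (defaults to the fit's own clade).
#' @param fit a [fit_range_model()] result.
#' @param n_maps number of maps (default 50).
#' @param seed master seed.
#' @return list of `bsm_history`, replicate ids `1..n_maps`.
#' @export
run_bsm <- function(fit, n_maps = 50L, seed = 1L, clade = NULL) {
  if (is.null(clade)) clade <- fit$clade
  if (n_maps == 0L) return(list())
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_maps)
  lapply(seq_len(n_maps), function(i) {
    sample_history(clade, fit$dmm, fit$model, fit$params, seed = seeds[i],
                   max_size = fit$max_size, map_id = i)
  })
}

#' @rdname run_bsm
#' @param object a `range_fit`.
#' @param nsim number of stochastic maps.
#' @param ... unused.
#' @export
simulate.range_fit <- function(object, nsim = 50L, seed = 1L, ...) {
  run_bsm(object, n_maps = nsim, seed = seed)
}

#' Classify and realm-attribute the events of a stochastic map
#'
#' Expands a raw event log into typed, realm-attributed records.  Anagenetic
#' range expansions become `dispersal` (destination = gained realm, source
#' attribution split over the occupied realms), contractions become
#' `extinction` in the lost realm.  Cladogenetic events become
#' `in_situ_speciation` (narrow sympatry and widespread copying, attributed
#' across the sympatric range), `subset_sympatry` (attributed to the nested
#' single-realm daughter), `allopatry` (vicariance, split over the ancestral
#' realms) or `founder_event_speciation` (destination = jump realm, source
#' split over the ancestral realms).  Every dispersal-like record carries a
#' weight; weights sum to 1 per event, so each event contributes exactly one
#' immigration (to `dest`) and one emigration (over its sources).
#'
#' @param log a `bsm_history`.
#' @param realms a [realm_set()].
#' @param source_rule attribution of multi-realm sources: `"fractional"`
#'   (default, weight 1/|R| each), `"max_multiplier"` (all weight on the
#'   occupied realm with the largest multiplier toward the destination,
#'   requires `dmm`), or `"random"` (one occupied realm at random).
#' @param dmm required for `source_rule = "max_multiplier"`.
#' @return data.frame with columns `map_id`, `event_id`, `time_ma`, `type`,
#'   `realm` (source or affected realm), `weight`, `dest`.
#' @export
classify_events <- function(log, realms, source_rule = c("fractional", "max_multiplier", "random"),
                            dmm = NULL) {
  source_rule <- match.arg(source_rule)
  ev <- log$events
  out <- vector("list", nrow(ev))
  for (r in seq_len(nrow(ev))) {
    e <- ev[r, ]
    if (e$kind == "anagenetic") {
      if (e$type == "dispersal") {
        gained <- setdiff(bit_indices(e$to), bit_indices(e$from))
        src <- attribute_sources(bit_indices(e$from), gained, source_rule, dmm, e$time_ma)
        out[[r]] <- data.frame(event_id = r, time_ma = e$time_ma, type = "dispersal",
                               realm = realms[src$idx], weight = src$w,
                               dest = realms[gained], stringsAsFactors = FALSE)
      } else {
        lost <- setdiff(bit_indices(e$from), bit_indices(e$to))
        out[[r]] <- data.frame(event_id = r, time_ma = e$time_ma, type = "extinction",
                               realm = realms[lost], weight = 1,
                               dest = NA_character_, stringsAsFactors = FALSE)
      }
    } else {
      anc <- bit_indices(e$from)
      if (e$type %in% c("narrow_sympatry", "copying")) {
        out[[r]] <- data.frame(event_id = r, time_ma = e$time_ma,
                               type = "in_situ_speciation",
                               realm = realms[anc], weight = 1 / length(anc),
                               dest = NA_character_, stringsAsFactors = FALSE)
      } else if (e$type == "subset_sympatry") {
        nested <- if (range_size(e$left) == 1L) e$left else e$right
        out[[r]] <- data.frame(event_id = r, time_ma = e$time_ma,
                               type = "subset_sympatry",
                               realm = realms[bit_indices(nested)], weight = 1,
                               dest = NA_character_, stringsAsFactors = FALSE)
      } else if (e$type == "vicariance") {
        out[[r]] <- data.frame(event_id = r, time_ma = e$time_ma, type = "allopatry",
                               realm = realms[anc], weight = 1 / length(anc),
                               dest = NA_character_, stringsAsFactors = FALSE)
      } else if (e$type == "founder") {
        jump <- if (!bitwAnd(e$left, e$from)) e$left else e$right
        dest <- bit_indices(jump)
        src <- attribute_sources(anc, dest, source_rule, dmm, e$time_ma)
        out[[r]] <- data.frame(event_id = r, time_ma = e$time_ma,
                               type = "founder_event_speciation",
                               realm = realms[src$idx], weight = src$w,
                               dest = realms[dest], stringsAsFactors = FALSE)
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(event_id = integer(0), time_ma = numeric(0), type = character(0),
               realm = character(0), weight = numeric(0), dest = character(0),
               stringsAsFactors = FALSE)
  cbind(map_id = rep(log$map_id, nrow(res)), res)
}

attribute_sources <- function(occ_idx, dest_idx, rule, dmm, age) {
  if (rule == "fractional" || length(occ_idx) == 1L) {
    return(list(idx = occ_idx, w = rep(1 / length(occ_idx), length(occ_idx))))
  }
  if (rule == "max_multiplier") {
    if (is.null(dmm)) stop("source_rule 'max_multiplier' needs a dmm")
    M <- dmm$M[[epoch_at(dmm, age)]]
    pick <- occ_idx[which.max(M[occ_idx, dest_idx])]
    return(list(idx = pick, w = 1))
  }
  list(idx = sample(occ_idx, 1), w = 1)
}

#' Replay a stochastic map and verify its consistency
#'
#' Applies each branch's anagenetic events, in time order, to the branch-top
#' (corner) state and checks that the result matches the sampled state at the
#' branch's child node; also checks that each cladogenetic event's daughter
#' states match the recorded corners.
#'
#' @param log a `bsm_history`.
#' @param clade the [clade_data()] it was sampled from.
#' @return `TRUE` invisibly if consistent; otherwise an error.
#' @export
replay_history <- function(log, clade) {
  tree <- clade$tree
  for (k in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[k, 2]
    st <- replay_branch(log, ch)
    if (st != log$node_state[ch]) {
      stop("replay mismatch at node ", ch, ": got ", st, " expected ", log$node_state[ch])
    }
  }
  invisible(TRUE)
}

# state at the young end of the branch above node ch, by replaying events
replay_branch <- function(log, ch) {
  st <- log$corner[ch]
  ev <- log$events
  rows <- which(ev$node == ch & ev$kind == "anagenetic")
  if (length(rows)) {
    rows <- rows[order(-ev$time_ma[rows])]
    for (r in rows) {
      if (ev$from[r] != st) stop("replay: branch event does not chain")
      st <- ev$to[r]
    }
  }
  st
}
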