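event_types <- c("in_situ_speciation", "founder_event_speciation", "allopatry",
                 "subset_sympatry", "dispersal", "extinction")

# flatten run_bsm output (one clade) or a list of such lists (several clades)
# into one classified data.frame per map index
classified_by_map <- function(histories, realms, source_rule = "fractional", dmm = NULL) {
  if (inherits(histories[[1]], "bsm_history")) histories <- list(histories)
  n_maps <- unique(vapply(histories, length, integer(1)))
  if (length(n_maps) != 1L) stop("all clades must carry the same number of maps")
  lapply(seq_len(n_maps), function(m) {
    do.call(rbind, lapply(histories, function(h) {
      classify_events(h[[m]], realms, source_rule = source_rule, dmm = dmm)
    }))
  })
}

#' Tally classified events into summary tables
#'
#' Aggregates stochastic maps into the two summary products: a realm-by-type
#' event table (per-map counts averaged over maps, summed over clades) and a
#' realm-by-realm interchange matrix built from the source/destination
#' attributions of dispersal and founder events (source realms in rows, sink
#' realms in columns).  `immigration` and `emigration` columns are derived
#' from those attributions: each dispersal-like event contributes exactly one
#' immigration and one emigration in total.  Per-cell spread across maps is
#' reported as the median and the 2.5/97.5% quantiles (linear interpolation).
#'
#' @param histories output of [run_bsm()] for one clade, or a list of such
#'   outputs for several clades (same number of maps each).
#' @param realms a [realm_set()].
#' @param source_rule,dmm passed to [classify_events()].
#' @return object of class `event_tally`: list with `event_table` (mean
#'   realm x type matrix including immigration/emigration columns), `median`,
#'   `lower`, `upper` (same shape), `interchange` (mean source x sink
#'   matrix), `in_situ`, `extinction_diag` (per-realm means for the
#'   interchange diagonal), `type_totals` (mean global count per event
#'   type) and `n_maps`.
#' @export
tally <- function(histories, realms, source_rule = "fractional", dmm = NULL) {
  maps <- classified_by_map(histories, realms, source_rule, dmm)
  if (!length(maps)) stop("empty logs")
  n <- length(realms)
  cols <- c(event_types, "immigration", "emigration")
  per_map <- array(0, dim = c(n, length(cols), length(maps)),
                   dimnames = list(unclass(realms), cols, NULL))
  inter <- array(0, dim = c(n, n, length(maps)),
                 dimnames = list(unclass(realms), unclass(realms), NULL))
  totals <- matrix(0, length(maps), length(event_types),
                   dimnames = list(NULL, event_types))
  for (m in seq_along(maps)) {
    cl <- maps[[m]]
    if (is.null(cl) || !nrow(cl)) next
    for (ty in event_types) {
      sub <- cl[cl$type == ty, , drop = FALSE]
      if (!nrow(sub)) next
      agg <- rowsum(sub$weight, sub$realm)
      per_map[rownames(agg), ty, m] <- agg
      # one count per event regardless of attribution splitting
      totals[m, ty] <- length(unique(sub$event_id))
    }
    disp <- cl[cl$type %in% c("dispersal", "founder_event_speciation"), , drop = FALSE]
    if (nrow(disp)) {
      em <- rowsum(disp$weight, disp$realm)
      per_map[rownames(em), "emigration", m] <- em
      im <- rowsum(disp$weight, disp$dest)
      per_map[rownames(im), "immigration", m] <- im
      fl <- rowsum(disp$weight, paste(disp$realm, disp$dest, sep = "\r"))
      key <- do.call(rbind, strsplit(rownames(fl), "\r", fixed = TRUE))
      inter[cbind(match(key[, 1], unclass(realms)), match(key[, 2], unclass(realms)), m)] <- fl
    }
  }
  qfun <- function(p) apply(per_map, c(1, 2), stats::quantile, probs = p, type = 7)
  structure(list(
    event_table = apply(per_map, c(1, 2), mean),
    median = qfun(0.5), lower = qfun(0.025), upper = qfun(0.975),
    interchange = apply(inter, c(1, 2), mean),
    in_situ = apply(per_map[, "in_situ_speciation", , drop = FALSE], 1, mean),
    extinction_diag = apply(per_map[, "extinction", , drop = FALSE], 1, mean),
    type_totals = colMeans(totals),
    n_maps = length(maps), realms = realms), class = "event_tally")
}

#' @export
print.event_tally <- function(x, ...) {
  cat("Event tally over", x$n_maps, "stochastic maps\n")
  print(round(x$event_table, 3))
  invisible(x)
}

#' Share of each biogeographic process
#'
#' Percentage contribution of each event type to the grand total.
#'
#' @param totals named non-negative vector of event-type totals.
#' @return named vector of percentages summing to 100.
#' @examples
#' process_shares(c(in_situ = 60, dispersal = 40))
#' @export
process_shares <- function(totals) {
  if (any(totals < 0)) stop("negative totals")
  s <- sum(totals)
  if (s == 0) stop("all-zero totals")
  100 * totals / s
}

#' Standardize event counts by realm richness
#'
#' Divides each realm's event counts by its extant species richness, giving
#' per-species rates, optionally rescaled (e.g. per 1,000 species).  Realms
#' with richness of 1 or fewer species are excluded (value `NA`, listed in
#' the `excluded` attribute) since a per-species rate is meaningless there.
#'
#' @param table realm x type matrix (or a named per-realm vector).
#' @param richness named richness vector, see [realm_richness()].
#' @param scale multiplier applied after division (default 1).
#' @return standardized table with attribute `excluded`.
#' @export
standardize_by_richness <- function(table, richness, scale = 1) {
  vec <- is.null(dim(table))
  if (vec) table <- matrix(table, ncol = 1, dimnames = list(names(table), "value"))
  rich <- richness[rownames(table)]
  excl <- rownames(table)[is.na(rich) | rich <= 1]
  out <- sweep(table, 1, as.numeric(rich), "/") * scale
  out[rownames(table) %in% excl, ] <- NA_real_
  if (vec) out <- stats::setNames(out[, 1], rownames(table))
  attr(out, "excluded") <- excl
  out
}

#' Per-realm share of an event type
#'
#' Each included realm's percentage of the summed (typically
#' richness-standardized) values; excluded realms get `NA`.
#'
#' @param values named per-realm values.
#' @param exclude realm codes to exclude.
#' @return named percentage vector over the included realms.
#' @export
realm_share <- function(values, exclude = character(0)) {
  keep <- setdiff(names(values)[!is.na(values)], exclude)
  if (!length(keep)) stop("no realms left after exclusion")
  out <- rep(NA_real_, length(values))
  names(out) <- names(values)
  out[keep] <- 100 * values[keep] / sum(values[keep])
  out
}

#' Rolling binned event series
#'
#' Bins classified events per realm and type into 1-Myr bins over the recent
#' `span` Ma, averages counts across maps, and applies a centered rolling
#' mean (3-bin window by default, partial windows averaged over the
#' available bins).  Events older than the span are dropped (their count is
#' reported in the `dropped` attribute).  Optional richness standardization
#' is applied after binning.
#'
#' @param classified list of per-map classified data.frames (see
#'   [classify_events()]) or one stacked data.frame with a `map_id` column.
#' @param realms a [realm_set()].
#' @param bin bin width in Myr.
#' @param window rolling window in bins.
#' @param span series span in Ma.
#' @param richness optional named richness vector.
#' @param scale scale factor used with `richness`.
#' @return data.frame with columns `realm`, `type`, `bin` (bin start age,
#'   Ma), `value`.
#' @export
binned_series <- function(classified, realms, bin = 1, window = 3, span = 65,
                          richness = NULL, scale = 1) {
  if (is.data.frame(classified)) classified <- split(classified, classified$map_id)
  n_maps <- length(classified)
  edges <- seq(0, span, by = bin)
  n_bins <- length(edges) - 1L
  types <- c(event_types, "immigration", "emigration")
  acc <- array(0, dim = c(length(realms), length(types), n_bins),
               dimnames = list(unclass(realms), types, NULL))
  dropped <- 0L
  for (cl in classified) {
    if (is.null(cl) || !nrow(cl)) next
    old <- cl$time_ma >= span
    dropped <- dropped + length(unique(cl$event_id[old]))
    cl <- cl[!old, , drop = FALSE]
    if (!nrow(cl)) next
    bidx <- pmin(floor(cl$time_ma / bin) + 1L, n_bins)
    add_rows <- function(realm, type, w, b) {
      for (u in seq_along(w)) {
        acc[realm[u], type[u], b[u]] <<- acc[realm[u], type[u], b[u]] + w[u]
      }
    }
    add_rows(cl$realm, cl$type, cl$weight, bidx)
    disp <- cl$type %in% c("dispersal", "founder_event_speciation")
    if (any(disp)) {
      add_rows(cl$realm[disp], rep("emigration", sum(disp)), cl$weight[disp], bidx[disp])
      add_rows(cl$dest[disp], rep("immigration", sum(disp)), cl$weight[disp], bidx[disp])
    }
  }
  acc <- acc / n_maps
  out <- expand.grid(realm = unclass(realms), type = types,
                     bin = edges[-length(edges)], stringsAsFactors = FALSE)
  out$value <- NA_real_
  for (r in seq_along(realms)) {
    rich_div <- if (is.null(richness)) 1 else {
      rv <- richness[unclass(realms)[r]]
      if (is.na(rv) || rv <= 1) NA_real_ else rv / scale
    }
    for (ty in seq_along(types)) {
      sm <- rolling_mean(acc[r, ty, ], window) / rich_div
      out$value[out$realm == unclass(realms)[r] & out$type == types[ty]] <- sm
    }
  }
  attr(out, "dropped") <- dropped
  out
}

# centered rolling mean, partial windows averaged over available bins
rolling_mean <- function(x, window) {
  half <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Lineages through time per realm
#'
#' Replays each stochastic map and counts, per time bin, the lineages whose
#' reconstructed range includes each realm; reports the mean and the
#' 2.5/97.5% quantile envelope across maps.  Lineage ranges are evaluated at
#' each bin's start age.
#'
#' @param histories output of [run_bsm()] (one clade).
#' @param clade the [clade_data()] the maps were sampled from.
#' @param bin bin width in Myr (default 0.1).
#' @return list per realm of a data.frame with columns `age`, `mean`,
#'   `lower`, `upper`.
#' @export
ltt_per_realm <- function(histories, clade, bin = 0.1) {
  realms <- clade$realms
  tree <- clade$tree
  ages <- node_ages(tree)
  ra <- root_age(tree)
  grid <- seq(0, ra - 1e-9, by = bin)
  counts <- array(0L, dim = c(length(grid), length(realms), length(histories)))
  for (h in seq_along(histories)) {
    log <- histories[[h]]
    for (k in seq_len(nrow(tree$edge))) {
      ch <- tree$edge[k, 2]
      pa <- tree$edge[k, 1]
      spans <- grid >= ages[ch] & grid < ages[pa]
      if (!any(spans)) next
      st <- branch_state_at(log, ch, ages[pa], grid[spans])
      for (u in seq_along(st)) {
        idx <- bit_indices(st[u])
        gi <- which(spans)[u]
        counts[gi, idx, h] <- counts[gi, idx, h] + 1L
      }
    }
    # the root itself contributes its two daughter branches only (no stem)
  }
  out <- lapply(seq_along(realms), function(r) {
    m <- counts[, r, , drop = FALSE][, 1, ]
    if (is.null(dim(m))) m <- matrix(m, ncol = length(histories))
    data.frame(age = grid,
               mean = rowMeans(m),
               lower = apply(m, 1, stats::quantile, 0.025, type = 7),
               upper = apply(m, 1, stats::quantile, 0.975, type = 7))
  })
  names(out) <- unclass(realms)
  out
}

# states of the branch above node ch at the requested ages (descending ages
# handled in any order); branch spans [age(ch), age(pa))
branch_state_at <- function(log, ch, age_parent, at_ages) {
  ev <- log$events
  rows <- which(ev$node == ch & ev$kind == "anagenetic")
  st <- log$corner[ch]
  if (!length(rows)) return(rep(st, length(at_ages)))
  rows <- rows[order(-ev$time_ma[rows])]
  times <- ev$time_ma[rows]
  states_after <- ev$to[rows]
  vapply(at_ages, function(a) {
    done <- times > a  # events strictly older than the query age have happened
    if (!any(done)) st else states_after[max(which(done))]
  }, numeric(1))
}

#' Strongest interchange edges
#'
#' Retains the directed source-to-sink edges whose weight reaches the upper
#' `q` fraction of the positive off-diagonal interchange weights (threshold
#' at the `1 - q` linear-interpolation quantile; ties at the threshold are
#' kept).
#'
#' @param interchange source x sink matrix.
#' @param q top fraction to keep (default 0.25).
#' @return data.frame `source`, `sink`, `weight`, strongest first.
#' @export
top_quantile_edges <- function(interchange, q = 0.25) {
  m <- as.matrix(interchange)
  off <- row(m) != col(m)
  w <- m[off]
  pos <- w > 0
  if (!any(pos)) {
    return(data.frame(source = character(0), sink = character(0), weight = numeric(0)))
  }
  thr <- stats::quantile(w[pos], 1 - q, type = 7)
  keep <- which(off & m >= thr & m > 0, arr.ind = TRUE)
  out <- data.frame(source = rownames(m)[keep[, 1]], sink = colnames(m)[keep[, 2]],
                    weight = m[keep])
  out[order(-out$weight), , drop = FALSE]
}
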