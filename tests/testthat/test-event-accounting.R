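manual_history <- function(events, map_id = 1L) {
  structure(list(map_id = map_id, node_state = integer(0), corner = integer(0),
                 events = events), class = "bsm_history")
}

anag <- function(node, time, from, to) {
  data.frame(node = node, time_ma = time, kind = "anagenetic",
             type = if (sum(bitwAnd(to, 2L^(0:8)) > 0) > sum(bitwAnd(from, 2L^(0:8)) > 0))
               "dispersal" else "extinction",
             from = from, to = to, left = NA_integer_, right = NA_integer_,
             stringsAsFactors = FALSE)
}

test_that("tally builds the interchange and event tables from single events", {
  # one dispersal A -> B and one extirpation of A
  ev <- rbind(anag(1L, 2, 1L, 3L), anag(1L, 1, 3L, 2L))
  tl <- tally(list(list(manual_history(ev))), realms2)
  expect_equal(tl$interchange["A", "B"], 1)
  expect_equal(sum(tl$interchange) - tl$interchange["A", "B"], 0)
  expect_equal(unname(tl$extinction_diag["A"]), 1)
  expect_equal(tl$event_table["B", "immigration"], 1)
  expect_equal(tl$event_table["A", "emigration"], 1)
})

test_that("per-map spread uses interpolated quantiles", {
  ev2 <- rbind(anag(1L, 2, 1L, 3L), anag(1L, 1, 1L, 3L))
  maps <- list(list(manual_history(searange:::empty_events()), manual_history(ev2, 2L)))
  tl <- tally(maps, realms2)
  expect_equal(tl$event_table["A", "dispersal"], 1)   # mean of 0 and 2
  expect_equal(unname(tl$lower["A", "dispersal"]), 0.05)
  expect_equal(unname(tl$upper["A", "dispersal"]), 1.95)
})

test_that("tallies equal a naive recount of forward-simulated logs", {
  r3 <- realms3
  dmm <- uniform_dmm(r3)
  tr <- sim_tree(12, lambda = 0.8, seed = 41)
  sim <- sim_ranges(tr, r3, dmm, "DEC+J", model_params(.1, .03, j = .4), seed = 42)
  tl <- tally(list(list(sim$history)), r3)
  ce <- classify_events(sim$history, r3)
  # oracle: naive scan of the classified log
  for (ty in c("dispersal", "extinction", "in_situ_speciation")) {
    for (rl in unclass(r3)) {
      expect_equal(tl$event_table[rl, ty],
                   sum(ce$weight[ce$type == ty & ce$realm == rl]))
    }
  }
  disp <- ce[ce$type %in% c("dispersal", "founder_event_speciation"), ]
  expect_equal(sum(tl$interchange), sum(disp$weight))
  expect_equal(sum(tl$interchange), length(unique(disp$event_id)))
})

test_that("process shares reproduce the printed global percentages", {
  tabs <- example_tables()
  totals <- stats::setNames(tabs$process_totals$total_events,
                            tabs$process_totals$process_type)
  sh <- process_shares(totals)
  expect_equal(sum(sh), 100, tolerance = 1e-9)
  expect_equal(unname(sh["in_situ_speciation"]), 39.18479, tolerance = 1e-4)
  expect_equal(unname(sh["dispersal"]), 15.93153, tolerance = 1e-4)
  expect_equal(unname(sh["extinction"]), 26.19772, tolerance = 1e-4)
  expect_equal(sum(totals), 44508.6, tolerance = 1e-6)
  expect_equal(unname(process_shares(c(a = 5, b = 0))["a"]), 100)
  expect_error(process_shares(c(a = 0, b = 0)), "all-zero")
})

test_that("richness standardization divides, scales and excludes sparse realms", {
  v <- c(A = 10, B = 4, C = 7)
  rich <- c(A = 5, B = 1, C = 0)
  s <- standardize_by_richness(v, rich, scale = 1)
  expect_equal(unname(s["A"]), 2)
  expect_true(is.na(s["B"]))   # richness 1: excluded
  expect_true(is.na(s["C"]))   # richness 0: no division by zero
  expect_setequal(attr(s, "excluded"), c("B", "C"))
  s1000 <- standardize_by_richness(v, rich, scale = 1000)
  expect_equal(unname(s1000["A"]), 2000)
})

test_that("realm shares reproduce the printed extinction percentages", {
  tabs <- example_tables()
  rr <- tabs$realm_rates
  fish <- stats::setNames(rr$extinction[rr$group == "fishes"],
                          rr$realm[rr$group == "fishes"])
  sh <- realm_share(fish)
  expect_equal(unname(round(sh["CI"], 1)), 7.4)
  coral <- stats::setNames(rr$extinction[rr$group == "corals"],
                           rr$realm[rr$group == "corals"])
  shc <- realm_share(coral, exclude = c("NC", "SC", "NP"))
  expect_equal(unname(round(shc["CI"], 1)), 14.4)
  expect_true(is.na(shc["NC"]))
  expect_equal(unname(realm_share(c(A = 3))["A"]), 100)
})

test_that("binned rolling series behave on constant, impulse and empty inputs", {
  mk <- function(times, realm = "A", type = "dispersal") {
    n <- length(times)
    data.frame(map_id = rep(1L, n), event_id = seq_len(n), time_ma = times,
               type = rep(type, n), realm = rep(realm, n), weight = rep(1, n),
               dest = rep("B", n), stringsAsFactors = FALSE)
  }
  # constant 5 events per bin
  times <- rep(0:64 + 0.5, each = 5)
  out <- binned_series(list(mk(times)), realms2)
  a <- out$value[out$realm == "A" & out$type == "dispersal"]
  expect_equal(a, rep(5, 65))
  # impulse of 3 events in one interior bin: 1.0 in three consecutive windows
  out2 <- binned_series(list(mk(rep(30.5, 3))), realms2)
  a2 <- out2$value[out2$realm == "A" & out2$type == "dispersal"]
  expect_equal(sum(a2 > 0), 3L)
  expect_equal(a2[a2 > 0], rep(1, 3))
  # empty log: all-zero series of length 65
  out3 <- binned_series(list(mk(numeric(0))), realms2)
  expect_equal(sum(out3$value[out3$type == "dispersal"]), 0)
  expect_length(out3$value[out3$realm == "A" & out3$type == "dispersal"], 65L)
  # events older than the span are dropped and counted
  out4 <- binned_series(list(mk(c(10, 80))), realms2)
  expect_equal(attr(out4, "dropped"), 1L)
  # interior mean identity: total/65 when no edge effects
  expect_equal(mean(a), sum(times >= 0 & times < 65) / 65)
})

test_that("per-realm LTT matches hand construction and the plain LTT at zero rates", {
  # cherry, both lineages always in A, root at 1 Ma
  cl <- cherry_clade()
  fit <- structure(list(model = "DEC", params = model_params(0, 0),
                        dmm = uniform_dmm(realms2), clade = cl, max_size = 2),
                   class = "range_fit")
  logs <- run_bsm(fit, n_maps = 3, seed = 5)
  lt <- ltt_per_realm(logs, cl, bin = 0.1)
  expect_equal(lt$A$mean, rep(2, 10))   # 2 lineages through [0, 1)
  expect_equal(lt$B$mean, rep(0, 10))   # realm never occupied
  # zero-rate maps on a bigger tree: realm-A LTT equals the plain phylogenetic LTT
  tr <- sim_tree(8, lambda = 1, seed = 51)
  cl8 <- clade_data(tr, stats::setNames(rep(1L, 8), tr$tip.label), realms2)
  fit8 <- structure(list(model = "DEC", params = model_params(0, 0),
                         dmm = uniform_dmm(realms2), clade = cl8, max_size = 2),
                    class = "range_fit")
  logs8 <- run_bsm(fit8, n_maps = 2, seed = 6)
  lt8 <- ltt_per_realm(logs8, cl8, bin = 0.1)
  ages <- lt8$A$age
  # independent LTT: count branches spanning each age from the tree itself
  depth <- ape::node.depth.edgelength(tr)
  node_age <- max(depth[1:8]) - depth
  plain <- vapply(ages, function(a) {
    sum(node_age[tr$edge[, 2]] <= a & node_age[tr$edge[, 1]] > a)
  }, numeric(1))
  expect_equal(lt8$A$mean, plain)
  expect_equal(lt8$B$mean, rep(0, length(ages)))
})

test_that("top-quantile edge extraction uses interpolated thresholds and keeps ties", {
  m <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m["A", "B"] <- m["B", "A"] <- m["A", "C"] <- m["C", "A"] <- 2
  e <- top_quantile_edges(m, q = 0.25)
  expect_equal(nrow(e), 4L)   # all tied at the threshold: all kept
  # weights 1..8: threshold is the 75th percentile 6.25, edges 7 and 8 survive
  lab4 <- c("A", "B", "C", "D")
  m8 <- matrix(0, 4, 4, dimnames = list(lab4, lab4))
  k <- 1L
  for (a in 1:4) for (b in 1:4) {
    if (a == b || k > 8L) next
    m8[a, b] <- k; k <- k + 1L
  }
  e8 <- top_quantile_edges(m8, q = 0.25)
  expect_setequal(e8$weight, c(7, 8))
  expect_equal(nrow(top_quantile_edges(m8, q = 1)), 8L)
  expect_equal(nrow(top_quantile_edges(m * 0, q = 0.25)), 0L)
})
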