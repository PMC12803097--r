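test_that("realm extrapolation labels water cells by nearest seed", {
  rAB <- realm_set(c("A", "B"))
  mask <- row_mask(4)
  sn <- paleo_snapshot(0, data.frame(realm = c("A", "B"), lon = c(0, 3), lat = 0), mask)
  lab <- extrapolate_realms(sn, rAB)
  expect_identical(as.vector(lab), c("A", "A", "B", "B"))
  # equidistant cell goes to the realm earlier in canonical order
  mask3 <- row_mask(3)
  sn3 <- paleo_snapshot(0, data.frame(realm = c("B", "A"), lon = c(0, 2), lat = 0), mask3)
  lab3 <- extrapolate_realms(sn3, rAB)
  expect_identical(as.vector(lab3), c("B", "A", "A"))
  # seeds matching a present-day 2-realm map reproduce it
  mask6 <- row_mask(6)
  sn6 <- paleo_snapshot(0, data.frame(realm = rep(c("A", "B"), each = 3),
                                      lon = 0:5, lat = 0), mask6)
  expect_identical(as.vector(extrapolate_realms(sn6, rAB)),
                   rep(c("A", "B"), each = 3))
})

test_that("realm centroids are spherical means with degenerate detection", {
  mask <- row_mask(2, lon_step = 10)
  lab <- matrix(c("A", "A"), 1)
  cen <- realm_centroids(lab, mask)
  expect_equal(cen$lon, 5, tolerance = 1e-6)
  expect_equal(cen$lat, 0, tolerance = 1e-6)
  single <- realm_centroids(matrix(c("A", NA), 1), mask)
  expect_equal(single$lon, 0)
  # antipodal pair has no defined centroid
  anti <- water_mask(c(0, 180), 0, matrix(TRUE, 1, 2))
  expect_error(realm_centroids(matrix(c("A", "A"), 1), anti), "undefined centroid")
})

test_that("over-water distances: straight path, disconnection, Dijkstra = brute force", {
  # 1 x 5 row; step ~111 km at the equator for 1 degree
  mask <- row_mask(5)
  step_km <- geosphere::distHaversine(c(0, 0), c(1, 0)) / 1000
  cen <- data.frame(realm = c("A", "B"), lon = c(0, 4), lat = c(0, 0))
  D <- overwater_distance_matrix(cen, mask)
  expect_equal(D["A", "B"], 4 * step_km, tolerance = 1e-6)
  expect_equal(D["A", "A"], 0)
  # land in the middle of a single row disconnects the realms
  maskL <- row_mask(5, land_cols = 3)
  expect_warning(DL <- overwater_distance_matrix(cen, maskL), "unreachable")
  expect_true(is.infinite(DL["A", "B"]))
  # 3 x 5 grid with a mid-row land pillar: detour equals brute-force minimum
  water <- matrix(TRUE, 3, 5); water[2, 3] <- FALSE
  m3 <- water_mask(0:4, c(-1, 0, 1), water)
  cen3 <- data.frame(realm = c("A", "B"), lon = c(0, 4), lat = c(0, 0))
  D3 <- overwater_distance_matrix(cen3, m3)
  g <- mask_graph(m3)
  src <- which(g$coords[, 1] == 0 & g$coords[, 2] == 0)
  dst <- which(g$coords[, 1] == 4 & g$coords[, 2] == 0)
  brute <- oracle_grid_shortest(g$coords, g$from, g$to, g$w, src, dst)
  expect_equal(D3["A", "B"], brute, tolerance = 1e-9)
})

test_that("over-water distance is bounded below by the geodesic and shrinks with the barrier", {
  set.seed(8)
  for (i in 1:5) {
    water <- matrix(stats::runif(15) > 0.2, 3, 5)
    water[1, 1] <- TRUE; water[3, 5] <- TRUE
    m <- water_mask(seq(0, 8, by = 2), c(-2, 0, 2), water)
    cen <- data.frame(realm = c("A", "B"), lon = c(0, 8), lat = c(-2, 2))
    D <- suppressWarnings(overwater_distance_matrix(cen, m))
    gc <- geosphere::distHaversine(c(0, -2), c(8, 2)) / 1000
    if (is.finite(D["A", "B"])) expect_gte(D["A", "B"], gc - 1e-6)
  }
  # removing a land bar can only shorten paths
  barred <- matrix(TRUE, 3, 5); barred[1:2, 3] <- FALSE
  open <- matrix(TRUE, 3, 5)
  cen <- data.frame(realm = c("A", "B"), lon = c(0, 4), lat = c(0, 0))
  Db <- overwater_distance_matrix(cen, water_mask(0:4, c(-1, 0, 1), barred))
  Do <- overwater_distance_matrix(cen, water_mask(0:4, c(-1, 0, 1), open))
  expect_gte(Db["A", "B"], Do["A", "B"])
})

test_that("multiplier normalization maps distances onto [0,1] as specified", {
  D <- matrix(c(0, 50, 100, 50, 0, 75, 100, 75, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  M <- multipliers_from_distances(D)
  expect_equal(M["A", "B"], 0.5)
  expect_equal(M["A", "C"], 0.0)
  expect_equal(M["B", "C"], 0.25)
  expect_equal(diag(M), c(A = 1, B = 1, C = 1))
  # two realms: the single off-diagonal distance normalizes to 0 unless floored
  D2 <- matrix(c(0, 10, 10, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_true(attr(multipliers_from_distances(D2), "degenerate"))  # all-equal override
  M2 <- multipliers_from_distances(D2, degenerate_to_one = FALSE)
  expect_equal(M2["A", "B"], 0)
  M2e <- multipliers_from_distances(D2, eps = 0.01, degenerate_to_one = FALSE)
  expect_equal(M2e["A", "B"], 0.01)
  # all-equal off-diagonals default to the all-ones override
  D3 <- matrix(5, 3, 3); diag(D3) <- 0
  M3 <- multipliers_from_distances(D3)
  expect_true(all(M3 == 1))
  # infinite entries become near-zero multipliers
  D4 <- D; D4["A", "C"] <- D4["C", "A"] <- Inf
  M4 <- multipliers_from_distances(D4)
  expect_true(all(M4 >= 0 & M4 <= 1))
  expect_lt(M4["A", "C"], M4["B", "C"])
})

test_that("preset stratifications carry 10 (cetacean) and 15 (other) strata", {
  expect_length(dmm_preset_boundaries("cetacean"), 10L)
  expect_identical(dmm_preset_boundaries("cetacean"), c(seq(5, 45, 5), 360))
  expect_length(dmm_preset_boundaries("other"), 15L)
  expect_identical(dmm_preset_boundaries("other"), c(seq(10, 140, 10), 360))
})

test_that("stratified DMM construction validates invariants and is deterministic", {
  r3 <- realm_set(c("A", "B", "C"))
  snaps <- sim_paleogeography(r3, boundaries = c(10, 20, 360), seed = 2)
  dmm <- build_stratified_dmm(snaps, c(10, 20, 360), r3)
  expect_s3_class(dmm, "stratified_dmm")
  for (M in dmm$M) {
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(unname(diag(M)), rep(1, 3))
    expect_equal(M, t(M))
  }
  # identical snapshots give identical matrices
  snaps0 <- sim_paleogeography(r3, boundaries = c(10, 20, 360), seed = 2,
                               drift_deg_per_ma = 0)
  dmm0 <- build_stratified_dmm(snaps0, c(10, 20, 360), r3)
  expect_equal(dmm0$M[[1]], dmm0$M[[2]])
  expect_equal(dmm0$M[[2]], dmm0$M[[3]])
  expect_error(build_stratified_dmm(snaps[1:2], c(10, 20, 360), r3), "one snapshot")
  expect_error(stratified_dmm(list(matrix(1, 3, 3)), c(-5), r3), "positive")
})

test_that("DMM stack files round-trip", {
  r3 <- realm_set(c("A", "B", "C"))
  snaps <- sim_paleogeography(r3, boundaries = c(10, 360), seed = 3)
  dmm <- build_stratified_dmm(snaps, c(10, 360), r3, eps = 0.01)
  f <- tempfile()
  write_dmm_stack(dmm, f)
  back <- read_dmm_stack(f, r3)
  expect_equal(back$boundaries, dmm$boundaries)
  for (k in seq_along(dmm$M)) expect_equal(back$M[[k]], dmm$M[[k]], tolerance = 1e-6)
})
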