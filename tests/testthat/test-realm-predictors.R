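test_that("diversity metrics on hand-computable trees", {
  rAB <- realm_set(c("A", "B"))
  # star tree: 3 tips, branch 1 each, all only in A
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  asg <- c(a = 1L, b = 1L, c = 1L)
  pm <- phylo_metrics(star, asg, rAB)
  A <- pm[pm$realm == "A", ]
  expect_equal(A$PD, 3)
  expect_equal(A$PE, 3)
  expect_equal(A$WE, 3)
  expect_equal(A$ED_median, 1)
  expect_true(is.na(pm[pm$realm == "B", "PD"]))
  # cherry with a stem: PE under the union convention
  cherry <- ape::read.tree(text = "(t1:1,t2:1):1;")
  expect_equal(cherry$root.edge, 1)
  pm2 <- phylo_metrics(cherry, c(t1 = 1L, t2 = 3L), rAB)
  expect_equal(pm2[pm2$realm == "A", "PE"], 1 + 0.5 + 0.5)  # tip1 + tip2/2 + stem/2
  expect_equal(pm2[pm2$realm == "A", "PD"], 3)
  expect_equal(pm2[pm2$realm == "A", "WE"], 1 + 0.5)
  # caterpillar ED by fair proportion
  cat3 <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  ed <- evol_distinct_fp(cat3)
  expect_equal(unname(ed["c"]), 2)
  expect_equal(unname(ed["a"]), 1.5)
  expect_equal(unname(ed["b"]), 1.5)
})

test_that("fair proportion conserves total tree length and matches picante", {
  skip_if_not_installed("picante")
  tr <- sim_tree(20, lambda = 1, seed = 61)
  ed <- evol_distinct_fp(tr)
  expect_equal(sum(ed), sum(tr$edge.length), tolerance = 1e-9)
  po <- picante::evol.distinct(tr, type = "fair.proportion")
  expect_equal(unname(ed[po$Species]), po$w, tolerance = 1e-8)
})

test_that("PD matches picante and PE is bounded by PD", {
  skip_if_not_installed("picante")
  r3 <- realm_set(c("A", "B", "C"))
  tr <- sim_tree(15, lambda = 1, seed = 62)
  set.seed(63)
  asg <- stats::setNames(as.integer(sample(1:7, 15, TRUE)), tr$tip.label)
  pm <- phylo_metrics(tr, asg, r3)
  comm <- t(vapply(unclass(r3), function(rl) {
    as.numeric(vapply(asg, function(b) {
      any(range_labels(b, r3) == rl)
    }, logical(1)))
  }, numeric(15)))
  colnames(comm) <- tr$tip.label
  pd <- picante::pd(comm, tr, include.root = TRUE)
  expect_equal(pm$PD, pd$PD, tolerance = 1e-8)
  expect_true(all(pm$PE <= pm$PD + 1e-12))
  expect_true(all(pm$PE >= 0))
  # a realm of single-realm endemics has WE equal to its species count
  endemics <- stats::setNames(rep(1L, 15), tr$tip.label)
  pmE <- phylo_metrics(tr, endemics, r3)
  expect_equal(pmE[pmE$realm == "A", "WE"], 15)
  expect_equal(pmE[pmE$realm == "A", "PE"], pmE[pmE$realm == "A", "PD"])
})

test_that("mean range size per realm", {
  r3 <- realm_set(c("A", "B", "C"))
  asg <- c(s1 = 1L, s2 = 7L)       # s1 in A; s2 everywhere
  mrs <- mean_range_size(asg, r3)
  expect_equal(unname(mrs["A"]), 2)     # (1 + 3) / 2
  expect_equal(unname(mrs["B"]), 3)
  all1 <- mean_range_size(c(x = 1L, y = 2L, z = 4L), r3)
  expect_equal(unname(all1), rep(1, 3))
  expect_true(is.na(mean_range_size(c(x = 1L), r3)["B"]))
  # oracle: recompute from the presence matrix
  set.seed(64)
  rnd <- stats::setNames(as.integer(sample(1:7, 30, TRUE)), sprintf("t%d", 1:30))
  mrs2 <- mean_range_size(rnd, r3)
  sizes <- range_size(rnd)
  for (k in 1:3) {
    m <- bitwAnd(rnd, 2L^(k - 1)) > 0
    expect_equal(unname(mrs2[k]), mean(sizes[m]))
  }
})

test_that("centroid isolation is a symmetric metric with expected symmetries", {
  cen <- data.frame(realm = c("A", "B"), lon = c(10, 10), lat = c(0, 0))
  expect_equal(euclidean_isolation(cen)$distance["A", "B"], 0)
  # three equally spaced realms on the equator wrap symmetrically
  cen3 <- data.frame(realm = c("A", "B", "C"), lon = c(0, 120, -120), lat = c(0, 0, 0))
  iso <- euclidean_isolation(cen3)
  expect_equal(unname(iso$isolation), rep(iso$isolation[[1]], 3))
  set.seed(65)
  rnd <- data.frame(realm = paste0("R", 1:5),
                    lon = stats::runif(5, -180, 180), lat = stats::runif(5, -60, 60))
  D <- euclidean_isolation(rnd)$distance
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 5))
  for (a in 1:5) for (b in 1:5) for (c in 1:5) {
    expect_lte(D[a, b], D[a, c] + D[c, b] + 1e-9)
  }
  # chord distances never exceed great-circle distances
  Dch <- euclidean_isolation(rnd, method = "chord")$distance
  expect_true(all(Dch <= D + 1e-9))
})

test_that("shelf area masks the 0-200 m depth band with a closed boundary", {
  r <- realm_set(c("A", "B"))
  expect_equal(shelf_area(c(-50, -150, -300), rep("A", 3), 1, r)[["A"]], 2)
  expect_equal(shelf_area(c(-200), "A", 1, r)[["A"]], 1)    # boundary included
  expect_equal(shelf_area(c(10, NA), c("A", "A"), 1, r)[["A"]], 0)
  expect_equal(shelf_area(c(-50, -60), c("A", "B"), c(2, 3), r)[["B"]], 3)
})

test_that("collinearity screen drops the specified member of correlated pairs", {
  set.seed(66)
  x <- stats::rnorm(20)
  df <- data.frame(v1 = x, v2 = x, v3 = stats::rnorm(20))
  kept <- collinearity_screen(df, 0.7)
  expect_length(kept, 2L)
  expect_true("v3" %in% kept)
  expect_length(intersect(c("v1", "v2"), kept), 1L)
  # mutually uncorrelated columns are all retained
  set.seed(67)
  un <- as.data.frame(matrix(stats::rnorm(100 * 4), 100))
  expect_length(collinearity_screen(un, 0.7), 4L)
  # constant column dropped first with a warning
  expect_warning(kc <- collinearity_screen(cbind(df, k = 1), 0.7), "constant")
  expect_false("k" %in% kc)
  # r(1,2) = 0.9 case: the result is also a minimal removal set (brute force)
  set.seed(68)
  a <- stats::rnorm(50)
  b <- 0.9 * a + sqrt(1 - 0.81) * stats::rnorm(50)
  dd <- data.frame(a = a, b = b, c = stats::rnorm(50))
  kept2 <- collinearity_screen(dd, 0.7)
  # brute force: smallest subset with no |r| > 0.7 among all drop sets
  all_ok <- function(cols) {
    if (length(cols) < 2) return(TRUE)
    C <- abs(stats::cor(dd[cols])); diag(C) <- 0
    max(C) <= 0.7
  }
  best_size <- max(Filter(function(k) {
    any(vapply(utils::combn(names(dd), k, simplify = FALSE), all_ok, logical(1)))
  }, 1:3))
  expect_length(kept2, best_size)
  expect_true(all_ok(kept2))
})
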