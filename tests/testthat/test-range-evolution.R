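test_that("anagenetic rates follow the dispersal/extirpation formula", {
  sp <- enumerate_states(2)
  M <- matrix(1, 2, 2)
  Q <- build_Q(model_params(d = 0.1, e = 0.05), M, sp)
  pos <- function(b) which(sp$bits == b)
  expect_equal(Q[pos(1L), pos(3L)], 0.1)   # {A} -> {A,B}
  expect_equal(Q[pos(3L), pos(1L)], 0.05)  # {A,B} -> {A}
  expect_equal(Q[pos(1L), pos(0L)], 0.05)  # {A} -> empty
  expect_equal(sum(abs(Q[pos(0L), ])), 0)  # empty absorbing
  M2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  Q2 <- build_Q(model_params(d = 0.1, e = 0.05), M2, sp)
  expect_equal(Q2[pos(1L), pos(3L)], 0.05)
  # rows sum to zero on random builds
  set.seed(3)
  sp3 <- enumerate_states(3)
  for (i in 1:10) {
    M3 <- matrix(stats::runif(9, 0.1, 1), 3); M3 <- (M3 + t(M3)) / 2; diag(M3) <- 1
    Q3 <- build_Q(model_params(d = stats::runif(1), e = stats::runif(1)), M3, sp3)
    expect_lt(max(abs(rowSums(Q3))), 1e-12)
  }
  # cap blocks expansions beyond max_size
  spc <- enumerate_states(3, 1)
  Qc <- build_Q(model_params(d = 1, e = 0), matrix(1, 3, 3), spc)
  expect_equal(max(abs(Qc)), 0)
})

test_that("cladogenetic event tables enumerate each model's daughters", {
  sp <- enumerate_states(2)
  p <- model_params(d = .1, e = .1)
  dec1 <- build_clado_table("DEC", p, sp)
  one <- dec1[dec1$anc == 1L, ]
  expect_equal(nrow(one), 1L)
  expect_equal(one$prob, 1)
  expect_identical(one$type, "narrow_sympatry")
  # widespread DEC ancestor: 4 subset + 2 vicariance events, each 1/6
  ab <- dec1[dec1$anc == 3L, ]
  expect_equal(nrow(ab), 6L)
  expect_equal(unique(ab$prob), 1 / 6)
  expect_equal(sum(ab$type == "subset_sympatry"), 4L)
  expect_equal(sum(ab$type == "vicariance"), 2L)
  # BAYAREALIKE: pure copying
  bay <- build_clado_table("BAYAREALIKE", p, sp)
  expect_equal(nrow(bay[bay$anc == 3L, ]), 1L)
  expect_equal(bay[bay$anc == 3L, "prob"], 1)
  expect_identical(bay[bay$anc == 3L, "left"], 3L)
  # probabilities sum to 1 per ancestor for every model
  sp3 <- enumerate_states(3)
  for (m in models6) {
    ct <- build_clado_table(m, model_params(.1, .1, j = .5), sp3)
    sums <- tapply(ct$prob, ct$anc, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)))
  }
})

test_that("pruning likelihood reproduces the hand-enumerated cherry value", {
  cl <- cherry_clade()
  dmm <- uniform_dmm(realms2)
  expect_equal(loglikelihood(cl, dmm, "DEC", model_params(0, 0)), log(1 / 3),
               tolerance = 1e-12)
})

test_that("+J with j = 0 collapses to the base model", {
  set.seed(10)
  dmm <- uniform_dmm(realms3)
  for (i in 1:4) {
    cl <- random_small_clade(sample(3:6, 1), realms3, seed = 20 + i)
    p0 <- model_params(d = stats::runif(1, .01, .3), e = stats::runif(1, .01, .2), j = 0)
    for (base in c("DEC", "DIVALIKE", "BAYAREALIKE")) {
      expect_equal(loglikelihood(cl, dmm, paste0(base, "+J"), p0),
                   loglikelihood(cl, dmm, base, p0), tolerance = 1e-9)
    }
  }
})

test_that("propagators are proper stochastic matrices", {
  set.seed(4)
  sp <- enumerate_states(3)
  M <- matrix(stats::runif(9, .2, 1), 3); M <- (M + t(M)) / 2; diag(M) <- 1
  Q <- build_Q(model_params(.2, .1), M, sp)
  for (t in c(0.01, 0.5, 3, 25)) {
    P <- as.matrix(Matrix::expm(Q * t))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_gt(min(P), -1e-12)
  }
})

test_that("likelihood is equivariant under realm relabeling", {
  dmm <- uniform_dmm(realms3)
  cl <- random_small_clade(5, realms3, seed = 42)
  p <- model_params(d = .12, e = .05, j = .3)
  # swap realms A and B in every tip range
  swap <- function(b) {
    a <- bitwAnd(b, 1L); bb <- bitwAnd(b, 2L)
    bitwOr(bitwOr(a * 2L, bb %/% 2L), bitwAnd(b, 4L))
  }
  r2 <- cl$ranges
  r2[] <- vapply(cl$ranges, swap, integer(1))
  cl2 <- clade_data(cl$tree, r2, realms3)
  for (m in c("DEC", "DIVALIKE+J")) {
    expect_equal(loglikelihood(cl, dmm, m, p), loglikelihood(cl2, dmm, m, p),
                 tolerance = 1e-10)
  }
})

test_that("shared-realm tips approach 1/(non-empty states) as rates vanish", {
  dmm <- uniform_dmm(realms3)
  tr <- sim_tree(6, lambda = 1, seed = 13)
  cl <- clade_data(tr, stats::setNames(rep(2L, 6), tr$tip.label), realms3)
  lnl <- loglikelihood(cl, dmm, "DEC", model_params(d = 1e-9, e = 0))
  expect_equal(lnl, log(1 / 7), tolerance = 1e-4)
})

test_that("model selection ranks by AIC with the fewer-parameter tie rule", {
  cl <- cherry_clade()
  fake <- function(model, lnL, k) {
    structure(list(model = model, params = model_params(.1, .1), lnL = lnL,
                   k = k, AIC = 2 * k - 2 * lnL, convergence = 0L,
                   clade = cl, dmm = uniform_dmm(realms2), max_size = 2),
              class = "range_fit")
  }
  ms <- model_select(list(fake("DEC", -100, 2L), fake("DEC+J", -98, 3L)))
  expect_equal(ms$AIC, c(202, 204))
  expect_identical(ms$model[1], "DEC+J")
  expect_equal(ms$dAIC, c(0, 2))
  # equal AIC: the base model (fewer parameters) wins
  tie <- model_select(list(fake("DEC+J", -99, 3L), fake("DEC", -100, 2L)))
  expect_identical(tie$model[1], "DEC")
  # six models on one clade: 6 rows, best dAIC 0
  six <- model_select(lapply(seq_along(models6), function(i)
    fake(models6[i], -100 - i, if (grepl("J", models6[i])) 3L else 2L)))
  expect_equal(nrow(six), 6L)
  expect_equal(six$dAIC[1], 0)
  # mixing clades errors
  other <- fake("DEC", -10, 2L)
  other$clade <- random_small_clade(3, realms2, seed = 77)
  expect_error(model_select(list(fake("DEC", -100, 2L), other)), "same clade")
})

test_that("fitting recovers the AIC bookkeeping and is stable across seeds", {
  cl <- random_small_clade(10, realms2, seed = 30)
  dmm <- uniform_dmm(realms2)
  f1 <- fit_range_model(cl, dmm, "DEC", n_starts = 3, seed = 1)
  expect_equal(f1$AIC, 2 * f1$k - 2 * f1$lnL)
  expect_equal(f1$k, 2L)
  expect_equal(unname(stats::AIC(f1)), f1$AIC)
  f2 <- fit_range_model(cl, dmm, "DEC", n_starts = 3, seed = 99)
  expect_lt(abs(f1$lnL - f2$lnL), 1e-3)
  fj <- fit_range_model(cl, dmm, "DEC+J", n_starts = 3, seed = 1)
  expect_equal(fj$k, 3L)
  expect_gte(fj$lnL, f1$lnL - 1e-6)  # nested model cannot fit worse
  expect_named(coef(fj), c("d", "e", "j"))
})
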