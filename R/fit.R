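#' Fit a DEC-family range-evolution model by maximum likelihood
#'
#' Maximizes the stratified pruning likelihood over the anagenetic rates
#' `d`, `e` (and the founder weight `j` for +J models) with multi-start
#' local optimization: `n_starts` seeded starting points, L-BFGS-B on
#' `(log d, log e, j)`, best optimum kept.  Bounds are `d, e` in
#' `[1e-9, 5]` events/Myr and `j` in `[0, 2.99999]`.
#'
#' @param clade a [clade_data()].
#' @param dmm a [stratified_dmm()]; use [uniform_dmm()] for an unstratified
#'   analysis.
#' @param model one of `"DEC"`, `"DEC+J"`, `"DIVALIKE"`, `"DIVALIKE+J"`,
#'   `"BAYAREALIKE"`, `"BAYAREALIKE+J"`.
#' @param max_size optional range-size cap (default: number of realms).
#' @param n_starts number of optimizer starts (default 5).
#' @param seed integer seed for the start points.
#' @param bounds list with elements `d`, `e`, `j`, each `c(lower, upper)`.
#' @return An object of class `range_fit` with components `model`, `params`
#'   (the MLE as a [model_params()]), `lnL`, `k` (number of free
#'   parameters), `AIC`, `convergence` (0 = all starts converged) and the
#'   inputs needed by [simulate.range_fit()].
#' @seealso [model_select()], [run_bsm()]
#' @export
fit_range_model <- function(clade, dmm, model = "DEC", max_size = NULL,
                            n_starts = 5L, seed = 1L,
                            bounds = list(d = c(1e-9, 5), e = c(1e-9, 5),
                                          j = c(0, 2.99999))) {
  model <- match.arg(model, range_models)
  has_j <- model_has_j(model)
  ctx <- lik_context(clade, dmm, model, max_size)
  obj <- function(par) {
    p <- model_params(d = exp(par[1]), e = exp(par[2]),
                      j = if (has_j) par[3] else 0)
    val <- lnL_context(ctx, p)
    if (!is.finite(val)) 1e10 else -val
  }
  lower <- c(log(bounds$d[1]), log(bounds$e[1]), if (has_j) bounds$j[1])
  upper <- c(log(bounds$d[2]), log(bounds$e[2]), if (has_j) bounds$j[2])
  set.seed(seed)
  starts <- replicate(n_starts, {
    c(stats::runif(1, log(1e-3), log(1)), stats::runif(1, log(1e-3), log(1)),
      if (has_j) stats::runif(1, 0.01, 1.5))
  }, simplify = FALSE)
  best <- NULL
  codes <- integer(0)
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 300, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(res)) next
    codes <- c(codes, res$convergence)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")
  mle <- model_params(d = exp(best$par[1]), e = exp(best$par[2]),
                      j = if (has_j) best$par[3] else 0)
  k <- if (has_j) 3L else 2L
  lnL <- -best$value
  structure(list(model = model, params = mle, lnL = lnL, k = k,
                 AIC = 2 * k - 2 * lnL,
                 convergence = if (all(codes == 0)) 0L else 1L,
                 n_starts = n_starts, seed = seed,
                 clade = clade, dmm = dmm,
                 max_size = if (is.null(max_size)) length(clade$realms) else max_size),
            class = "range_fit")
}

#' @export
print.range_fit <- function(x, ...) {
  cat("Range-evolution model fit:", x$model, "\n")
  cat(sprintf("  d = %.5g  e = %.5g%s\n", x$params$d, x$params$e,
              if (model_has_j(x$model)) sprintf("  j = %.5g", x$params$j) else ""))
  cat(sprintf("  lnL = %.4f  k = %d  AIC = %.4f\n", x$lnL, x$k, x$AIC))
  if (x$convergence != 0L) cat("  warning: at least one optimizer start did not converge\n")
  invisible(x)
}

#' @export
summary.range_fit <- function(object, ...) {
  cat("Clade: ", ape::Ntip(object$clade$tree), " tips, root age ",
      signif(root_age(object$clade$tree), 4), " Ma, ",
      length(object$clade$realms), " realms (cap ", object$max_size, ")\n", sep = "")
  cat("Strata: ", length(object$dmm$M), " (boundaries ",
      paste(object$dmm$boundaries, collapse = ", "), " Ma)\n", sep = "")
  print(object)
}

#' @export
coef.range_fit <- function(object, ...) {
  p <- unlist(object$params[c("d", "e", "j")])
  if (!model_has_j(object$model)) p <- p[c("d", "e")]
  p
}

#' @export
logLik.range_fit <- function(object, ...) {
  structure(object$lnL, df = object$k, nobs = ape::Ntip(object$clade$tree),
            class = "logLik")
}

#' Rank fitted models by AIC
#'
#' Compares fits of different models on the same clade data, sorted by
#' ascending AIC with ties broken in favor of fewer parameters.
#'
#' @param fits list of [fit_range_model()] results on identical data.
#' @return data.frame with columns `model`, `k`, `lnL`, `AIC`, `dAIC`,
#'   ordered best first; attribute `best` holds the winning fit.
#' @export
model_select <- function(fits) {
  if (length(fits) < 2L) stop("need at least 2 fits to compare")
  ref <- fits[[1]]$clade
  same <- vapply(fits, function(f) {
    identical(f$clade$tree$tip.label, ref$tree$tip.label) &&
      identical(unname(f$clade$ranges), unname(ref$ranges))
  }, logical(1))
  if (!all(same)) stop("fits are not all on the same clade data")
  tab <- data.frame(model = vapply(fits, `[[`, character(1), "model"),
                    k = vapply(fits, `[[`, integer(1), "k"),
                    lnL = vapply(fits, `[[`, numeric(1), "lnL"),
                    AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  ord <- order(tab$AIC, tab$k)
  tab <- tab[ord, ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  attr(tab, "best") <- fits[[ord[1]]]
  tab
}
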