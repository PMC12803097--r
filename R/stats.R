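#' Paired Wilcoxon signed-rank test
#'
#' Compares two paired series of per-timebin event rates.  Zero differences
#' are dropped (reducing n, the standard signed-rank practice).  The
#' statistic V is the sum of the ranks (average ranks under ties) of the
#' positive differences.  For n of at most 25 the p-value is exact, computed
#' by full enumeration of the 2^n sign assignments via a generating-function
#' convolution (which, unlike the classical shift algorithm, remains exact
#' under tied ranks); larger n uses the normal approximation with continuity
#' and tie corrections.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (for the
#'   location of `x` relative to `y`).
#' @return list of class `searange_test`: `statistic` ("V"), `value`,
#'   `p.value`, `n` (pairs used), `method`.
#' @examples
#' paired_wilcoxon(c(1, 2, 3), c(2, 3, 4))  # V = 0, exact p = 0.25
#' @export
paired_wilcoxon <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  M <- n * (n + 1) / 2
  if (n <= 25L) {
    p <- exact_signrank_p(r, V, alternative)
    method <- "exact (sign-pattern enumeration)"
  } else {
    mu <- M / 2
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- switch(alternative, two.sided = sign(V - mu) * 0.5, greater = 0.5, less = -0.5)
    z <- (V - mu - cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE), 0.5),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    method <- "normal approximation with continuity correction"
  }
  structure(list(statistic = "V", value = V, p.value = p, n = n,
                 method = paste("paired Wilcoxon signed-rank,", method),
                 alternative = alternative),
            class = "searange_test")
}

# exact signed-rank distribution under possibly tied (average) ranks: work on
# doubled ranks so every value is integer, convolve the per-pair generating
# functions, and read tail probabilities off the full distribution
exact_signrank_p <- function(ranks, V, alternative) {
  r2 <- as.integer(round(2 * ranks))
  tot <- sum(r2)
  f <- numeric(tot + 1L)   # f[w + 1] = number of sign patterns with 2V = w
  f[1L] <- 1
  for (rk in r2) {
    g <- f
    g[(rk + 1L):(tot + 1L)] <- g[(rk + 1L):(tot + 1L)] + f[1L:(tot + 1L - rk)]
    f <- g
  }
  f <- f / 2^length(r2)
  w <- 0:tot
  V2 <- round(2 * V)
  p_le <- sum(f[w <= V2])
  p_ge <- sum(f[w >= V2])
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, sum(f[abs(w - tot / 2) >= abs(V2 - tot / 2) - 1e-9])))
}

#' @export
print.searange_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("%s = %g, p = %.4g, n = %d (%s)\n", x$statistic, x$value,
              x$p.value, x$n, x$alternative))
  invisible(x)
}

#' Classify ages into pre/post-Miocene epochs
#'
#' @param age_ma ages in Ma.
#' @param boundary Miocene onset (23.03 Ma).
#' @return factor with levels `"pre"` (older) and `"post"` (younger).
#' @export
geologic_epoch <- function(age_ma, boundary = 23.03) {
  factor(ifelse(age_ma >= boundary, "pre", "post"), levels = c("pre", "post"))
}

#' Generalized least squares with AR1 errors
#'
#' Fits a GLS regression with a first-order autoregressive correlation
#' structure (coefficients and rho estimated jointly by maximum likelihood),
#' the standard guard against temporal autocorrelation in binned event
#' series.  The canonical design is a `timebin * epoch` interaction (epoch =
#' pre/post the Miocene boundary, see [geologic_epoch()]); pass any formula.
#' If the AR1 fit fails to converge the model falls back to independent
#' errors, flagged in the result.
#'
#' @param formula model formula.
#' @param data data.frame ordered by time.
#' @param log_response if `TRUE`, log-transform the response variable first
#'   (lineage-accumulation series grow exponentially, so the regression then
#'   tests acceleration on top of the expected exponential trend).
#' @param ar1 if `FALSE`, fit with independent errors (identity correlation:
#'   the fit then reproduces ordinary least squares).
#' @return list of class `searange_gls`: `fit` (the `nlme::gls` object),
#'   `coefficients` (estimate/SE/t/p table), `rho` (NA under the fallback),
#'   `fallback` (logical), `n`.
#' @export
gls_ar1 <- function(formula, data, log_response = FALSE, ar1 = TRUE) {
  if (log_response) {
    resp <- all.vars(formula)[1]
    if (any(data[[resp]] <= 0)) stop("log_response requires a positive response")
    data[[resp]] <- log(data[[resp]])
  }
  fallback <- !ar1
  fit <- if (ar1) tryCatch(
    nlme::gls(formula, data = data, correlation = nlme::corAR1(form = ~1),
              method = "ML"),
    error = function(e) NULL) else NULL
  if (is.null(fit)) {
    fallback <- TRUE
    fit <- tryCatch(nlme::gls(formula, data = data, method = "ML"),
                    error = function(e) NULL)
  }
  if (is.null(fit)) {
    # degenerate designs (e.g. an exactly collinear, noise-free response)
    # still admit an ordinary least-squares solution
    fit <- stats::lm(formula, data = data)
    tt <- summary(fit)$coefficients
    colnames(tt) <- c("Value", "Std.Error", "t-value", "p-value")
  } else {
    tt <- summary(fit)$tTable
  }
  rho <- if (fallback) NA_real_ else
    as.numeric(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  structure(list(fit = fit,
                 coefficients = data.frame(term = rownames(tt),
                                           estimate = tt[, "Value"],
                                           se = tt[, "Std.Error"],
                                           t = tt[, "t-value"],
                                           p.value = tt[, "p-value"],
                                           row.names = NULL),
                 rho = rho, fallback = fallback, n = nrow(data)),
            class = "searange_gls")
}

#' @export
print.searange_gls <- function(x, ...) {
  cat("GLS", if (x$fallback) "(independent errors fallback)" else
    sprintf("with AR1 errors, rho = %.3f", x$rho), "; n =", x$n, "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Linear mixed model with random intercepts
#'
#' Regresses a per-realm event response on standardized predictors with
#' random intercepts for the supplied grouping factors (REML).  Predictors
#' are z-scored before fitting so effect sizes are comparable;
#' constant/all-zero predictors are dropped with a warning.  Fixed effects
#' are reported with Wald 95% intervals and Satterthwaite p-values.
#'
#' @param data data.frame holding everything.
#' @param response response column name.
#' @param predictors character vector of predictor column names.
#' @param groupings character vector of grouping column names (each needs
#'   at least 2 levels).
#' @return list of class `searange_lmm`: `fit`, `effects` (variable /
#'   effect size / lower / upper / p value), `ranef_sd` (random-intercept
#'   SDs), `singular` (logical).
#' @export
lmm_random_intercepts <- function(data, response, predictors, groupings) {
  keep <- predictors
  const <- vapply(keep, function(v) stats::sd(data[[v]], na.rm = TRUE) == 0, logical(1))
  if (any(const)) {
    warning("dropping constant predictor(s): ", paste(keep[const], collapse = ", "))
    keep <- keep[!const]
  }
  if (!length(keep)) stop("no usable predictors")
  for (g in groupings) {
    if (length(unique(data[[g]])) < 2L) stop("grouping '", g, "' needs >= 2 levels")
  }
  z <- data
  for (v in keep) z[[v]] <- as.numeric(scale(z[[v]]))
  fml <- stats::as.formula(paste(
    response, "~", paste(keep, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", groupings), collapse = " + ")))
  fit <- lmerTest::lmer(fml, data = z, REML = TRUE)
  singular <- lme4::isSingular(fit, tol = 1e-4)
  sm <- summary(fit)$coefficients
  rows <- match(keep, rownames(sm))
  eff <- data.frame(variable = keep,
                    effect_size = sm[rows, "Estimate"],
                    lower = sm[rows, "Estimate"] - 1.96 * sm[rows, "Std. Error"],
                    upper = sm[rows, "Estimate"] + 1.96 * sm[rows, "Std. Error"],
                    p.value = sm[rows, "Pr(>|t|)"],
                    row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_sd <- stats::setNames(vc$sdcor[vc$grp %in% groupings], vc$grp[vc$grp %in% groupings])
  structure(list(fit = fit, effects = eff, ranef_sd = ranef_sd, singular = singular),
            class = "searange_lmm")
}

#' @export
print.searange_lmm <- function(x, ...) {
  cat("Linear mixed model", if (x$singular) "(singular fit)", "\n")
  print(x$effects, digits = 4)
  cat("random-intercept SD:", paste(sprintf("%s=%.3f", names(x$ranef_sd), x$ranef_sd),
                                    collapse = ", "), "\n")
  invisible(x)
}
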