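as_series_xy <- function(series) {
  if (is.data.frame(series)) {
    stopifnot(all(c("year", "value") %in% names(series)))
    list(x = as.numeric(series$year), y = as.numeric(series$value))
  } else if (is.list(series) && all(c("x", "y") %in% names(series))) {
    list(x = as.numeric(series$x), y = as.numeric(series$y))
  } else stop("series must be a data frame with columns year and value")
}

#' AIC from residual sum of squares
#'
#' The Gaussian-likelihood convention `n log(RSS/n) + 2k`, with `k` the
#' total parameter count including the error variance; additive constants
#' are dropped, so values are comparable only across models fit to the same
#' series. A numerically-zero RSS (below `max(TSS, 1) * 1e-12`) maps to
#' `-Inf`, a sentinel ordered below every finite AIC; such ties are broken
#' by parameter count during model selection.
#'
#' @param n number of observations.
#' @param rss residual sum of squares.
#' @param k parameter count including the error variance.
#' @param tss total sum of squares used for the zero-RSS floor (default 1).
#' @return AIC value (possibly `-Inf`).
#' @export
aic_rss <- function(n, rss, k, tss = 1) {
  if (rss < max(tss, 1) * 1e-12) return(-Inf)
  n * log(rss / n) + 2 * k
}

r2_from_rss <- function(rss, tss) {
  if (tss <= 0) return(if (rss <= 1e-12) 1 else NA_real_)
  1 - rss / tss
}

new_model_fit <- function(family, par, n, rss, tss, k, extra = list()) {
  structure(c(list(family = family, par = par, n = n, rss = rss,
                   k = k, aic = aic_rss(n, rss, k, tss),
                   r2 = r2_from_rss(rss, tss)),
              extra),
            class = if (family == "piecewise2")
              c("piecewise_fit", "model_fit") else "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: n=%d  RSS=%.4g  AIC=%.3f  r2=%.4f\n", x$family, x$n,
              x$rss, x$aic, x$r2))
  print(signif(unlist(x$par), 6))
  if (!is.null(x$psi)) cat("breakpoints:", round(x$psi, 3), "\n")
  invisible(x)
}

#' AIC of a fitted temporal model
#' @param fit a `model_fit`.
#' @return its AIC (see [aic_rss()]).
#' @export
model_aic <- function(fit) fit$aic

#' Predict from a fitted temporal model
#' @param fit a `model_fit`.
#' @param year years at which to evaluate the mean function.
#' @return fitted values.
#' @export
predict_fit <- function(fit, year) {
  x <- as.numeric(year)
  p <- fit$par
  switch(fit$family,
    linear = p[["a"]] + p[["b"]] * x,
    piecewise2 = p[["a"]] + p[["b"]] * x +
      p[["c"]] * pmax(x - fit$psi[1], 0) +
      p[["d"]] * pmax(x - fit$psi[2], 0),
    quadratic = p[["a"]] + p[["b"]] * x + p[["c"]] * x^2,
    unimodal = if (identical(fit$form, "polynomial"))
      p[["a"]] * p[["b"]] * (x - p[["c"]])^2
    else p[["a"]] * p[["b"]]^((x - p[["c"]])^2),
    asymptotic = p[["a"]] + p[["b"]] * exp(-exp(p[["c"]]) * x),
    logistic4 = p[["a"]] + (p[["b"]] - p[["a"]]) /
      (1 + exp((p[["c"]] - x) / p[["d"]])),
    stop("unknown family ", fit$family))
}

#' Linear trend fit (D = a + b year)
#'
#' Ordinary least squares; `b` is the rate of change of the diversity metric
#' per year.
#'
#' @param series data frame with columns `year` and `value`.
#' @return a `model_fit` with parameters `a`, `b`.
#' @export
fit_linear <- function(series) {
  s <- as_series_xy(series)
  if (length(s$x) < 3) stop("insufficient-data error: need >= 3 points")
  f <- stats::lm.fit(cbind(1, s$x), s$y)
  rss <- sum(f$residuals^2)
  tss <- sum((s$y - mean(s$y))^2)
  new_model_fit("linear", list(a = unname(f$coefficients[1]),
                               b = unname(f$coefficients[2])),
                length(s$x), rss, tss, k = 3)
}

#' Quadratic trend fit (D = a + b year + c year^2)
#' @param series data frame with columns `year` and `value`.
#' @return a `model_fit` with parameters `a`, `b`, `c`.
#' @export
fit_quadratic <- function(series) {
  s <- as_series_xy(series)
  if (length(s$x) < 5) stop("insufficient-data error: need >= 5 points")
  f <- stats::lm.fit(cbind(1, s$x, s$x^2), s$y)
  rss <- sum(f$residuals^2)
  tss <- sum((s$y - mean(s$y))^2)
  co <- unname(f$coefficients)
  new_model_fit("quadratic", list(a = co[1], b = co[2], c = co[3]),
                length(s$x), rss, tss, k = 4)
}

piecewise_design <- function(x, psi, with_gap = TRUE) {
  u1 <- pmax(x - psi[1], 0)
  u2 <- pmax(x - psi[2], 0)
  if (!with_gap) return(cbind(1, x, u1, u2))
  cbind(1, x, u1, u2, -as.numeric(x > psi[1]), -as.numeric(x > psi[2]))
}

piecewise_admissible <- function(x, psi, min_seg = 2L) {
  psi[1] < psi[2] && psi[1] > min(x) && psi[2] < max(x) &&
    sum(x <= psi[1]) >= min_seg &&
    sum(x > psi[1] & x <= psi[2]) >= min_seg &&
    sum(x > psi[2]) >= min_seg
}

piecewise_iterate <- function(x, y, psi, tol, max_iter) {
  span <- diff(range(x))
  yscale <- max(stats::sd(y), 1e-12)
  for (it in seq_len(max_iter)) {
    X <- piecewise_design(x, psi)
    f <- stats::lm.fit(X, y)
    if (f$rank < ncol(X)) return(NULL)
    beta <- f$coefficients
    slope_diff <- beta[3:4]
    gap <- beta[5:6]
    delta <- numeric(2)
    for (m in 1:2) {
      if (abs(slope_diff[m]) < 1e-10 * yscale / span) {
        # slope difference numerically zero: no information to move psi_m
        if (abs(gap[m]) < 1e-8 * yscale) delta[m] <- 0 else return(NULL)
      } else delta[m] <- gap[m] / slope_diff[m]
    }
    # damp huge steps, and project back inside the data range rather than
    # abandoning the start; crossed breakpoints still fail it
    delta <- pmin(pmax(delta, -span / 2), span / 2)
    psi_new <- psi + delta
    xs <- sort(x)
    lo <- xs[2]
    hi <- xs[length(xs) - 1L]
    psi_new <- pmin(pmax(psi_new, lo), hi)
    if (psi_new[1] >= psi_new[2]) return(NULL)
    if (max(abs(delta)) < tol) {
      psi <- psi_new
      break
    }
    psi <- psi_new
  }
  if (!piecewise_admissible(x, psi)) return(NULL)
  X <- piecewise_design(x, psi, with_gap = FALSE)
  f <- stats::lm.fit(X, y)
  if (f$rank < ncol(X)) return(NULL)
  list(psi = unname(psi), coef = unname(f$coefficients),
       rss = sum(f$residuals^2), iter = it)
}

#' Two-breakpoint piecewise-linear fit
#'
#' Fits `D = a + b year + c (year - psi1) I(year > psi1) +
#' d (year - psi2) I(year > psi2)` by iterative linearization: at each step
#' an OLS fit on the broken-line basis plus breakpoint gap indicators yields
#' an update `psi_m <- psi_m + gap_m / slope_diff_m`, iterated to
#' convergence (`max |delta psi| < tol`) from a grid of initial breakpoint
#' pairs (quantiles of the observed years). Solutions whose breakpoints
#' cross, leave the data range, or strand a segment with fewer than two
#' observations are discarded; the converged solution with the lowest RSS
#' is returned. Segment slopes are `b`, `b + c`, `b + c + d`.
#'
#' @param series data frame with columns `year` and `value` (>= 8 points).
#' @param init optional numeric length-2 initial breakpoint guess, tried
#'   before the grid.
#' @param grid_probs quantile probabilities generating the initial-pair
#'   grid (default deciles).
#' @param tol convergence tolerance on the breakpoint update, in years.
#' @param max_iter maximum iterations per start.
#' @return a `piecewise_fit` with parameters `a`,`b`,`c`,`d`, breakpoints
#'   `psi`, segment `slopes`, RSS, AIC (k = 7), r-squared.
#' @export
fit_piecewise2 <- function(series, init = NULL,
                           grid_probs = seq(0.1, 0.9, by = 0.1),
                           tol = 1e-6, max_iter = 50L) {
  s <- as_series_xy(series)
  x <- s$x
  y <- s$y
  if (length(x) < 8) stop("insufficient-data error: need >= 8 points")
  qs <- if (is.null(grid_probs)) numeric(0) else
    unique(as.numeric(stats::quantile(x, grid_probs, names = FALSE)))
  qs <- qs[qs > min(x) & qs < max(x)]
  starts <- list()
  if (!is.null(init)) starts[[1]] <- sort(as.numeric(init))
  if (length(qs) >= 2)
    for (i in seq_len(length(qs) - 1))
      for (j in (i + 1):length(qs))
        starts[[length(starts) + 1L]] <- c(qs[i], qs[j])
  if (!length(starts))
    stop("non-convergence error: no admissible initial breakpoint pairs")
  best <- NULL
  tried <- 0L
  for (ps in starts) {
    tried <- tried + 1L
    if (!piecewise_admissible(x, ps)) next
    res <- piecewise_iterate(x, y, ps, tol, max_iter)
    if (is.null(res)) next
    if (is.null(best) || res$rss < best$rss) best <- res
  }
  if (is.null(best))
    stop("non-convergence error: no converged admissible piecewise solution",
         " over ", tried, " starts (n = ", length(x), ")")
  tss <- sum((y - mean(y))^2)
  co <- best$coef
  new_model_fit("piecewise2",
                list(a = co[1], b = co[2], c = co[3], d = co[4]),
                length(x), best$rss, tss, k = 7,
                extra = list(psi = best$psi,
                             slopes = c(pre = co[2],
                                        mid = co[2] + co[3],
                                        post = co[2] + co[3] + co[4]),
                             iterations = best$iter))
}

nls_try <- function(formula, data, starts, lower = NULL) {
  fits <- list()
  for (st in starts) {
    f <- tryCatch(
      if (is.null(lower))
        minpack.lm::nlsLM(formula, data = data, start = st,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) return(NULL)
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), 0)
  fits[[which.min(rss)]]
}

#' Unimodal trend fit (D = a b^((year - c)^2))
#'
#' Gaussian-like bump with peak (for `0 < b < 1`) or trough (`b > 1`) at
#' year `c`; `a` is the value at the extremum. Fit by least squares with
#' data-driven multi-starts on centered years, parameters mapped back. The
#' degenerate flat solution (`b = 1`, `a` = mean) is always evaluated as a
#' candidate so constant series fit cleanly. `form = "polynomial"` selects
#' the alternative reading `D = a b (year - c)^2`.
#'
#' @param series data frame with columns `year` and `value`.
#' @param form `"power"` (default) or `"polynomial"`.
#' @return a `model_fit` with parameters `a`, `b`, `c`.
#' @export
fit_unimodal <- function(series, form = c("power", "polynomial")) {
  form <- match.arg(form)
  s <- as_series_xy(series)
  if (length(s$x) < 5) stop("insufficient-data error: need >= 5 points")
  xbar <- mean(s$x)
  xc <- s$x - xbar
  y <- s$y
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  if (form == "polynomial") {
    cc0 <- xc[which.max(abs(y - mean(y)))]
    f <- nls_try(y ~ k * (xc - cc)^2, data.frame(xc = xc, y = y),
                 list(list(k = 1, cc = cc0), list(k = -1, cc = cc0),
                      list(k = stats::sd(y) / max(diff(range(xc))^2, 1),
                           cc = 0)))
    if (is.null(f)) stop("non-convergence error: unimodal (polynomial) fit")
    k_hat <- stats::coef(f)[["k"]]
    a <- mean(y)
    rss <- sum(stats::residuals(f)^2)
    return(new_model_fit("unimodal",
                         list(a = a, b = k_hat / a,
                              c = stats::coef(f)[["cc"]] + xbar),
                         n, rss, tss, k = 4,
                         extra = list(form = form)))
  }
  a0 <- mean(y)
  cc0 <- xc[which.max(abs(y - a0))]
  b0 <- 0.999
  edge <- which.max(abs(xc - cc0))
  if (a0 > 0 && y[edge] > 0 && (xc[edge] - cc0)^2 > 0) {
    cand <- (y[edge] / a0)^(1 / (xc[edge] - cc0)^2)
    if (is.finite(cand) && cand > 0) b0 <- min(max(cand, 1e-6), 5)
  }
  starts <- list(list(a = a0, b = b0, c = cc0),
                 list(a = a0, b = 0.99, c = cc0),
                 list(a = max(y), b = 0.9995, c = 0),
                 list(a = a0, b = 1.01, c = cc0))
  f <- nls_try(y ~ a * b^((xc - c)^2), data.frame(xc = xc, y = y), starts,
               lower = c(a = -Inf, b = 1e-12, c = -Inf))
  rss_flat <- tss
  if (is.null(f) || sum(stats::residuals(f)^2) > rss_flat) {
    par <- list(a = mean(y), b = 1, c = xbar)
    rss <- rss_flat
  } else {
    co <- stats::coef(f)
    par <- list(a = co[["a"]], b = co[["b"]], c = co[["c"]] + xbar)
    rss <- sum(stats::residuals(f)^2)
  }
  new_model_fit("unimodal", par, n, rss, tss, k = 4,
                extra = list(form = form))
}

#' Asymptotic trend fit (D = a + b exp(-exp(c) year))
#'
#' `a` is the asymptote, `b` the gap between intercept and asymptote, `c`
#' the log rate constant. Fit on centered years with a small grid of rate
#' starts; `b` is mapped back to the original year scale. A flat candidate
#' (`b = 0`) is always evaluated so constant series fit cleanly.
#'
#' @param series data frame with columns `year` and `value`.
#' @return a `model_fit` with parameters `a`, `b`, `c`.
#' @export
fit_asymptotic <- function(series) {
  s <- as_series_xy(series)
  if (length(s$x) < 5) stop("insufficient-data error: need >= 5 points")
  xbar <- mean(s$x)
  xc <- s$x - xbar
  y <- s$y
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  span <- max(diff(range(s$x)), 1)
  ord <- order(xc)
  a0 <- y[ord[n]]
  b0 <- y[ord[1]] - a0
  starts <- lapply(log(c(0.2, 1, 4) / span), function(c0)
    list(a = a0, b = if (abs(b0) > 0) b0 else stats::sd(y) + 1e-9, c = c0))
  f <- nls_try(y ~ a + b * exp(-exp(c) * xc), data.frame(xc = xc, y = y),
               starts)
  if (is.null(f) || sum(stats::residuals(f)^2) > tss) {
    par <- list(a = mean(y), b = 0, c = log(1 / span))
    rss <- tss
  } else {
    co <- stats::coef(f)
    r <- exp(co[["c"]])
    par <- list(a = co[["a"]], b = co[["b"]] * exp(r * xbar), c = co[["c"]])
    rss <- sum(stats::residuals(f)^2)
  }
  new_model_fit("asymptotic", par, n, rss, tss, k = 4)
}

#' Four-parameter logistic trend fit
#'
#' `D = a + (b - a) / (1 + exp((c - year) / d))` with lower asymptote `a`,
#' upper asymptote `b`, inflection year `c` and scale `d` (years). Fit on
#' centered years with increasing and decreasing starts; `c` mapped back.
#'
#' @param series data frame with columns `year` and `value`.
#' @return a `model_fit` with parameters `a`, `b`, `c`, `d`.
#' @export
fit_logistic4 <- function(series) {
  s <- as_series_xy(series)
  if (length(s$x) < 6) stop("insufficient-data error: need >= 6 points")
  xbar <- mean(s$x)
  xc <- s$x - xbar
  y <- s$y
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  d0 <- max(diff(range(s$x)) / 4, 0.5)
  starts <- list(list(a = min(y), b = max(y), c = 0, d = d0),
                 list(a = max(y), b = min(y), c = 0, d = d0),
                 list(a = min(y), b = max(y), c = 0, d = d0 / 4))
  f <- nls_try(y ~ a + (b - a) / (1 + exp((c - xc) / d)),
               data.frame(xc = xc, y = y), starts)
  if (is.null(f)) stop("non-convergence error: logistic4 fit")
  co <- stats::coef(f)
  new_model_fit("logistic4",
                list(a = co[["a"]], b = co[["b"]], c = co[["c"]] + xbar,
                     d = co[["d"]]),
                n, sum(stats::residuals(f)^2), tss, k = 5)
}

model_families <- c("linear", "piecewise2", "quadratic", "unimodal",
                    "asymptotic", "logistic4")

#' Fit all six candidate temporal models and rank by AIC
#'
#' Fits the linear, two-breakpoint piecewise, quadratic, unimodal,
#' asymptotic and four-parameter logistic families; failures are recorded
#' as non-fits, never silently skipped. Ranking is by AIC ascending, with
#' numerically-zero-RSS ties broken in favour of fewer parameters.
#'
#' @param series data frame with columns `year` and `value`.
#' @param families subset of families to fit (default all six).
#' @return list with `fits` (named list of `model_fit` or error message)
#'   and `table` (ranked data frame: family, k, rss, aic, delta_aic, r2,
#'   converged).
#' @export
select_model <- function(series, families = model_families) {
  fitters <- list(linear = fit_linear, piecewise2 = fit_piecewise2,
                  quadratic = fit_quadratic, unimodal = fit_unimodal,
                  asymptotic = fit_asymptotic, logistic4 = fit_logistic4)
  fits <- lapply(families, function(fam)
    tryCatch(fitters[[fam]](series), error = function(e)
      conditionMessage(e)))
  names(fits) <- families
  ok <- vapply(fits, inherits, TRUE, what = "model_fit")
  tab <- data.frame(
    family = families,
    k = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "model_fit")) f$k else NA_real_, 0), NA),
    rss = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "model_fit")) f$rss else NA_real_, 0), NA),
    aic = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "model_fit")) f$aic else NA_real_, 0), NA),
    r2 = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "model_fit")) f$r2 else NA_real_, 0), NA),
    converged = ok,
    note = ifelse(ok, "", vapply(fits, function(f)
      if (is.character(f)) f else "", "")),
    stringsAsFactors = FALSE)
  o <- order(!tab$converged, tab$aic, tab$k)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  best <- suppressWarnings(min(tab$aic[tab$converged], na.rm = TRUE))
  delta <- tab$aic - best
  delta[is.nan(delta)] <- 0  # -Inf sentinel ties
  tab$delta_aic <- delta
  list(fits = fits, table = tab)
}

#' Bootstrap a two-breakpoint piecewise fit
#'
#' Case-resampling bootstrap: observation pairs (year, D) are resampled
#' with replacement at the original size and the piecewise model refit to
#' each replicate (warm-started at the point-estimate breakpoints, with a
#' quartile-grid fallback). Reported parameters, breakpoints, AIC and
#' r-squared are medians over successful replicates (the midpoint of the
#' two central order statistics for even counts). Replicate failures are
#' logged and excluded; if fewer than `min_success` of the replicates
#' converge the fit is declared unstable.
#'
#' @param series data frame with columns `year` and `value`.
#' @param n_boot bootstrap replicates (default 500).
#' @param seed integer seed (resampling is bit-reproducible).
#' @param min_success minimum fraction of successful replicates (default
#'   0.8).
#' @return the point `piecewise_fit` augmented with a `boot` element:
#'   `medians` (a, b, c, d, psi1, psi2, aic, r2), `replicates` (data
#'   frame), `n_success`, `n_boot`, `seed`.
#' @export
bootstrap_piecewise <- function(series, n_boot = 500L, seed = 1L,
                                min_success = 0.8) {
  s <- as_series_xy(series)
  point <- fit_piecewise2(series)
  set.seed(seed)
  n <- length(s$x)
  reps <- vector("list", n_boot)
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- data.frame(year = s$x[idx], value = s$y[idx])
    # warm start at the point-estimate breakpoints; full grid on failure
    f <- tryCatch(fit_piecewise2(sub, init = point$psi, grid_probs = NULL),
                  error = function(e) NULL)
    if (is.null(f))
      f <- tryCatch(fit_piecewise2(sub), error = function(e) NULL)
    reps[[r]] <- if (is.null(f)) NULL else
      c(a = f$par$a, b = f$par$b, c = f$par$c, d = f$par$d,
        psi1 = f$psi[1], psi2 = f$psi[2], aic = f$aic, r2 = f$r2)
  }
  ok <- !vapply(reps, is.null, TRUE)
  n_success <- sum(ok)
  if (n_success < min_success * n_boot)
    stop("instability error: only ", n_success, " of ", n_boot,
         " bootstrap replicates converged (need >= ",
         ceiling(min_success * n_boot), ")")
  df <- as.data.frame(do.call(rbind, reps[ok]))
  med <- vapply(df, stats::median, 0)
  point$boot <- list(medians = med, replicates = df,
                     n_success = n_success, n_boot = n_boot, seed = seed)
  point
}
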