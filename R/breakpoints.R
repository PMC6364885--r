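#' Regional change indicators from a piecewise fit
#'
#' Three indicators summarize each region-by-metric trajectory: the onset of
#' major change (first breakpoint, `psi1`), its duration (`psi2 - psi1`,
#' reported as a positive number of years), and the post-onset rate of
#' change (`b + c`, the slope between the breakpoints, in metric units per
#' year). Bootstrap medians are used when present, otherwise the point
#' estimates.
#'
#' @param fit a `piecewise_fit` (ideally from [bootstrap_piecewise()]).
#' @return list with `onset`, `duration`, `post_break_slope`.
#' @export
indicators <- function(fit) {
  stopifnot(inherits(fit, "piecewise_fit"))
  if (!is.null(fit$boot)) {
    m <- fit$boot$medians
    psi1 <- m[["psi1"]]
    psi2 <- m[["psi2"]]
    slope <- m[["b"]] + m[["c"]]
  } else {
    psi1 <- fit$psi[1]
    psi2 <- fit$psi[2]
    slope <- fit$par$b + fit$par$c
  }
  if (!(psi1 < psi2))
    stop("instability error: breakpoint medians out of order (psi1 = ",
         round(psi1, 2), ", psi2 = ", round(psi2, 2), ")")
  list(onset = psi1, duration = psi2 - psi1, post_break_slope = slope)
}

#' Tidy indicator table for a set of fits
#' @param fits named list (names = `region|metric` or similar keys) of
#'   `piecewise_fit` objects; fits whose indicators error are dropped with a
#'   warning listing them (never imputed).
#' @param keys optional data frame with columns `region` and `metric`
#'   aligned to `fits`.
#' @return data frame: region, metric, onset, duration, post_break_slope.
#' @export
indicator_table <- function(fits, keys = NULL) {
  if (is.null(keys)) {
    parts <- strsplit(names(fits), "|", fixed = TRUE)
    keys <- data.frame(region = vapply(parts, `[`, "", 1L),
                       metric = vapply(parts, function(p)
                         if (length(p) > 1) p[2] else NA_character_, ""),
                       stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_along(fits), function(i)
    tryCatch({
      ind <- indicators(fits[[i]])
      data.frame(region = keys$region[i], metric = keys$metric[i],
                 onset = ind$onset, duration = ind$duration,
                 post_break_slope = ind$post_break_slope,
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL))
  dropped <- vapply(rows, is.null, TRUE)
  if (any(dropped))
    warning("indicators unavailable for: ",
            paste(names(fits)[dropped], collapse = ", "))
  do.call(rbind, rows[!dropped])
}

#' Cross-region regression of one indicator on another
#'
#' OLS of `y` on `x` with pairing by region label; only regions present in
#' both vectors are used. The usual t-based p-value for the slope is
#' returned.
#'
#' @param x,y named numeric vectors (names = region labels), e.g. onsets of
#'   two diversity metrics.
#' @return list: slope, intercept, r2, p, n, regions used.
#' @export
cross_regress <- function(x, y) {
  common <- intersect(names(x), names(y))
  common <- common[!is.na(x[common]) & !is.na(y[common])]
  if (length(common) < 3)
    stop("insufficient-data error: need >= 3 paired regions")
  xv <- as.numeric(x[common])
  yv <- as.numeric(y[common])
  f <- stats::lm(yv ~ xv)
  sm <- suppressWarnings(summary(f))  # exact fits are legitimate inputs
  list(slope = unname(stats::coef(f)[2]),
       intercept = unname(stats::coef(f)[1]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       n = length(common), regions = common)
}

#' Joint F-test against a 1:1 relationship
#'
#' Tests whether the regression of `y` on `x` differs from the identity
#' line, via the joint linear hypothesis {intercept = 0, slope = 1}:
#' `F = ((RSS_restricted - RSS_full) / 2) / (RSS_full / (n - 2))` with
#' `RSS_restricted` computed from predictions `yhat = x`, compared to
#' `F(2, n - 2)`. An exact 1:1 relationship (both RSS zero) reports p = 1.
#'
#' @param x,y named numeric vectors paired by region label.
#' @return list: F, p, n.
#' @export
test_one_to_one <- function(x, y) {
  common <- intersect(names(x), names(y))
  common <- common[!is.na(x[common]) & !is.na(y[common])]
  n <- length(common)
  if (n < 3) stop("insufficient-data error: need >= 3 paired regions")
  xv <- as.numeric(x[common])
  yv <- as.numeric(y[common])
  f <- stats::lm(yv ~ xv)
  rss_full <- sum(stats::residuals(f)^2)
  rss_restr <- sum((yv - xv)^2)
  if (rss_full < 1e-24) {
    if (rss_restr < 1e-24) return(list(F = 0, p = 1, n = n))
    return(list(F = Inf, p = 0, n = n))
  }
  Fstat <- ((rss_restr - rss_full) / 2) / (rss_full / (n - 2))
  if (Fstat < 0) Fstat <- 0  # numerical guard; restricted RSS >= full RSS
  list(F = Fstat, p = stats::pf(Fstat, 2, n - 2, lower.tail = FALSE), n = n)
}

#' Cross-region summary of an indicator
#'
#' @param v named numeric vector of one indicator across regions.
#' @param center `"mean"` (with sd) or `"median"` (with median absolute
#'   deviation).
#' @return list: center, spread, n.
#' @export
summarize_indicator <- function(v, center = c("mean", "median")) {
  center <- match.arg(center)
  v <- v[!is.na(v)]
  if (center == "mean")
    list(center = mean(v), spread = stats::sd(v), n = length(v))
  else
    list(center = stats::median(v), spread = stats::mad(v), n = length(v))
}
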