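#' Bray-Curtis dissimilarity between two communities
#'
#' `sum |x_i - y_i| / sum (x_i + y_i)` over the union of taxa (absent taxa
#' count as 0): 0 for identical communities, 1 for disjoint ones.
#'
#' @param x,y named abundance vectors.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  taxa <- union(names(x), names(y))
  xv <- yv <- stats::setNames(numeric(length(taxa)), taxa)
  xv[names(x)] <- x
  yv[names(y)] <- y
  tot <- sum(xv + yv)
  if (tot <= 0)
    stop("undefined-value error: Bray-Curtis of two empty communities")
  sum(abs(xv - yv)) / tot
}

#' Pairwise Bray-Curtis matrix over all region-year communities
#'
#' Builds the global community matrix (rows = region-year samples at
#' commodity-group granularity, regions in lexical order with years
#' ascending) and computes all pairwise Bray-Curtis dissimilarities. Empty
#' communities are excluded with a warning.
#'
#' @param panel a `crop_panel`.
#' @return a `dist` of class `crop_dist` with attribute `keys`, a data frame
#'   (`region`, `year`) aligned to the samples.
#' @export
dissimilarity_matrix <- function(panel) {
  m <- panel_matrix(panel)
  keys <- data.frame(region = attr(m, "region"), year = attr(m, "year"),
                     stringsAsFactors = FALSE)
  nonempty <- rowSums(m) > 0
  if (!all(nonempty)) {
    warning(sum(!nonempty), " empty region-year communities excluded: ",
            paste(utils::head(rownames(m)[!nonempty], 5L), collapse = ", "))
    m <- m[nonempty, , drop = FALSE]
    keys <- keys[nonempty, , drop = FALSE]
  }
  if (nrow(m) < 2)
    stop("insufficient-data error: need >= 2 non-empty communities")
  d <- vegan::vegdist(m, method = "bray")
  attr(d, "keys") <- keys
  class(d) <- c("crop_dist", class(d))
  d
}

#' Sample keys of a dissimilarity matrix
#' @param dm a `crop_dist`.
#' @return data frame with columns `region`, `year`.
#' @export
dist_keys <- function(dm) attr(dm, "keys")

#' NMDS ordination of a dissimilarity matrix
#'
#' Non-metric multidimensional scaling minimizing Kruskal stress-1 with
#' monotone regression of configuration distances on dissimilarity ranks;
#' `restarts` random initializations plus a metric-scaling start, best
#' stress returned; deterministic given `seed`.
#'
#' @param dm a `crop_dist` (or any `dist`).
#' @param k ordination dimensions (default 2).
#' @param restarts random restarts (default 20).
#' @param seed integer seed.
#' @return list: `coordinates` (n x k matrix), `stress` (Kruskal stress-1,
#'   0-1 scale), `converged`, `restarts`, `seed`.
#' @export
nmds <- function(dm, k = 2L, restarts = 20L, seed = 1L) {
  n <- attr(dm, "Size")
  if (is.null(n)) stop("dm must be a dist object")
  if (n < k + 2) stop("insufficient-data error: need >= k + 2 samples")
  v <- as.numeric(dm)
  if (max(v) - min(v) < 1e-12)
    stop("degenerate-solution error: all dissimilarities equal")
  set.seed(seed)
  fit <- vegan::metaMDS(stats::as.dist(dm), k = k, try = restarts,
                        trymax = restarts, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  coords <- fit$points
  keys <- attr(dm, "keys")
  if (!is.null(keys))
    rownames(coords) <- paste(keys$region, keys$year, sep = "|")
  list(coordinates = coords, stress = fit$stress,
       converged = isTRUE(fit$converged) || fit$converged > 0,
       restarts = restarts, seed = seed)
}

#' PERMANOVA of crop composition on region, year and their interaction
#'
#' Partitions the dissimilarity matrix by sequential (Type-I) sums of
#' squares in the order region (categorical), year (numeric covariate),
#' region x year, with free permutation of sample labels;
#' `p = (exceedances + 1) / (permutations + 1)`. A term with a single level
#' contributes SS = 0, r2 = 0. Term r2 values plus the residual sum to 1.
#'
#' @param dm a `crop_dist` (keys supply the factors) or a `dist` with
#'   `keys` given.
#' @param keys data frame with columns `region` and `year` aligned to the
#'   samples (default taken from `dm`).
#' @param permutations number of permutations (default 999).
#' @param seed integer seed.
#' @param terms model terms in sequential order.
#' @return data frame: term, df, SS, r2, F, p (residual and total rows
#'   included).
#' @export
permanova <- function(dm, keys = dist_keys(dm), permutations = 999L,
                      seed = 1L,
                      terms = c("region", "year", "region:year")) {
  if (permutations < 1) stop("config error: permutations must be >= 1")
  if (is.null(keys)) stop("sample keys required")
  keys <- data.frame(region = factor(keys$region),
                     year = as.numeric(keys$year))
  usable <- vapply(terms, function(tm) {
    vars <- strsplit(tm, ":", fixed = TRUE)[[1]]
    all(vapply(vars, function(v) length(unique(keys[[v]])) > 1, TRUE))
  }, TRUE)
  rhs <- paste(terms[usable], collapse = " + ")
  if (!nzchar(rhs)) stop("config error: no usable terms")
  set.seed(seed)
  form <- stats::as.formula(paste("dm ~", rhs))
  res <- vegan::adonis2(form, data = keys, permutations = permutations,
                        by = "terms")
  tab <- data.frame(term = rownames(res), df = res$Df, SS = res$SumOfSqs,
                    r2 = res$R2, F = res$F, p = res$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  if (any(!usable)) {
    zero <- data.frame(term = terms[!usable], df = 0, SS = 0, r2 = 0,
                       F = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
    tab <- rbind(tab[tab$term %in% terms, , drop = FALSE], zero,
                 tab[!tab$term %in% terms, , drop = FALSE])
  }
  rownames(tab) <- NULL
  tab
}

#' Within-year region-pair dissimilarities
#'
#' All pairs of distinct regions observed in the same year, with their
#' Bray-Curtis dissimilarity. With R regions over Y years and one region
#' covering only y of them, the pair count is
#' `(Y - y) * choose(R - 1, 2) + y * choose(R, 2)`.
#'
#' @param dm a `crop_dist` from [dissimilarity_matrix()].
#' @return data frame: year, region_i, region_j, bc.
#' @export
within_year_pairs <- function(dm) {
  keys <- dist_keys(dm)
  m <- as.matrix(dm)
  out <- lapply(sort(unique(keys$year)), function(y) {
    idx <- which(keys$year == y)
    if (length(idx) < 2) return(NULL)
    pr <- utils::combn(idx, 2)
    data.frame(year = y, region_i = keys$region[pr[1, ]],
               region_j = keys$region[pr[2, ]],
               bc = m[cbind(pr[1, ], pr[2, ])],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Trend in among-region similarity through time
#'
#' Regresses within-year pairwise Bray-Curtis dissimilarity on year, over
#' all region pairs (one observation per pair-year, not yearly averages): a
#' negative slope indicates homogenization (regions growing more similar
#' crops). Returns both the OLS fit and the two-breakpoint piecewise fit of
#' the same series. Values are dissimilarities; similarity is `1 - bc`.
#'
#' @param dm a `crop_dist` from [dissimilarity_matrix()].
#' @return list: `pairs` (the data), `linear` (slope, intercept, r2, p, n),
#'   `piecewise` (a `piecewise_fit`, or the error message if it failed).
#' @export
similarity_trend <- function(dm) {
  pairs <- within_year_pairs(dm)
  if (is.null(pairs) || length(unique(pairs$year)) < 3)
    stop("insufficient-data error: need >= 3 distinct years with pairs")
  f <- stats::lm(bc ~ year, data = pairs)
  sm <- summary(f)
  linear <- list(slope = unname(stats::coef(f)[2]),
                 intercept = unname(stats::coef(f)[1]),
                 r2 = sm$r.squared,
                 p = unname(sm$coefficients[2, 4]),
                 n = nrow(pairs))
  pw <- tryCatch(fit_piecewise2(data.frame(year = pairs$year,
                                           value = pairs$bc)),
                 error = function(e) conditionMessage(e))
  list(pairs = pairs, linear = linear, piecewise = pw)
}
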