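#' Evaluate a two-breakpoint piecewise-linear curve
#'
#' `a + b y + c max(y - psi1, 0) + d max(y - psi2, 0)`: slope `b` before
#' `psi1`, `b + c` between the breakpoints, `b + c + d` after `psi2`;
#' continuous at both breakpoints.
#'
#' @param year numeric years.
#' @param a,b,c,d curve parameters.
#' @param psi1,psi2 breakpoint years.
#' @return curve values.
#' @export
piecewise_curve <- function(year, a, b, c, d, psi1, psi2) {
  a + b * year + c * pmax(year - psi1, 0) + d * pmax(year - psi2, 0)
}

#' Scenario specification for synthetic area-harvested panels
#'
#' Defaults encode the study conditions of a global FAO-style panel:
#' 22 subcontinental regions observed 1961-2014 over a pool of 157
#' commodity groups, one region truncated to 1992 onward (as Central Asia
#' is in FAO data); per-region species-richness trajectories are
#' two-breakpoint piecewise-linear with onsets drawn from N(1982.4, 5.6^2),
#' change rates from N(2.1, 2.4^2) species per year and change durations
#' from N(8.4, 5.4^2) years (truncated to feasible values), flat slopes
#' before and after the change window, and Gaussian richness noise of sd 1
#' species; per-record areas are heavy-tailed log-normal hectares
#' (meanlog 8, sdlog 2).
#'
#' @param n_regions number of regions.
#' @param years observed calendar years.
#' @param n_groups commodity-group pool size.
#' @param base_richness_range uniform range for 1961 richness.
#' @param onset_mean,onset_sd distribution of the first breakpoint year.
#' @param duration_mean,duration_sd distribution of psi2 - psi1 (years).
#' @param rate_mean,rate_sd distribution of the between-breakpoint slope
#'   (groups per year).
#' @param pre_slope,post_slope slopes before psi1 and after psi2.
#' @param noise_sd richness noise sd (groups).
#' @param area_meanlog,area_sdlog log-normal area parameters (ha).
#' @param truncated_region truncate the last region's series?
#' @param truncated_start first observed year of the truncated region.
#' @param trajectories optional data frame (region, a, b, c, d, psi1, psi2)
#'   overriding the random trajectory draws.
#' @param seed integer seed.
#' @return a list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_regions = 22L, years = 1961:2014,
                          n_groups = 157L,
                          base_richness_range = c(40, 80),
                          onset_mean = 1982.4, onset_sd = 5.6,
                          duration_mean = 8.4, duration_sd = 5.4,
                          rate_mean = 2.1, rate_sd = 2.4,
                          pre_slope = 0, post_slope = 0,
                          noise_sd = 1,
                          area_meanlog = 8, area_sdlog = 2,
                          truncated_region = TRUE,
                          truncated_start = 1992L,
                          trajectories = NULL,
                          seed = 1L) {
  spec <- as.list(environment())
  stopifnot(n_regions >= 1, length(years) >= 8, n_groups >= 2,
            noise_sd >= 0, onset_sd >= 0, duration_sd >= 0, rate_sd >= 0)
  class(spec) <- "scenario_spec"
  spec
}

region_names <- function(n) sprintf("region%02d", seq_len(n))
group_names <- function(n) sprintf("grp%03d", seq_len(n))

draw_trajectories <- function(spec) {
  yrs <- spec$years
  lo <- min(yrs)
  hi <- max(yrs)
  regions <- region_names(spec$n_regions)
  out <- vector("list", spec$n_regions)
  for (i in seq_along(regions)) {
    r0 <- stats::runif(1, spec$base_richness_range[1],
                       spec$base_richness_range[2])
    dur <- min(max(stats::rnorm(1, spec$duration_mean, spec$duration_sd),
                   3), 20)
    psi1 <- min(max(stats::rnorm(1, spec$onset_mean, spec$onset_sd),
                    lo + 5), hi - dur - 5)
    rate <- stats::rnorm(1, spec$rate_mean, spec$rate_sd)
    # keep the trajectory inside the group pool
    max_gain <- spec$n_groups - 2 - r0
    if (rate * dur > max_gain) rate <- max_gain / dur
    if (r0 + rate * dur < 2) rate <- (2 - r0) / dur
    b <- spec$pre_slope
    mid <- rate
    post <- spec$post_slope
    out[[i]] <- data.frame(region = regions[i],
                           a = r0 - b * lo, b = b, c = mid - b,
                           d = post - mid,
                           psi1 = psi1, psi2 = psi1 + dur,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic area-harvested panel with known ground truth
#'
#' Per region-year the target richness is the piecewise-linear trajectory
#' value plus Gaussian noise, rounded and clamped to `[1, n_groups]`; the
#' groups present are the first k of a fixed per-region preference ordering
#' over the pool (so richness changes imply nested, persistent gains and
#' losses, the way new FAO commodity groups appear once and persist); areas
#' are i.i.d. log-normal. Byte-identical output for the same spec/seed.
#'
#' @param spec a [scenario_spec()].
#' @return list: `panel` (a `crop_panel`), `truth` (per-region trajectory
#'   parameters), `preferences` (per-region group orderings).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  groups <- group_names(spec$n_groups)
  regions <- region_names(spec$n_regions)
  truth <- if (is.null(spec$trajectories)) draw_trajectories(spec)
           else spec$trajectories
  stopifnot(nrow(truth) == spec$n_regions)
  prefs <- lapply(regions, function(r) sample(groups))
  names(prefs) <- regions
  rows <- vector("list", spec$n_regions)
  for (i in seq_along(regions)) {
    yrs <- spec$years
    if (spec$truncated_region && i == spec$n_regions)
      yrs <- yrs[yrs >= spec$truncated_start]
    tr <- truth[i, ]
    target <- piecewise_curve(yrs, tr$a, tr$b, tr$c, tr$d, tr$psi1, tr$psi2)
    k <- round(target + stats::rnorm(length(yrs), 0, spec$noise_sd))
    if (any(target > spec$n_groups))
      stop("spec error: trajectory exceeds the group pool for ",
           regions[i])
    k <- pmin(pmax(k, 1L), spec$n_groups)
    per_year <- lapply(seq_along(yrs), function(t) {
      g <- prefs[[i]][seq_len(k[t])]
      data.frame(region = regions[i], year = yrs[t], group = g,
                 area = stats::rlnorm(k[t], spec$area_meanlog,
                                      spec$area_sdlog),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, per_year)
  }
  panel <- as_crop_panel(do.call(rbind, rows))
  list(panel = panel, truth = truth, preferences = prefs)
}

#' Generate a group-species mapping with multi-species groups
#'
#' A configurable fraction of groups carries several species (exercising
#' the one-species-per-group randomization); the rest map to exactly one.
#'
#' @param n_groups number of commodity groups.
#' @param multi_frac fraction of groups with several species (default 0.2).
#' @param multi_sizes candidate species counts for multi-species groups.
#' @param seed integer seed.
#' @return named list: group -> species labels (species unique overall).
#' @export
generate_group_map <- function(n_groups, multi_frac = 0.2,
                               multi_sizes = 2:5, seed = 1L) {
  set.seed(seed)
  groups <- group_names(n_groups)
  n_multi <- round(multi_frac * n_groups)
  sizes <- rep(1L, n_groups)
  if (n_multi > 0)
    sizes[sample.int(n_groups, n_multi)] <-
      sample(multi_sizes, n_multi, replace = TRUE)
  total <- sum(sizes)
  species <- sprintf("sp%04d", seq_len(total))
  map <- split(species, rep(seq_len(n_groups), sizes))
  names(map) <- groups
  map
}

#' Generate a random dated tree and a partial calibration table
#'
#' Random bifurcating topology by sequential random joins; join ages are
#' sorted uniforms on `(0, root_age)` (root at `root_age` exactly), so
#' ancestor ages always exceed descendant ages. The returned calibration
#' table exposes only a fraction of internal-node ages (the root always),
#' enabling round-trip tests of the interpolation dater.
#'
#' @param n_taxa number of tips (>= 2).
#' @param root_age root age, My.
#' @param dated_fraction fraction of non-root internal nodes whose true age
#'   is exposed in the calibration table.
#' @param seed integer seed.
#' @param tip_labels optional tip labels (default `sp0001...`).
#' @return list: `tree` (fully dated `dated_tree` with true ages),
#'   `age_table` (named vector for [bladj_date()]).
#' @export
generate_tree <- function(n_taxa, root_age = 150, dated_fraction = 0.5,
                          seed = 1L, tip_labels = NULL) {
  stopifnot(n_taxa >= 2, root_age > 0)
  set.seed(seed)
  if (is.null(tip_labels)) tip_labels <- sprintf("sp%04d", seq_len(n_taxa))
  stopifnot(length(tip_labels) == n_taxa)
  heights <- c(sort(stats::runif(n_taxa - 2, 0, root_age)), root_age)
  active <- seq_len(n_taxa)
  next_id <- n_taxa + 1L
  edges <- matrix(0L, nrow = 2L * (n_taxa - 1L), ncol = 2L)
  age <- c(rep(0, n_taxa), numeric(n_taxa - 1L))
  e <- 0L
  for (k in seq_len(n_taxa - 1L)) {
    pick <- sample.int(length(active), 2L)
    kids <- active[pick]
    edges[e + 1L, ] <- c(next_id, kids[1])
    edges[e + 2L, ] <- c(next_id, kids[2])
    e <- e + 2L
    age[next_id] <- heights[k]
    active <- c(active[-pick], next_id)
    next_id <- next_id + 1L
  }
  # renumber internals in preorder so the root gets n_taxa + 1
  root_old <- next_id - 1L
  order_new <- integer(2L * n_taxa - 1L)
  order_new[seq_len(n_taxa)] <- seq_len(n_taxa)
  stack <- root_old
  nid <- n_taxa
  kids_of <- split(edges[, 2], edges[, 1])
  preorder <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    preorder <- c(preorder, v)
    ch <- kids_of[[as.character(v)]]
    stack <- c(stack, rev(ch[ch > n_taxa]))
  }
  for (v in preorder) {
    nid <- nid + 1L
    order_new[v] <- nid
  }
  new_edges <- cbind(order_new[edges[, 1]], order_new[edges[, 2]])
  new_age <- numeric(2L * n_taxa - 1L)
  new_age[order_new] <- age
  # emit edges in depth-first preorder (the cladewise convention)
  kids_new <- split(new_edges[, 2], new_edges[, 1])
  ord_edges <- integer(0)
  emit <- function(v) {
    for (ch in kids_new[[as.character(v)]]) {
      ord_edges[length(ord_edges) + 1L] <<- match(ch, new_edges[, 2])
      if (ch > n_taxa) emit(ch)
    }
  }
  emit(n_taxa + 1L)
  new_edges <- new_edges[ord_edges, , drop = FALSE]
  labs <- sprintf("node%04d", seq_len(n_taxa - 1L))
  phy <- structure(list(edge = new_edges, tip.label = tip_labels,
                        node.label = labs, Nnode = n_taxa - 1L),
                   class = "phylo", order = "cladewise")
  dt <- dated_tree(phy, ages = new_age)
  internal_ages <- stats::setNames(new_age[n_taxa + seq_len(n_taxa - 1L)],
                                   labs)
  expose <- 1L  # root (first preorder internal)
  others <- setdiff(seq_len(n_taxa - 1L), expose)
  n_extra <- round(dated_fraction * length(others))
  if (n_extra > 0) expose <- c(expose, sample(others, n_extra))
  list(tree = dt, age_table = internal_ages[sort(expose)])
}

#' Generate a panel with converging regional crop pools
#'
#' As [generate_panel()], but each region's crop pool converges toward a
#' common pool across a convergence window, emulating homogenization. A
#' region's abundance profile assigns log-areas declining with its
#' preference rank (major crops carry most of the harvested area); across
#' the window each profile blends linearly into a common profile, and
#' group membership follows the correspondingly blended ordering, so
#' within-year Bray-Curtis dissimilarity among regions declines close to
#' linearly across the window (up to small yearly jitter and membership
#' truncation) and is static outside it.
#'
#' @param spec a [scenario_spec()].
#' @param window numeric length-2 convergence window (years), inside the
#'   spec's year range.
#' @return list: `panel`, `truth`, `window`.
#' @export
generate_homogenization_panel <- function(spec, window = c(1983, 1992)) {
  stopifnot(inherits(spec, "scenario_spec"), length(window) == 2)
  if (window[1] > window[2] || window[1] < min(spec$years) ||
      window[2] > max(spec$years))
    stop("spec error: convergence window outside the year range")
  set.seed(spec$seed)
  groups <- group_names(spec$n_groups)
  regions <- region_names(spec$n_regions)
  truth <- if (is.null(spec$trajectories)) draw_trajectories(spec)
           else spec$trajectories
  common <- sample(groups)
  common_rank <- match(groups, common)
  prefs <- lapply(regions, function(r) match(groups, sample(groups)))
  names(prefs) <- regions
  # log-area level by preference rank: top-ranked crops dominate the area
  rank_level <- spec$area_meanlog +
    spec$area_sdlog * stats::qnorm(1 - (seq_len(spec$n_groups) - 0.5) /
                                     spec$n_groups)
  profile_common <- exp(rank_level)[common_rank]
  frac <- function(y) {
    if (window[2] == window[1]) as.numeric(y >= window[2])
    else pmin(pmax((y - window[1]) / (window[2] - window[1]), 0), 1)
  }
  rows <- vector("list", spec$n_regions)
  for (i in seq_along(regions)) {
    yrs <- spec$years
    if (spec$truncated_region && i == spec$n_regions)
      yrs <- yrs[yrs >= spec$truncated_start]
    tr <- truth[i, ]
    target <- piecewise_curve(yrs, tr$a, tr$b, tr$c, tr$d, tr$psi1, tr$psi2)
    k <- pmin(pmax(round(target + stats::rnorm(length(yrs), 0,
                                               spec$noise_sd)), 1L),
              spec$n_groups)
    profile_region <- exp(rank_level)[prefs[[i]]]
    per_year <- lapply(seq_along(yrs), function(t) {
      f <- frac(yrs[t])
      score <- (1 - f) * prefs[[i]] + f * common_rank
      sel <- order(score)[seq_len(k[t])]
      ab <- (1 - f) * profile_region[sel] + f * profile_common[sel]
      data.frame(region = regions[i], year = yrs[t], group = groups[sel],
                 area = ab * exp(stats::rnorm(k[t], 0, 0.1)),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, per_year)
  }
  panel <- as_crop_panel(do.call(rbind, rows))
  list(panel = panel, truth = truth, window = window)
}

#' Write a scenario's artifacts in the formats the readers consume
#'
#' Emits the delimited panel (FAOSTAT dialect), the group-species mapping,
#' the newick tree, the ages file and a delimited truth table, so the whole
#' pipeline can be exercised through its file interfaces.
#'
#' @param sim result of [generate_panel()].
#' @param map a group-species map.
#' @param tree_gen result of [generate_tree()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_scenario <- function(sim, map, tree_gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(panel = file.path(dir, "panel.csv"),
             mapping = file.path(dir, "mapping.csv"),
             tree = file.path(dir, "tree.nwk"),
             ages = file.path(dir, "ages.txt"),
             truth = file.path(dir, "truth.tsv"))
  pd <- sim$panel
  utils::write.table(data.frame(region = pd$region, year = pd$year,
                                item = pd$group,
                                element = "Area harvested",
                                value = pd$area),
                     paths[["panel"]], sep = ",", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(group = rep(names(map), lengths(map)),
                                species = unlist(map, use.names = FALSE)),
                     paths[["mapping"]], sep = ",", quote = FALSE,
                     row.names = FALSE)
  write_newick(tree_gen$tree, paths[["tree"]])
  write_ages(tree_gen$age_table, paths[["ages"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
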