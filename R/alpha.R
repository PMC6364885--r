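#' Species richness of a community
#'
#' Number of taxa with positive abundance. At the panel's native granularity
#' each commodity group counts once (one species per group).
#'
#' @param comm named abundance vector (see [community()]).
#' @return integer count.
#' @export
species_richness <- function(comm) {
  as.integer(sum(comm > 0))
}

#' Gini-Simpson diversity of a community
#'
#' `1 - sum(p_i^2)` with `p_i` the proportional area harvested. Ranges in
#' `[0, 1)`: 0 for a single taxon, approaching 1 as many taxa become equally
#' abundant.
#'
#' @param comm named abundance vector with positive total.
#' @return numeric in `[0, 1)`.
#' @export
simpson_diversity <- function(comm) {
  comm <- comm[comm > 0]
  if (!length(comm))
    stop("undefined-value error: Simpson diversity of an empty community")
  p <- comm / sum(comm)
  1 - sum(p^2)
}

#' Draw one species per commodity group
#'
#' Uniform draw from each group's species list; uses the current RNG state.
#'
#' @param map group-species map (named list).
#' @param groups group labels to draw for.
#' @return named character vector: group -> drawn species.
#' @export
draw_assignment <- function(map, groups) {
  missing <- setdiff(groups, names(map))
  if (length(missing))
    stop("validation error: groups missing from mapping: ",
         paste(missing, collapse = ", "))
  sp <- vapply(map[groups], function(s) s[sample.int(length(s), 1L)], "")
  names(sp) <- groups
  sp
}

#' Faith's phylogenetic diversity of a community under one assignment
#'
#' Sum of branch lengths (My) spanned by the species drawn for the present
#' groups, root path included: the millions of years of plant evolution
#' represented by the crops grown. Two groups resolving to the same species
#' contribute that species once (set semantics).
#'
#' @param dt a dated `dated_tree`.
#' @param comm named abundance vector (groups).
#' @param map group-species map.
#' @param draw named vector group -> species covering the present groups
#'   (see [draw_assignment()]).
#' @return PD in My.
#' @export
faith_pd <- function(dt, comm, map, draw) {
  groups <- names(comm)[comm > 0]
  sp <- assignment_species(groups, map, draw)
  total_branch_length(dt, unique(sp))
}

#' Rao's quadratic entropy (phylogenetic) under one assignment
#'
#' `sum_i sum_{j != i} d_ij p_i p_j` over ordered species pairs, with `d_ij`
#' the patristic distance (My) and `p` proportional area harvested. Group
#' areas attach to the drawn species; groups resolving to the same species
#' pool their areas (total area conserved).
#'
#' @inheritParams faith_pd
#' @return QE in My (expected pairwise evolutionary distance).
#' @export
rao_qe <- function(dt, comm, map, draw) {
  comm <- comm[comm > 0]
  sp <- assignment_species(names(comm), map, draw)
  ab <- tapply(as.numeric(comm), sp, sum)
  if (length(ab) < 2) return(0)
  p <- ab / sum(ab)
  d <- patristic_matrix(dt, names(ab))
  as.numeric(t(p) %*% d %*% p)
}

assignment_species <- function(groups, map, draw) {
  if (!all(groups %in% names(draw)))
    stop("assignment must cover every present group")
  sp <- draw[groups]
  ok <- vapply(groups, function(g) sp[[g]] %in% map[[g]], TRUE)
  if (!all(ok))
    stop("assignment picks species outside their group: ",
         paste(groups[!ok], collapse = ", "))
  unname(sp)
}

# precomputed structures for fast repeated PD/QE over one species universe
phylo_cache <- function(dt, species) {
  unknown <- setdiff(species, dt$phy$tip.label)
  if (length(unknown))
    stop("lookup error: species not in tree: ",
         paste(sort(unknown), collapse = ", "))
  par <- parent_vec(dt$phy)
  bl <- dt$ages[par] - dt$ages
  idx <- match(species, dt$phy$tip.label)
  paths <- lapply(idx, function(tip) {
    v <- tip
    out <- integer(0)
    while (!is.na(par[v])) {
      out <- c(out, v)
      v <- par[v]
    }
    out
  })
  names(paths) <- species
  list(paths = paths, bl = bl, dmat = patristic_matrix(dt, species))
}

cache_pd <- function(cache, species) {
  sum(cache$bl[unique(unlist(cache$paths[species], use.names = FALSE))])
}

cache_qe <- function(cache, species, areas) {
  ab <- tapply(areas, species, sum)
  if (length(ab) < 2) return(0)
  p <- as.numeric(ab) / sum(ab)
  d <- cache$dmat[names(ab), names(ab)]
  as.numeric(t(p) %*% d %*% p)
}

new_diversity_series <- function(region, metric, year, value,
                                 n_rep = NA_integer_, seed = NA_integer_) {
  structure(data.frame(year = as.integer(year), value = as.numeric(value)),
            region = region, metric = metric, n_rep = n_rep, seed = seed,
            class = c("diversity_series", "data.frame"))
}

#' Taxonomic diversity series for one region
#'
#' Yearly species richness (`"SR"`) or Gini-Simpson diversity (`"SD"`) at
#' commodity-group granularity, over the region's observed years.
#'
#' @param panel a `crop_panel`.
#' @param region region label.
#' @param metric `"SR"` or `"SD"`.
#' @return a `diversity_series` data frame (`year`, `value`) with attributes
#'   `region` and `metric`.
#' @export
alpha_series <- function(panel, region, metric = c("SR", "SD")) {
  metric <- match.arg(metric)
  yrs <- panel_years(panel, region)
  if (!length(yrs)) stop("lookup error: unknown region '", region, "'")
  val <- vapply(yrs, function(y) {
    comm <- community(panel, region, y)
    if (metric == "SR") as.numeric(species_richness(comm))
    else simpson_diversity(comm)
  }, 0)
  new_diversity_series(region, metric, yrs, val)
}

region_stream_seed <- function(seed, region, year = 0L) {
  h <- sum(utf8ToInt(region) * seq_along(utf8ToInt(region)))
  as.integer((as.numeric(seed) * 48271 + h * 7919 +
                as.numeric(year) * 104729) %% 2147483629)
}

#' Randomized phylogenetic diversity series for one region
#'
#' Area-harvested panels report abundance per commodity group while the
#' phylogeny lives at species level, so PD and QE are computed under
#' repeated random one-species-per-group assignments: `n_rep` independent
#' draws per year (or one draw per replicate held across the whole series
#' when `per_year = FALSE`), summarized as the median over replicates. Runs
#' are bit-reproducible given `seed`; substreams are derived per
#' (region, year) so evaluation order does not matter.
#'
#' @param panel a `crop_panel`.
#' @param region region label.
#' @param tree a dated `dated_tree` containing every mapped species.
#' @param map group-species map covering the region's groups.
#' @param n_rep replicates (default 100).
#' @param seed integer master seed.
#' @param per_year redraw assignments independently each year (default) or
#'   hold one assignment per replicate across years.
#' @return list with `diversity_series` elements `PD` and `QEphy`.
#' @export
randomized_series <- function(panel, region, tree, map, n_rep = 100L,
                              seed = 1L, per_year = TRUE) {
  stopifnot(n_rep >= 1L)
  yrs <- panel_years(panel, region)
  if (!length(yrs)) stop("lookup error: unknown region '", region, "'")
  groups_all <- sort(unique(panel$group[panel$region == region]),
                     method = "radix")
  missing <- setdiff(groups_all, names(map))
  if (length(missing))
    stop("validation error: groups missing from mapping: ",
         paste(missing, collapse = ", "))
  universe <- unique(unlist(map[groups_all], use.names = FALSE))
  cache <- phylo_cache(tree, universe)
  sizes <- lengths(map[groups_all])
  names(sizes) <- groups_all
  draw_for <- function(groups) {
    vapply(groups, function(g) {
      s <- map[[g]]
      s[[sample.int(length(s), 1L)]]
    }, "")
  }
  held <- NULL
  if (!per_year) {
    set.seed(region_stream_seed(seed, region))
    held <- replicate(n_rep, draw_for(groups_all), simplify = FALSE)
  }
  pd_med <- qe_med <- numeric(length(yrs))
  for (i in seq_along(yrs)) {
    comm <- community(panel, region, yrs[i])
    groups <- names(comm)
    if (!length(groups)) {
      pd_med[i] <- 0
      qe_med[i] <- 0
      next
    }
    if (per_year) set.seed(region_stream_seed(seed, region, yrs[i]))
    pd_r <- qe_r <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      sp <- if (per_year) draw_for(groups) else held[[r]][groups]
      pd_r[r] <- cache_pd(cache, unique(sp))
      qe_r[r] <- cache_qe(cache, sp, as.numeric(comm))
    }
    pd_med[i] <- stats::median(pd_r)
    qe_med[i] <- stats::median(qe_r)
  }
  list(PD = new_diversity_series(region, "PD", yrs, pd_med, n_rep, seed),
       QEphy = new_diversity_series(region, "QEphy", yrs, qe_med, n_rep,
                                    seed))
}

#' Bind diversity series into a tidy table
#' @param series a list of `diversity_series`.
#' @return data frame with columns region, year, metric, value, n_rep, seed.
#' @export
series_table <- function(series) {
  do.call(rbind, lapply(series, function(s)
    data.frame(region = attr(s, "region"), year = s$year,
               metric = attr(s, "metric"), value = s$value,
               n_rep = attr(s, "n_rep"), seed = attr(s, "seed"),
               stringsAsFactors = FALSE)))
}

#' Write a tidy diversity table
#' @param series list of `diversity_series`.
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_series_table <- function(series, path) {
  utils::write.table(series_table(series), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
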