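test_that("Bray-Curtis matches hand values and the brute-force oracle", {
  expect_equal(bray_curtis(c(a = 3, b = 2), c(a = 3, b = 2)), 0)
  expect_equal(bray_curtis(c(a = 5), c(b = 9)), 1)
  expect_equal(bray_curtis(c(a = 6, b = 2), c(a = 2, b = 2)), 4 / 12)
  expect_error(bray_curtis(c(a = 0), c(b = 0)), "undefined-value")
  set.seed(31)
  for (i in 1:20) {
    x <- random_community(sample(2:10, 1))
    y <- random_community(sample(2:10, 1))
    bc <- bray_curtis(x, y)
    expect_equal(bc, bf_bray(x, y), tolerance = 1e-12)
    expect_gte(bc, 0)
    expect_lte(bc, 1)
    perm <- sample(length(x))
    expect_equal(bray_curtis(x[perm], y), bc, tolerance = 1e-12)
  }
})

test_that("the dissimilarity matrix agrees with pairwise values and ignores row order", {
  df <- data.frame(region = rep(c("a", "b"), each = 2),
                   year = 1990L, group = c("w", "m", "w", "r"),
                   area = c(6, 2, 2, 2))
  dm <- dissimilarity_matrix(as_crop_panel(df))
  m <- as.matrix(dm)
  expect_equal(m[1, 2],
               bray_curtis(community(as_crop_panel(df), "a", 1990),
                           community(as_crop_panel(df), "b", 1990)))
  dm2 <- dissimilarity_matrix(as_crop_panel(df[c(3, 1, 4, 2), ]))
  expect_equal(as.matrix(dm2), m)
  keys <- dist_keys(dm)
  expect_equal(keys$region, c("a", "b"))
})

test_that("empty communities are excluded from the matrix with a warning", {
  df <- data.frame(region = c("a", "a", "b"), year = c(1990L, 1991L, 1990L),
                   group = "w", area = c(5, 0, 3))
  expect_warning(dm <- dissimilarity_matrix(as_crop_panel(df)), "empty")
  expect_equal(nrow(dist_keys(dm)), 2L)
})

test_that("NMDS embeds an embeddable configuration with near-zero stress", {
  pts <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0), c(0.5, 0.5),
               c(0.2, 0.8))
  d <- stats::dist(pts)
  d <- d / max(d)
  res <- suppressWarnings(nmds(d, k = 2, restarts = 10, seed = 4))
  expect_lt(res$stress, 1e-3)
  expect_equal(dim(res$coordinates), c(6L, 2L))
})

test_that("more NMDS restarts never increase the best stress", {
  set.seed(41)
  m <- matrix(rlnorm(20 * 8), 20, 8)
  d <- vegan::vegdist(m, "bray")
  s1 <- suppressWarnings(nmds(d, restarts = 2, seed = 7))$stress
  s2 <- suppressWarnings(nmds(d, restarts = 8, seed = 7))$stress
  expect_lte(s2, s1 + 1e-8)
  expect_error(nmds(stats::as.dist(matrix(0.5, 4, 4) - diag(0.5, 4)),
                    seed = 1),
               "degenerate")
})

test_that("NMDS separates well-separated region clusters", {
  set.seed(42)
  base1 <- rlnorm(12, 3, 0.2)
  base2 <- rlnorm(12, 3, 0.2)
  m <- rbind(t(sapply(1:6, function(i)
    c(base1 * runif(12, 0.9, 1.1), rep(0, 12)))),
    t(sapply(1:6, function(i)
      c(rep(0, 12), base2 * runif(12, 0.9, 1.1)))))
  d <- vegan::vegdist(m, "bray")
  res <- suppressWarnings(nmds(d, restarts = 5, seed = 2))
  co <- res$coordinates
  within <- c(stats::dist(co[1:6, ]), stats::dist(co[7:12, ]))
  between <- as.matrix(stats::dist(co))[1:6, 7:12]
  expect_gte(mean(between > max(within)), 0.95)
})

test_that("PERMANOVA partitions a hand-computable design exactly", {
  # two groups of 3 identical samples; within BC = 0, between = 1
  m <- rbind(matrix(rep(c(5, 0), each = 3), 3, 2),
             matrix(rep(c(0, 7), each = 3), 3, 2))
  d <- vegan::vegdist(m, "bray")
  keys <- data.frame(region = rep(c("A", "B"), each = 3),
                     year = rep(1961:1963, 2))
  tab <- permanova(d, keys = keys, permutations = 99, seed = 1,
                   terms = "region")
  expect_equal(tab$r2[tab$term == "region"], 1, tolerance = 1e-10)
  expect_equal(tab$SS[tab$term == "Residual"], 0, tolerance = 1e-10)
  expect_equal(sum(tab$r2[!tab$term %in% "Total"]), 1, tolerance = 1e-10)
})

test_that("single-level factors contribute zero sums of squares", {
  set.seed(43)
  m <- matrix(rlnorm(12 * 5), 12, 5)
  d <- vegan::vegdist(m, "bray")
  keys <- data.frame(region = "only", year = rep(1961:1966, 2))
  tab <- permanova(d, keys = keys, permutations = 49, seed = 1,
                   terms = c("region", "year"))
  expect_equal(tab$SS[tab$term == "region"], 0)
  expect_equal(tab$r2[tab$term == "region"], 0)
  expect_true("year" %in% tab$term)
})

test_that("PERMANOVA r-squared values always partition to one", {
  set.seed(44)
  sim <- generate_panel(scenario_spec(n_regions = 4, years = 1961:1975,
                                      n_groups = 40,
                                      base_richness_range = c(10, 20),
                                      truncated_region = FALSE, seed = 3))
  dm <- dissimilarity_matrix(sim$panel)
  tab <- permanova(dm, permutations = 49, seed = 9)
  expect_equal(sum(tab$r2[tab$term != "Total"]), 1, tolerance = 1e-10)
  expect_true(all(tab$SS >= -1e-12))
})

test_that("within-year pair counts follow the truncation identity", {
  sim <- generate_panel(scenario_spec(n_regions = 5, years = 1961:1970,
                                      n_groups = 30,
                                      base_richness_range = c(8, 15),
                                      truncated_region = TRUE,
                                      truncated_start = 1966, seed = 5))
  dm <- dissimilarity_matrix(sim$panel)
  pairs <- within_year_pairs(dm)
  # 5 years with 4 regions, 5 years with 5 regions
  expect_equal(nrow(pairs), 5 * choose(4, 2) + 5 * choose(5, 2))
  expect_true(all(pairs$region_i != pairs$region_j))
})

test_that("identical regional crops give a flat zero dissimilarity trend", {
  df <- expand.grid(region = c("a", "b", "c"), year = 1961:1970,
                    group = c("w", "m"), stringsAsFactors = FALSE)
  df$area <- ifelse(df$group == "w", 10, 5)  # same everywhere
  dm <- dissimilarity_matrix(as_crop_panel(df))
  tr <- similarity_trend(dm)
  expect_true(all(tr$pairs$bc == 0))
  expect_equal(tr$linear$slope, 0, tolerance = 1e-12)
})
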