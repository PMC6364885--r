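test_that("noiseless panels reproduce their piecewise richness trajectory exactly", {
  traj <- data.frame(region = "region01", a = 20, b = 0, c = 2, d = -2,
                     psi1 = 1980, psi2 = 1990)
  spec <- scenario_spec(n_regions = 1, years = 1961:2014, n_groups = 60,
                        noise_sd = 0, truncated_region = FALSE,
                        trajectories = traj, seed = 8)
  sim <- generate_panel(spec)
  s <- alpha_series(sim$panel, "region01", "SR")
  expect_equal(s$value,
               piecewise_curve(1961:2014, 20, 0, 2, -2, 1980, 1990))
})

test_that("trajectories beyond the pool raise a spec error", {
  traj <- data.frame(region = "region01", a = 50, b = 0, c = 5, d = -5,
                     psi1 = 1970, psi2 = 2000)
  spec <- scenario_spec(n_regions = 1, n_groups = 60, noise_sd = 0,
                        truncated_region = FALSE, trajectories = traj,
                        seed = 8)
  expect_error(generate_panel(spec), "spec error")
})

test_that("the truncated region has no records before its start year", {
  sim <- generate_panel(scenario_spec(n_regions = 3, n_groups = 60,
                                      base_richness_range = c(10, 20),
                                      truncated_start = 1992L, seed = 2))
  p <- sim$panel
  expect_equal(min(panel_years(p, "region03")), 1992L)
  expect_equal(min(panel_years(p, "region01")), 1961L)
  expect_equal(panel_years(p, "region03"), 1992:2014)
})

test_that("generation is byte-deterministic in the seed", {
  spec <- scenario_spec(n_regions = 3, n_groups = 40,
                        base_richness_range = c(10, 18), seed = 33)
  a <- generate_panel(spec)
  b <- generate_panel(spec)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    a$panel,
    generate_panel(scenario_spec(n_regions = 3, n_groups = 40,
                                 base_richness_range = c(10, 18),
                                 seed = 34))$panel))
  expect_true(all(a$panel$area > 0))
})

test_that("generated maps cover the pool and carry multi-species groups", {
  map <- generate_group_map(100, multi_frac = 0.2, seed = 4)
  expect_length(map, 100L)
  expect_equal(sum(lengths(map) > 1), 20L)
  expect_true(all(lengths(map) >= 1))
  sp <- unlist(map)
  expect_false(anyDuplicated(sp) > 0)
})

test_that("generated trees expose exact calibrations and true branch sums", {
  tg <- generate_tree(30, root_age = 120, dated_fraction = 1, seed = 16)
  redated <- bladj_date(undate(tg$tree), tg$age_table)
  expect_equal(redated$ages, tg$tree$ages, tolerance = 1e-12)
  expect_equal(total_branch_length(tg$tree, tg$tree$phy$tip.label),
               sum(tg$tree$phy$edge.length), tolerance = 1e-9)

  tg0 <- generate_tree(20, root_age = 80, dated_fraction = 0, seed = 17)
  expect_length(tg0$age_table, 1L)  # root only
  rd <- bladj_date(undate(tg0$tree), tg0$age_table)
  internal <- rd$ages[-(1:20)]
  expect_true(all(internal > 0 & internal <= 80))
  e <- rd$phy$edge
  expect_true(all(rd$ages[e[, 1]] > rd$ages[e[, 2]]))
})

test_that("piecewise fits on generated noisy richness recover the onset", {
  hits <- 0L
  n_runs <- 40L
  for (s in seq_len(n_runs)) {
    traj <- data.frame(region = "region01", a = 30, b = 0, c = 2, d = -2,
                       psi1 = 1979, psi2 = 1989)
    spec <- scenario_spec(n_regions = 1, n_groups = 90, noise_sd = 1,
                          truncated_region = FALSE, trajectories = traj,
                          seed = 1000 + s)
    sim <- generate_panel(spec)
    s_sr <- alpha_series(sim$panel, "region01", "SR")
    f <- tryCatch(fit_piecewise2(s_sr), error = function(e) NULL)
    if (!is.null(f) && abs(f$psi[1] - 1979) <= 1.5) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.9)
})

test_that("homogenization panels converge crop pools across the window", {
  spec <- scenario_spec(n_regions = 6, n_groups = 60,
                        base_richness_range = c(25, 35),
                        truncated_region = FALSE, noise_sd = 0.5, seed = 12)
  hom <- generate_homogenization_panel(spec, window = c(1983, 1992))
  dm <- dissimilarity_matrix(hom$panel)
  pairs <- within_year_pairs(dm)
  first <- pairs$bc[pairs$year == 1961]
  last <- pairs$bc[pairs$year == 2014]
  expect_lt(mean(last), mean(first))
  expect_lt(max(last), min(first) + 1e-9)

  # zero-length window with flat richness: pools are static, trend is flat
  traj0 <- data.frame(region = sprintf("region%02d", 1:6), a = 30, b = 0,
                      c = 0, d = 0, psi1 = 1980, psi2 = 1990)
  spec0 <- scenario_spec(n_regions = 6, n_groups = 60, noise_sd = 0,
                         truncated_region = FALSE, trajectories = traj0,
                         seed = 12)
  hom0 <- generate_homogenization_panel(spec0, window = c(1961, 1961))
  dm0 <- dissimilarity_matrix(hom0$panel)
  tr0 <- similarity_trend(dm0)
  expect_lt(abs(tr0$linear$slope), 1e-3)
  expect_error(generate_homogenization_panel(spec, window = c(1950, 1990)),
               "spec error")
})

test_that("the similarity trend brackets the true convergence window", {
  spec <- scenario_spec(n_regions = 8, n_groups = 80,
                        base_richness_range = c(30, 40),
                        truncated_region = FALSE, noise_sd = 1, seed = 19)
  hom <- generate_homogenization_panel(spec, window = c(1983, 1992))
  tr <- similarity_trend(dissimilarity_matrix(hom$panel))
  expect_lt(tr$linear$slope, 0)
  pw <- tr$piecewise
  expect_s3_class(pw, "piecewise_fit")
  mid <- mean(c(1983, 1992))
  expect_lte(abs(mean(pw$psi) - mid), 2)
})

test_that("scenario artifacts round-trip through the file readers", {
  spec <- scenario_spec(n_regions = 2, n_groups = 25,
                        base_richness_range = c(8, 12),
                        truncated_region = FALSE, seed = 6)
  sim <- generate_panel(spec)
  map <- generate_group_map(25, seed = 7)
  tg <- generate_tree(length(unique(unlist(map))), 100, 0.5, seed = 8)
  dir <- withr::local_tempdir()
  paths <- write_scenario(sim, map, tg, dir)
  p2 <- read_panel(paths[["panel"]])
  expect_equal(nrow(p2), nrow(sim$panel))
  expect_equal(community(p2, "region01", 1970),
               community(sim$panel, "region01", 1970),
               tolerance = 1e-12)
  map2 <- read_group_map(paths[["mapping"]])
  expect_identical(map2, map[order(names(map))])
  t2 <- read_newick(paths[["tree"]])
  expect_identical(sort(t2$phy$tip.label), sort(tg$tree$phy$tip.label))
  ages2 <- read_ages(paths[["ages"]])
  expect_equal(ages2, tg$age_table, tolerance = 1e-6)
})
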