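test_that("species richness counts positive abundances only", {
  expect_equal(species_richness(numeric(0)), 0L)
  expect_equal(species_richness(c(a = 100, b = 0, c = 3)), 2L)
  set.seed(1)
  comm <- random_community(9)
  expect_equal(species_richness(comm), species_richness(comm * 1000))
  expect_equal(species_richness(comm), species_richness(rev(comm)))
})

test_that("Gini-Simpson diversity matches hand values and vegan", {
  expect_equal(simpson_diversity(c(wheat = 42)), 0)
  expect_equal(simpson_diversity(c(a = 7, b = 7)), 0.5)
  expect_equal(simpson_diversity(c(a = 10, b = 30, c = 60)), 0.54)
  expect_error(simpson_diversity(numeric(0)), "undefined-value")
  set.seed(2)
  for (i in 1:20) {
    comm <- random_community(sample(2:12, 1))
    expect_equal(simpson_diversity(comm), bf_simpson(comm),
                 tolerance = 1e-12)
    expect_equal(simpson_diversity(comm),
                 unname(vegan::diversity(comm, index = "simpson")),
                 tolerance = 1e-12)
    expect_equal(simpson_diversity(comm), simpson_diversity(comm * 3.7),
                 tolerance = 1e-12)
  }
})

test_that("Faith PD under an assignment uses set semantics", {
  dt <- fixture_tree()
  map <- list(g1 = "A", g2 = "B", g3 = c("A", "C"))
  comm <- c(g1 = 10, g2 = 5)
  draw <- c(g1 = "A", g2 = "B")
  expect_equal(faith_pd(dt, comm, map, draw), 15)
  # single group: root-path length of its species
  expect_equal(faith_pd(dt, c(g1 = 3), map, c(g1 = "A")), 10)
  # two groups resolving to the same species count it once
  expect_equal(faith_pd(dt, c(g1 = 1, g3 = 1), map, c(g1 = "A", g3 = "A")),
               10)
  expect_error(faith_pd(dt, comm, map, c(g1 = "A")), "every present group")
})

test_that("Rao QE matches hand values and pools duplicate species areas", {
  dt <- fixture_tree()
  map <- list(g1 = "A", g2 = "B", g3 = "C", g4 = c("A", "B"))
  expect_equal(rao_qe(dt, c(g1 = 5), map, c(g1 = "A")), 0)
  # two species, equal areas, d = 10 -> 2 * 0.25 * 10 = 5
  expect_equal(rao_qe(dt, c(g1 = 7, g2 = 7), map,
                      c(g1 = "A", g2 = "B")), 5)
  # star tree: three species, equal areas, all pairwise distance delta
  delta <- 100
  st <- star_tree(3, delta / 2)
  mp <- list(h1 = "t1", h2 = "t2", h3 = "t3")
  expect_equal(rao_qe(st, c(h1 = 1, h2 = 1, h3 = 1), mp,
                      c(h1 = "t1", h2 = "t2", h3 = "t3")),
               delta * 2 / 3)
  # duplicate draw pools areas: groups g1+g4 both on A, against B
  qe <- rao_qe(dt, c(g1 = 5, g2 = 10, g4 = 5), map,
               c(g1 = "A", g2 = "B", g4 = "A"))
  expect_equal(qe, 2 * (10 / 20) * (10 / 20) * 10)
})

test_that("QE on a star tree ties analytically to Gini-Simpson", {
  set.seed(3)
  r <- 40
  st <- star_tree(6, r)
  comm <- random_community(6, taxa = paste0("t", 1:6))
  map <- as.list(names(comm))
  names(map) <- paste0("g", 1:6)
  draw <- unlist(map)
  qe <- rao_qe(st, stats::setNames(as.numeric(comm), names(map)), map, draw)
  expect_equal(qe, (1 - sum((comm / sum(comm))^2)) * 2 * r,
               tolerance = 1e-12)
  pd <- faith_pd(st, stats::setNames(as.numeric(comm), names(map)), map,
                 draw)
  expect_equal(pd, 6 * r)
})

test_that("PD and QE match picante on random fixtures", {
  for (s in 1:3) {
    tg <- generate_tree(20, root_age = 90, dated_fraction = 1, seed = s)
    dt <- tg$tree
    set.seed(s)
    taxa <- sample(dt$phy$tip.label, 8)
    cm <- matrix(1, 1, 8, dimnames = list("s", taxa))
    expect_equal(total_branch_length(dt, taxa),
                 picante::pd(cm, dt$phy, include.root = TRUE)$PD,
                 tolerance = 1e-9)
  }
})

test_that("randomization collapses when groups are single-species", {
  dt <- fixture_tree()
  map <- list(g1 = "A", g2 = "B")
  panel <- as_crop_panel(expand.grid(
    region = "r1", year = 1961:1970, group = c("g1", "g2"), area = 10,
    stringsAsFactors = FALSE))
  rs <- randomized_series(panel, "r1", dt, map, n_rep = 5, seed = 9)
  expect_true(all(rs$PD$value == 15))
  expect_true(all(rs$QEphy$value == rao_qe(dt, c(g1 = 10, g2 = 10), map,
                                           c(g1 = "A", g2 = "B"))))
  expect_equal(attr(rs$PD, "metric"), "PD")
})

test_that("randomized medians are reproducible and bracketed by the attainable values", {
  dt <- fixture_tree()
  map <- list(g1 = "A", g2 = c("B", "C"))  # one two-species group
  panel <- as_crop_panel(data.frame(region = "r1", year = 1961,
                                    group = c("g1", "g2"),
                                    area = c(10, 20)))
  # exhaustive enumeration of both assignments
  pd_ab <- faith_pd(dt, c(g1 = 10, g2 = 20), map, c(g1 = "A", g2 = "B"))
  pd_ac <- faith_pd(dt, c(g1 = 10, g2 = 20), map, c(g1 = "A", g2 = "C"))
  rs <- randomized_series(panel, "r1", dt, map, n_rep = 1000, seed = 4)
  expect_gte(rs$PD$value, min(pd_ab, pd_ac))
  expect_lte(rs$PD$value, max(pd_ab, pd_ac))
  rs2 <- randomized_series(panel, "r1", dt, map, n_rep = 1000, seed = 4)
  expect_identical(rs$PD$value, rs2$PD$value)
  expect_identical(rs$QEphy$value, rs2$QEphy$value)
  # median of two replicates is their midpoint
  rs3 <- randomized_series(panel, "r1", dt, map, n_rep = 2, seed = 11)
  set.seed(11)
  expect_true(rs3$PD$value %in%
                c(pd_ab, pd_ac, (pd_ab + pd_ac) / 2))
})

test_that("QE is zero whenever richness is one, and RAO/PD agree with brute force", {
  set.seed(12)
  for (s in 1:6) {
    tg <- generate_tree(15, root_age = 60, dated_fraction = 1, seed = s)
    dt <- tg$tree
    k <- sample(2:8, 1)
    sp <- sample(dt$phy$tip.label, k)
    areas <- runif(k, 1, 50)
    map <- as.list(sp)
    names(map) <- paste0("g", seq_len(k))
    comm <- stats::setNames(areas, names(map))
    draw <- stats::setNames(sp, names(map))
    expect_equal(rao_qe(dt, comm, map, draw), bf_rao(dt, sp, areas),
                 tolerance = 1e-9)
    expect_equal(faith_pd(dt, comm, map, draw), bf_pd(dt, sp),
                 tolerance = 1e-9)
  }
  dt <- fixture_tree()
  expect_equal(rao_qe(dt, c(g = 5), list(g = "B"), c(g = "B")), 0)
})

test_that("taxonomic series cover the region years in order", {
  sim <- generate_panel(scenario_spec(n_regions = 2, years = 1961:1980,
                                      n_groups = 30,
                                      base_richness_range = c(10, 15),
                                      truncated_region = TRUE,
                                      truncated_start = 1971, seed = 21))
  s <- alpha_series(sim$panel, "region02", "SR")
  expect_equal(s$year, 1971:1980)
  expect_true(all(diff(s$year) > 0))
  sd_series <- alpha_series(sim$panel, "region01", "SD")
  expect_true(all(sd_series$value >= 0 & sd_series$value < 1))
  expect_error(alpha_series(sim$panel, "region99"), "lookup error")
})
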