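test_that("histogram densities integrate to one", {
  h <- volume_density_histogram(rep(42, 10), bin_width = 5)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(sum(h$density * diff(h$breaks)), 1, tolerance = 1e-12)
  h2 <- volume_density_histogram(c(10, 12, 14, 40, 90, 200),
                                 bin_width = 7)
  expect_equal(sum(h2$density * diff(h2$breaks)), 1, tolerance = 1e-12)
  hp <- volume_density_histogram(c(10, 12, 14, 40, 90, 2000),
                                 bin_width = 7, peak_region = TRUE)
  expect_equal(sum(hp$density * diff(hp$breaks)), 1, tolerance = 1e-12)
  expect_error(volume_density_histogram(numeric(0)), "no volumes")
})

test_that("the peak-region domain is [0, mean + 2 sd] of the full sample", {
  v <- c(80, 90, 100, 110, 120)
  h <- volume_density_histogram(v, bin_width = 10, peak_region = TRUE)
  expect_equal(h$peak_region_domain, c(0, mean(v) + 2 * sd(v)))
  # values outside the domain are excluded before binning
  v2 <- c(rep(100, 20), 1e5)
  h2 <- volume_density_histogram(v2, bin_width = 50, peak_region = TRUE)
  expect_equal(h2$n, 20)
  expect_lte(max(h2$breaks), h2$peak_region_domain[2] + 50)
})

test_that("clustering metrics count the 2x unit-volume rule", {
  m <- clustering_metrics(c(100, 100, 500), unit_volume = 100)
  expect_equal(m$singleton_fraction, 2 / 3)
  expect_equal(m$cluster_fraction, 1 / 3)
  expect_equal(m$singleton_fraction + m$cluster_fraction, 1)
  expect_equal(m$cells_per_object, c(1, 1, 5))
  all_single <- clustering_metrics(c(50, 60, 70), unit_volume = 100)
  expect_equal(all_single$singleton_fraction, 1)
  expect_true(is.na(all_single$mean_cluster_volume))
  expect_error(clustering_metrics(numeric(0)), "no objects")
})

test_that("metrics are invariant to a common volume rescaling", {
  v <- c(90, 110, 130, 350, 800)
  m1 <- clustering_metrics(v, unit_volume = 100)
  m2 <- clustering_metrics(v * 7.5, unit_volume = 750)
  expect_equal(m1$singleton_fraction, m2$singleton_fraction)
  expect_equal(m1$cluster_fraction, m2$cluster_fraction)
  expect_equal(m1$cells_per_object, m2$cells_per_object)
})

test_that("condition comparison orders metrics and validates inputs", {
  a <- clustering_metrics(c(100, 100, 500, 600), unit_volume = 100)
  b <- clustering_metrics(c(100, 100, 100, 500), unit_volume = 100)
  cmp <- compare_conditions(list(control = a, treated = b))
  expect_equal(cmp$condition, c("control", "treated"))
  expect_equal(cmp$cluster_fraction_diff, c(0, 0.25 - 0.5))
  same <- compare_conditions(list(control = a, treated = a))
  expect_equal(same$cluster_fraction_diff, c(0, 0))
  expect_error(compare_conditions(list(control = a)), "at least 2")
  expect_error(compare_conditions(list(
    control = list(d3 = a, d7 = b), treated = list(d3 = a))),
    "day")
})

test_that("cluster fraction recovers the planted composition", {
  sim <- simulate_stack(fixture_glass_spec(seed = 5))
  cr <- crop_stack(sim$stack)
  seg <- segment_stack(cr$stack)
  unit <- 33 * voxel_volume(sim$stack)
  m <- clustering_metrics(seg$table, unit_volume = unit)
  # 10 singletons + 5 four-cell clusters: fraction 5/15, within 1 object
  expect_equal(m$n_objects, 15)
  expect_lte(abs(m$n_clusters - 5), 1)
  expect_lte(abs(m$cluster_fraction - 5 / 15), 1 / 15)
})

test_that("more planted clusters never lowers the cluster fraction", {
  frac_for <- function(n_clusters, seed) {
    spec <- stack_spec(shape_zyx = c(24, 96, 96), n_singletons = 8,
                       n_clusters = n_clusters,
                       cells_per_cluster = c(4, 4),
                       noise = list(sd = 2, background = 8), seed = seed)
    seg <- segment_stack(simulate_stack(spec)$stack)
    clustering_metrics(seg$table,
                       unit_volume = 33 * 2)$cluster_fraction
  }
  wins <- sapply(1:5, function(s)
    frac_for(4, s) >= frac_for(1, s))
  expect_gte(sum(wins), 3)   # majority over seeds
})
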