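test_that("Otsu separates a two-level image at the exhaustive optimum", {
  v <- c(rep(0, 50), rep(200, 50))
  t <- otsu_threshold(v)
  expect_true(t >= 0 && t < 200)
  expect_equal(sum(v > t), 50)
  expect_equal(as.numeric(t), oracle_otsu_8bit(v))
  # minimal two-point case
  v2 <- c(rep(10, 7), rep(11, 3))
  expect_equal(as.numeric(otsu_threshold(v2)), 10)
  expect_equal(sum(v2 > otsu_threshold(v2)), 3)
  expect_error(otsu_threshold(rep(5, 10)), "degenerate")
})

test_that("Otsu equals exhaustive between-class-variance maximization", {
  for (s in 1:25) {
    v <- random_stack_array(c(4, 8, 8), seed = s)
    expect_equal(as.numeric(otsu_threshold(v)), oracle_otsu_8bit(v))
  }
})

test_that("3D labeling handles cubes, gaps and diagonal adjacency", {
  m <- array(0L, c(7, 7, 7))
  m[2:4, 2:4, 2:4] <- 1L
  res <- label_components_3d(m)
  expect_equal(nrow(res$table), 1)
  expect_equal(res$table$voxels, 27)
  expect_equal(unlist(res$table[1, c("z", "y", "x")]),
               c(z = 3, y = 3, x = 3))
  m[2:3, 6:7, 6:7] <- 1L        # second cube, > 1 voxel away
  res <- label_components_3d(m)
  expect_equal(nrow(res$table), 2)
  # two voxels touching only at a corner: one object under
  # 26-connectivity, two under 6-connectivity
  dm <- array(0L, c(4, 4, 4))
  dm[1, 1, 1] <- 1L; dm[2, 2, 2] <- 1L
  expect_equal(nrow(label_components_3d(dm, 26)$table), 1)
  expect_equal(nrow(label_components_3d(dm, 6)$table), 2)
})

test_that("labeling agrees with brute-force flood fill", {
  dims_list <- list(c(10, 10, 10), c(14, 9, 11), c(20, 20, 20))
  for (i in seq_along(dims_list)) {
    m <- withr::with_seed(i, array(rbinom(prod(dims_list[[i]]), 1, 0.35),
                                   dims_list[[i]]))
    for (conn in c(26, 6)) {
      got <- label_components_3d(m, conn)
      want <- oracle_flood_fill(m, conn)
      expect_equal(max(got$labels), max(want))
      # same partition up to label permutation
      expect_equal(sort(tabulate(got$labels[got$labels > 0])),
                   sort(tabulate(want[want > 0])))
      agree <- tapply(got$labels[m != 0], want[m != 0],
                      function(g) length(unique(g)))
      expect_true(all(agree == 1))
    }
  }
})

test_that("voxel conservation and volume scaling hold", {
  m <- withr::with_seed(9, array(rbinom(12^3, 1, 0.3), c(12, 12, 12)))
  res <- label_components_3d(m, voxel_size_zyx = c(2, 1, 1))
  expect_equal(sum(res$table$voxels), sum(m))
  expect_equal(res$table$volume_um3, res$table$voxels * 2)
})

test_that("object filtering applies the size and edge rules", {
  m <- array(0L, c(12, 12, 12))
  m[2, 2, 2:10] <- 1L           # 9 voxels -> removed at min 10
  m[5, 5, 2:11] <- 1L           # 10 voxels -> retained
  m[8:9, 8:9, 8:10] <- 1L       # 12 voxels, interior
  res <- label_components_3d(m)
  kept <- filter_objects(res$table, min_voxels = 10,
                         exclude_edges = FALSE)
  expect_equal(sort(kept$voxels), c(10, 12))
  m[1, 1:4, 1:4] <- 1L          # 16 voxels on the z = 1 face
  res <- label_components_3d(m)
  with_edges <- filter_objects(res$table, 10, exclude_edges = FALSE)
  no_edges <- filter_objects(res$table, 10, exclude_edges = TRUE)
  expect_equal(nrow(with_edges) - nrow(no_edges), 1)
  expect_equal(nrow(filter_objects(res$table[0, ], 10)), 0)
  # raising min_voxels never adds objects
  counts <- sapply(c(1, 5, 10, 13, 20), function(mv)
    nrow(filter_objects(res$table, mv, FALSE)))
  expect_true(all(diff(counts) <= 0))
})

test_that("masked stacks round-trip to the same object table", {
  sim <- simulate_stack(fixture_singleton_spec(n = 5, seed = 6))
  seg <- segment_stack(sim$stack)
  relab <- label_components_3d(seg$masked,
                               voxel_size_zyx = sim$stack$voxel_size_zyx)
  expect_equal(sort(relab$table$voxels), sort(seg$table$voxels))
  empty <- masked_stack(array(0L, c(3, 3, 3)),
                        data.frame(id = integer(0)))
  expect_true(all(empty == 0))
})

test_that("segmentation recovers non-overlapping singletons exactly", {
  for (s in 1:5) {
    sim <- simulate_stack(fixture_singleton_spec(n = 8, seed = s))
    seg <- segment_stack(sim$stack)
    expect_equal(nrow(seg$table), 8)
    # digital sphere radius 2 = 33 voxels; tolerate a 1-voxel shell
    expect_true(all(abs(seg$table$voxels - 33) <= 15))
  }
})
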