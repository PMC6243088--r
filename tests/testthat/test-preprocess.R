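test_that("partition_grid tiles bounds with clipped edge blocks", {
  g <- partition_grid(list(offset = c(0L, 0L, 0L), shape = c(64L, 64L, 64L)),
                      c(32L, 32L, 32L))
  expect_equal(nrow(g$blocks), 8L)
  expect_true(all(g$blocks[, c(nz, ny, nx)] == 32L))

  g2 <- partition_grid(list(offset = c(0L, 0L, 0L), shape = c(40L, 40L, 40L)),
                       c(32L, 32L, 32L))
  expect_equal(nrow(g2$blocks), 8L)
  clipped <- with(g2$blocks, nz < 32L | ny < 32L | nx < 32L)
  expect_equal(sum(clipped), 7L)
  # block shapes cover the bounds exactly
  expect_equal(sum(g2$blocks$nz * g2$blocks$ny * g2$blocks$nx), 40L^3)

  g3 <- partition_grid(list(offset = c(0L, 0L, 0L), shape = c(10L, 10L, 10L)),
                       c(64L, 64L, 64L))
  expect_equal(nrow(g3$blocks), 1L)
  expect_equal(unlist(g3$blocks[1, c("nz", "ny", "nx")], use.names = FALSE),
               c(10L, 10L, 10L))
  expect_error(partition_grid(list(offset = c(0L, 0L, 0L), shape = c(0L, 4L, 4L)),
                              c(2L, 2L, 2L)), "empty")
})

test_that("local connected components split disconnected islands per label", {
  # two islands of label 4 far apart
  a <- array(0L, dim = c(5, 5, 5))
  a[1:2, 1, 1] <- 4L
  a[5, 5, 5] <- 4L
  cc <- local_connected_components(label_volume(a))
  expect_equal(nrow(cc$provenance), 2L)
  expect_equal(unique(cc$provenance$orig), 4L)
  expect_equal(length(unique_labels(cc$volume)), 2L)

  # diagonal contact is not 6-connected
  b <- array(0L, dim = c(3, 3, 1))
  b[1, 1, 1] <- 2L
  b[2, 2, 1] <- 2L
  cc2 <- local_connected_components(label_volume(b))
  expect_equal(nrow(cc2$provenance), 2L)

  # already-connected labels: relabeling is an isomorphism
  v <- tiny_volumes()$G
  cc3 <- local_connected_components(v)
  expect_true(same_partition(as.vector(v$data), as.vector(cc3$volume$data)))
})

test_that("global connected components join across blocks only through the ROI", {
  # one segment spanning two blocks -> one final label
  a <- array(0L, dim = c(8, 4, 4))
  a[2:7, 2, 2] <- 9L
  grid <- partition_grid(list(offset = c(0L, 0L, 0L), shape = c(8L, 4L, 4L)),
                         c(4L, 4L, 4L))
  cc <- connected_components_volume(label_volume(a), grid)
  expect_equal(nrow(cc$provenance), 1L)

  # U-shaped segment whose bend lies outside the ROI: two final labels
  u <- array(0L, dim = c(8, 8, 4))
  u[1:8, 1, 1] <- 7L     # left arm spans both z-blocks
  u[1:8, 8, 1] <- 7L     # right arm too
  u[1, 2:7, 1] <- 7L     # the bend, in low-z blocks only
  gridu <- partition_grid(list(offset = c(0L, 0L, 0L), shape = c(8L, 8L, 4L)),
                          c(4L, 8L, 4L))
  roi <- restrict_grid(gridu, rbind(c(1L, 0L, 0L)))  # keep only the high-z half
  ccu <- connected_components_volume(label_volume(u), roi)
  expect_equal(nrow(ccu$provenance), 2L)
  expect_equal(unique(ccu$provenance$orig), 7L)

  # single-block grid: identity up to renaming
  cc1 <- connected_components_volume(label_volume(a))
  expect_true(same_partition(a, cc1$volume$data))
})

test_that("blockwise connected components reproduce the unpartitioned partition", {
  for (seed in 1:3) {
    v <- rand_volume(c(16, 14, 12), k = 3, seed = seed)
    direct <- conneval:::cc_label6_cpp(as.vector(v$data), dim(v$data))
    for (bs in list(c(8, 8, 8), c(5, 14, 7))) {
      grid <- partition_grid(lv_bounds(v), bs)
      cc <- connected_components_volume(v, grid)
      expect_true(same_partition(direct, as.vector(cc$volume$data)))
      # canonical labels: identical to the single-block run, not just isomorphic
      expect_identical(cc$volume$data,
                       connected_components_volume(v)$volume$data)
    }
  }
})

test_that("boundary dilation erases voxels near other labels, monotonically", {
  strip <- label_volume(array(rep(c(1L, 2L), each = 3), dim = c(6, 1, 1)))
  expect_identical(dilate_gt_boundaries(strip, 0)$data, strip$data)
  expect_equal(as.vector(dilate_gt_boundaries(strip, 1)$data),
               c(1L, 1L, 0L, 0L, 2L, 2L))
  uni <- label_volume(array(4L, dim = c(4, 4, 4)))
  expect_identical(dilate_gt_boundaries(uni, 3)$data, uni$data)
  expect_error(dilate_gt_boundaries(strip, -1), "non-negative")

  v <- rand_volume(c(10, 10, 10), k = 4, seed = 6)
  erased <- function(r) which(v$data != 0L & dilate_gt_boundaries(v, r)$data == 0L)
  e1 <- erased(1); e2 <- erased(2)
  expect_true(all(e1 %in% e2))
})

test_that("sparse filtering masks the test volume to the traced subset", {
  S <- rand_volume(c(6, 6, 6), k = 5, seed = 7)
  G <- rand_volume(c(6, 6, 6), k = 3, seed = 8)
  out <- filter_sparse_bodies(S, G)
  expect_true(all(out$S$data[G$data == 0L] == 0L))
  expect_identical(out$S$data[G$data != 0L], S$data[G$data != 0L])
  dense <- label_volume(array(1L, dim = c(6, 6, 6)))
  expect_identical(filter_sparse_bodies(S, dense)$S$data, S$data)
  none <- label_volume(array(0L, dim = c(6, 6, 6)))
  expect_true(all(filter_sparse_bodies(S, none)$S$data == 0L))
})

test_that("small ground-truth orphans are removed by size", {
  a <- array(0L, dim = c(10, 4, 4))
  a[1:7, 1:4, 1:4] <- 1L    # 112 voxels
  a[9, 1, 1:3] <- 5L        # 3 voxels
  G <- label_volume(a)
  expect_identical(filter_small_orphans_gt(G, 0)$data, a)
  f <- filter_small_orphans_gt(G, 10)
  expect_equal(unique_labels(f), 1L)
  expect_equal(unique_labels(filter_small_orphans_gt(G, 1000)), integer(0))
})

test_that("mode-pooling downsample keeps modal labels with smallest-label ties", {
  v <- rand_volume(c(9, 7, 5), k = 4, seed = 9)
  expect_identical(downsample_labels(v, 1), v)
  blockvals <- array(c(1L, 1L, 1L, 2L, 2L, 2L, 0L, 0L), dim = c(2, 2, 2))
  expect_equal(as.vector(downsample_labels(label_volume(blockvals), 2)$data), 1L)
  uni <- label_volume(array(9L, dim = c(2, 2, 2)))
  expect_equal(as.vector(downsample_labels(uni, 2)$data), 9L)
  d <- downsample_labels(v, 2)
  expect_equal(dim(d$data), as.integer(ceiling(dim(v$data) / 2)))
  expect_equal(d$resolution, v$resolution * 2)
  expect_true(all(unique_labels(d) %in% unique_labels(v)))
  expect_equal(downsample_synapses(
    data.frame(id = "a", pre_z = 5L, pre_y = 4L, pre_x = 3L,
               post_z = 2L, post_y = 1L, post_x = 0L), 2),
    data.frame(id = "a", pre_z = 2L, pre_y = 2L, pre_x = 1L,
               post_z = 1L, post_y = 0L, post_x = 0L))
})
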