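test_that("scene generation is seed-deterministic and autapse-free", {
  sc <- generate_scene(c(32, 32, 32), 15, 100, seed = 42)
  sc2 <- generate_scene(c(32, 32, 32), 15, 100, seed = 42)
  expect_identical(sc, sc2)
  sc3 <- generate_scene(c(32, 32, 32), 15, 100, seed = 43)
  expect_false(identical(sc$ground_truth$data, sc3$ground_truth$data))

  expect_equal(length(unique_labels(sc$ground_truth)), 15L)
  expect_equal(sum(sc$connections$pre_label == sc$connections$post_label), 0L)
  # stored endpoint labels agree with the volume
  expect_equal(label_at(sc$ground_truth,
                        as.matrix(sc$connections[, c("pre_z", "pre_y", "pre_x")])),
               sc$connections$pre_label)
  # every segment is one connected component
  cc <- local_connected_components(sc$ground_truth)
  expect_equal(nrow(cc$provenance), 15L)

  two <- generate_scene(c(8, 8, 8), 2, 5, seed = 1)
  expect_equal(length(unique_labels(two$ground_truth)), 2L)
  expect_error(generate_scene(c(3, 3, 3), 200, 10, seed = 1), "too small")
})

test_that("plane splits raise fragmentation by exactly their count", {
  sc <- generate_scene(c(32, 32, 32), 10, 80, seed = 11)
  expect_identical(corrupt_split(sc, 0, seed = 1), sc)
  for (m in c(1L, 5L)) {
    scm <- corrupt_split(sc, m, seed = 12)
    t <- build_contingency(scm$test, sc$ground_truth)
    expect_equal(frag(t), m)
    expect_equal(length(scm$corruption_log), m)
    # both parts of every cut stay connected
    cc <- local_connected_components(scm$test)
    expect_equal(nrow(cc$provenance), 10L + m)
  }
})

test_that("splits away from synapse-bearing pairs leave connectivity intact", {
  # strip of 3 segments; connections only between segments 1 and 2
  a <- array(rep(1:3, each = 8), dim = c(24, 1, 1))
  G <- label_volume(a)
  syn <- data.frame(id = c("c1", "c2"),
                    pre_z = c(6L, 7L), pre_y = 0L, pre_x = 0L,
                    post_z = c(8L, 9L), post_y = 0L, post_x = 0L,
                    stringsAsFactors = FALSE)
  S <- G
  S$data[20:24] <- 4L   # split segment 3, which bears no synapse
  tep <- build_contingency(S, G, "synapse_endpoints",
                           points = conneval:::synapse_endpoints(syn))
  A <- match_segments(tep)
  expect_equal(connectivity_correctness(connection_graph(S, syn),
                                        connection_graph(G, syn), A), 1)
})

test_that("false merges require adjacency and are logged", {
  sc <- generate_scene(c(24, 24, 24), 8, 40, seed = 31)
  expect_identical(corrupt_merge(sc, matrix(integer(), ncol = 2)), sc)
  faces <- conneval:::adjacency_faces(sc$ground_truth$data)
  pair <- c(faces$l1[1], faces$l2[1])
  scm <- corrupt_merge(sc, matrix(pair, ncol = 2))
  expect_equal(length(unique_labels(scm$test)), 7L)
  expect_equal(scm$corruption_log[[1]]$op, "merge")
  # a non-adjacent pair: two labels never sharing a face
  adj <- unique(rbind(as.matrix(faces[, c("l1", "l2")]),
                      as.matrix(faces[, c("l2", "l1")])))
  allp <- expand.grid(a = 1:8, b = 1:8)
  allp <- allp[allp$a < allp$b, ]
  nonadj <- allp[!paste(allp$a, allp$b) %in% paste(adj[, 1], adj[, 2]), ]
  skip_if(nrow(nonadj) == 0, "all segment pairs adjacent in this scene")
  expect_error(corrupt_merge(sc, matrix(c(nonadj$a[1], nonadj$b[1]), ncol = 2)),
               "not face-adjacent")
})

test_that("boundary shifts perturb voxels but not topology or connectivity", {
  sc <- generate_scene(c(32, 32, 32), 12, 100, seed = 51)
  expect_identical(corrupt_boundary_shift(sc, 0, seed = 1), sc)
  scs <- corrupt_boundary_shift(sc, radius = 2, seed = 52)
  t <- build_contingency(scs$test, sc$ground_truth)
  expect_equal(frag(t), 0L)
  expect_gt(vi(t)$total, 0)
  expect_equal(scene_cc(scs), 1)
  # dilation at the shift radius removes the corruption from the voxel domain
  td <- build_contingency(scs$test, dilate_gt_boundaries(sc$ground_truth, 2))
  expect_lt(vi(td)$total, 1e-6)
  # changed voxels all lie inside the dilation band
  changed <- scs$test$data != sc$ground_truth$data
  band <- dilate_gt_boundaries(sc$ground_truth, 2)$data == 0L &
          sc$ground_truth$data != 0L
  expect_true(all(band[changed]))
})

test_that("scenes export to the formats the evaluator reads", {
  sc <- generate_scene(c(16, 16, 16), 5, 20, seed = 61)
  sc <- corrupt_split(sc, 2, seed = 62)
  prefix <- file.path(tempdir(), "scene")
  export_scene(sc, prefix)
  g <- read_label_volume(paste0(prefix, "_gt.zarr"))
  s <- read_label_volume(paste0(prefix, "_test.zarr"))
  syn <- read_synapses(paste0(prefix, "_synapses.json"))
  expect_identical(g$data, sc$ground_truth$data)
  expect_identical(s$data, sc$test$data)
  expect_equal(syn$pre_z, sc$connections$pre_z)
  unlink(paste0(prefix, c("_gt.zarr", "_test.zarr")), recursive = TRUE)
  file.remove(paste0(prefix, c("_synapses.json", "_log.json")))
})
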