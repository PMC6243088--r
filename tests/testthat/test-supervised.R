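test_that("vi matches hand-computed entropies and is symmetric under transpose", {
  t <- tiny_table()
  v <- vi(t)
  expect_equal(v$oversegmentation, 0.5)
  expect_equal(v$undersegmentation, 0)
  expect_equal(v$total, 0.5)

  ident <- build_contingency(tiny_volumes()$G, tiny_volumes()$G)
  vid <- vi(ident)
  expect_equal(vid$total, 0)

  tt <- conneval:::transpose_contingency(t)
  vt <- vi(tt)
  expect_equal(vt$oversegmentation, v$undersegmentation)
  expect_equal(vt$undersegmentation, v$oversegmentation)
  expect_error(vi(empty_contingency()), "no comparison points")
})

test_that("vi and rand_index agree with brute-force oracles on random volumes", {
  for (seed in 1:10) {
    S <- rand_volume(c(6, 5, 4), k = 8, seed = seed)
    G <- rand_volume(c(6, 5, 4), k = 5, seed = seed + 30)
    t <- build_contingency(S, G)
    bv <- brute_vi(as.vector(S$data), as.vector(G$data))
    v <- vi(t)
    expect_equal(v$oversegmentation, bv$over, tolerance = 1e-12)
    expect_equal(v$undersegmentation, bv$under, tolerance = 1e-12)
    expect_equal(rand_index(t),
                 brute_rand(as.vector(S$data), as.vector(G$data)),
                 tolerance = 1e-12)
  }
})

test_that("rand_index matches pair counting and its adjusted form", {
  t <- tiny_table()
  expect_equal(rand_index(t), 24 / 28)
  ident <- build_contingency(tiny_volumes()$G, tiny_volumes()$G)
  expect_equal(rand_index(ident), 1)
  expect_equal(rand_index(ident, adjusted = TRUE), 1)
  one <- build_contingency(label_volume(array(7L, dim = c(2, 2, 2))),
                           label_volume(array(3L, dim = c(2, 2, 2))))
  expect_equal(rand_index(one), 1)
  skip_if_not_installed("mclust")
  for (seed in 1:5) {
    S <- rand_volume(c(5, 5, 4), k = 6, seed = seed)
    G <- rand_volume(c(5, 5, 4), k = 4, seed = seed + 40)
    keep <- S$data != 0L & G$data != 0L
    expect_equal(rand_index(build_contingency(S, G), adjusted = TRUE),
                 mclust::adjustedRandIndex(S$data[keep], G$data[keep]),
                 tolerance = 1e-12)
  }
})

test_that("per-body VI decomposition conserves the summary components", {
  t <- tiny_table()
  d <- body_vi_decomposition(t)
  expect_equal(d, c("1" = 0, "2" = 0.5))
  for (seed in 1:8) {
    S <- rand_volume(c(6, 6, 4), k = 9, seed = seed)
    G <- rand_volume(c(6, 6, 4), k = 5, seed = seed + 60)
    t <- build_contingency(S, G)
    v <- vi(t)
    expect_equal(sum(body_vi_decomposition(t)), v$oversegmentation,
                 tolerance = 1e-10)
    expect_equal(sum(body_vi_decomposition(conneval:::transpose_contingency(t))),
                 v$undersegmentation, tolerance = 1e-10)
    expect_true(all(body_vi_decomposition(t) >= 0))
  }
})

test_that("body under/over scores pick up fragmentation and leakage", {
  t <- tiny_table()
  uo <- body_under_over(t, 2)
  expect_equal(uo$over, 0.5)
  expect_equal(uo$under, 0)
  ident <- build_contingency(tiny_volumes()$G, tiny_volumes()$G)
  expect_equal(body_under_over(ident, 1), list(over = 0, under = 0))
  # S merges both reference bodies into one segment: leakage shows as under > 0
  merged <- build_contingency(label_volume(array(1L, dim = c(2, 2, 2))),
                              tiny_volumes()$G)
  expect_gt(body_under_over(merged, 2)$under, 0)
  expect_error(body_under_over(t, 99), "not present")
})

test_that("greedy matching uses overlap-then-label tie-breaks; optimal dominates", {
  t <- tiny_table()
  A <- match_segments(t, "greedy")
  expect_equal(as.data.frame(A$pairs),
               data.frame(g = c(1L, 2L), s = c(10L, 20L), weight = c(4L, 2L)))
  ident <- build_contingency(tiny_volumes()$G, tiny_volumes()$G)
  Ai <- match_segments(ident)
  expect_equal(Ai$pairs$g, Ai$pairs$s)

  for (seed in 1:6) {
    S <- rand_volume(c(6, 5, 4), k = 8, seed = seed)
    G <- rand_volume(c(6, 5, 4), k = 5, seed = seed + 80)
    t <- build_contingency(S, G)
    wg <- sum(match_segments(t, "greedy")$pairs$weight)
    wo <- sum(match_segments(t, "optimal")$pairs$weight)
    expect_lte(wg, wo)
  }
  # split-only corruption: every test segment within one reference body
  sc <- generate_scene(c(24, 24, 24), 6, 40, seed = 5)
  sc <- corrupt_split(sc, 4, seed = 6)
  ts <- build_contingency(sc$test, sc$ground_truth)
  expect_equal(sum(match_segments(ts, "greedy")$pairs$weight),
               sum(match_segments(ts, "optimal")$pairs$weight))
})

test_that("connection graphs resolve endpoints and drop unresolved ones", {
  toy <- toy_connectivity()
  expect_equal(nrow(toy$Gg$edges), 3L)
  expect_equal(unique(toy$Gg$edges[, c("pre", "post")]),
               data.table::data.table(pre = 1L, post = 2L))
  empty <- connection_graph(toy$S, toy$syn[0, ])
  expect_equal(nrow(empty$edges), 0L)
  # endpoint on background -> unresolved
  Sz <- toy$S
  Sz$data[1] <- 0L
  gz <- connection_graph(Sz, toy$syn)
  expect_equal(gz$unresolved, 1L)
  # all endpoints in one segment -> self-loops
  uni <- label_volume(array(1L, dim = c(6, 1, 1)))
  gu <- connection_graph(uni, toy$syn)
  expect_true(all(gu$edges$pre == gu$edges$post))
})

test_that("connectivity correctness counts preserved connections under assignment", {
  toy <- toy_connectivity()
  expect_equal(connectivity_correctness(toy$Sg, toy$Gg, toy$A), 2 / 3)
  # perfect segmentation
  Gg <- connection_graph(toy$G, toy$syn)
  Ai <- match_segments(build_contingency(toy$G, toy$G))
  expect_equal(connectivity_correctness(Gg, Gg, Ai), 1)
  # false merge: both bodies collapse onto one segment; injectivity kills
  # every connection on the unmatched body
  Sm <- label_volume(array(77L, dim = c(6, 1, 1)))
  Sgm <- connection_graph(Sm, toy$syn)
  Am <- match_segments(build_contingency(Sm, toy$G, "synapse_endpoints",
                       points = conneval:::synapse_endpoints(toy$syn)))
  expect_equal(connectivity_correctness(Sgm, toy$Gg, Am), 0)
  expect_error(connectivity_correctness(toy$Sg, connection_graph(toy$S, toy$syn[0, ]),
                                        toy$A), "no ground-truth")
})

test_that("thresholded connectivity splits into recall and precision", {
  toy <- toy_connectivity()
  r <- cc_thresholded(toy$Sg, toy$Gg, toy$A, k = 0)
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 0.5)
  # k above every pair weight: undefined, not zero
  r9 <- cc_thresholded(toy$Sg, toy$Gg, toy$A, k = 99)
  expect_true(is.na(r9$recall) && is.na(r9$precision))
  # inclusive threshold counts pairs at exactly k
  r3 <- cc_thresholded(toy$Sg, toy$Gg, toy$A, k = 3, inclusive = TRUE)
  expect_equal(r3$recall, 0)  # the (1,2) path has 3 connections, only 2 preserved
  ident <- match_segments(build_contingency(toy$G, toy$G))
  Gg <- toy$Gg
  expect_equal(cc_thresholded(Gg, Gg, ident, k = 2), list(recall = 1, precision = 1))
})

test_that("fragmentation counts excess segments, thresholded by completeness", {
  t <- tiny_table()
  expect_equal(frag(t), 1L)
  ident <- build_contingency(tiny_volumes()$G, tiny_volumes()$G)
  expect_equal(frag(ident), 0L)
  expect_equal(frag(conneval:::transpose_contingency(t)), -1L)

  sizes <- c(a = 50, b = 30, c = 10, d = 5, e = 5)
  expect_equal(segments_to_threshold(sizes, 75), 2L)
  expect_equal(segments_to_threshold(sizes, 90), 3L)
  expect_equal(segments_to_threshold(sizes, 100), 5L)
  expect_equal(segments_to_threshold(c(x = 10), 50), 1L)
  expect_error(segments_to_threshold(sizes, 0), "percent")
  expect_error(segments_to_threshold(sizes, 101), "percent")
  ft <- frag_thresholded(sizes, c(g1 = 80, g2 = 20), 75)
  expect_equal(ft, list(count_S = 2L, count_G = 1L, difference = 1L))
})

test_that("per-body connection coverage scores incident preserved connections", {
  toy <- toy_connectivity()
  cov <- body_connection_coverage(toy$Gg, toy$Sg, toy$A)
  expect_equal(cov$coverage, c(2 / 3, 2 / 3))
  expect_equal(cov$n_connections, c(3L, 3L))
  # body 1 shattered across three fragments: only the connection through its
  # assigned fragment survives
  Ssplit <- label_volume(array(c(10L, 11L, 12L, 20L, 20L, 20L), dim = c(6, 1, 1)))
  tsp <- build_contingency(Ssplit, toy$G, "synapse_endpoints",
                           points = conneval:::synapse_endpoints(toy$syn))
  Asp <- match_segments(tsp)
  covs <- body_connection_coverage(connection_graph(toy$G, toy$syn),
                                   connection_graph(Ssplit, toy$syn), Asp)
  expect_equal(covs$coverage, c(1 / 3, 1 / 3))
  # a body whose assignment is lost entirely covers nothing
  Sm <- label_volume(array(77L, dim = c(6, 1, 1)))
  Am <- match_segments(build_contingency(Sm, toy$G, "synapse_endpoints",
                       points = conneval:::synapse_endpoints(toy$syn)))
  covm <- body_connection_coverage(connection_graph(toy$G, toy$syn),
                                   connection_graph(Sm, toy$syn), Am)
  expect_equal(covm$coverage, c(0, 0))
})

test_that("best bodies are ranked by largest single-segment overlap", {
  t <- tiny_table()
  b <- best_bodies_by_overlap(t)
  expect_equal(as.data.frame(b),
               data.frame(g = c(1L, 2L), s = c(10L, 20L), fraction = c(1, 0.5)))
  ident <- build_contingency(tiny_volumes()$G, tiny_volumes()$G)
  expect_true(all(best_bodies_by_overlap(ident)$fraction == 1))
})

test_that("subvolume VI localizes corruption to the affected block", {
  # 4x4x4 coarse cells of 16^3 voxels: each cell sits inside one 32^3 block
  a <- array(0L, dim = c(64, 64, 64))
  cell <- (seq_len(64) - 1L) %/% 16L
  vz <- rep.int(cell, 64 * 64)
  vy <- rep.int(rep(cell, each = 64), 64)
  vx <- rep(cell, each = 64 * 64)
  a[] <- vz * 16L + vy * 4L + vx + 1L
  G <- label_volume(a)
  S <- G
  S$data[1:8, 1:16, 1:16] <- max(a) + 1L  # split one cell inside block (0,0,0)
  grid <- conneval:::grid_for_volume(G, c(32, 32, 32))
  sv <- as.data.frame(subvolume_vi(S, G, grid))
  hot <- sv[sv$vi_total > 0, ]
  expect_equal(nrow(hot), 1L)
  expect_equal(unlist(hot[, c("iz", "iy", "ix")], use.names = FALSE), c(0L, 0L, 0L))

  svi <- subvolume_vi(G, G, grid)
  expect_true(all(svi$vi_total == 0))

  # single-block grid equals whole-ROI VI after local relabeling
  g1 <- conneval:::grid_for_volume(G, c(64, 64, 64))
  sv1 <- subvolume_vi(S, G, g1)
  SL <- local_connected_components(S)$volume
  GL <- local_connected_components(G)$volume
  expect_equal(sv1$vi_total, vi(build_contingency(SL, GL))$total)
})
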