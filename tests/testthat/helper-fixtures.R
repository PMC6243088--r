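# Fixtures and independent oracles used across the suite.

# 2x2x2 volumes realizing the joint counts {(10,1):4, (20,2):2, (21,2):2}.
tiny_volumes <- function() {
  G <- label_volume(array(rep(c(1L, 2L), each = 4), dim = c(2, 2, 2)))
  S <- label_volume(array(c(10L, 10L, 10L, 10L, 20L, 20L, 21L, 21L), dim = c(2, 2, 2)))
  list(S = S, G = G)
}

tiny_table <- function() {
  v <- tiny_volumes()
  build_contingency(v$S, v$G)
}

# Random label volume: labels 0..k (0 with its own mass so the ignore path
# is always exercised).
rand_volume <- function(shape, k = 6L, seed = 1L, offset = c(0L, 0L, 0L)) {
  set.seed(seed)
  label_volume(array(sample(0:k, prod(shape), replace = TRUE), dim = shape),
               offset = offset)
}

# Brute-force VI from raw label vectors via joint/marginal entropies of the
# empirical distribution -- independent of the contingency-table route.
brute_vi <- function(s, g) {
  keep <- s != 0L & g != 0L
  s <- s[keep]; g <- g[keep]
  N <- length(s)
  H <- function(p) -sum(p * log2(p))
  hj <- H(as.numeric(table(paste(s, g))) / N)
  hs <- H(as.numeric(table(s)) / N)
  hg <- H(as.numeric(table(g)) / N)
  list(over = hj - hg, under = hj - hs, total = 2 * hj - hs - hg)
}

# Brute-force Rand index by enumerating every unordered point pair.
brute_rand <- function(s, g) {
  keep <- s != 0L & g != 0L
  s <- s[keep]; g <- g[keep]
  ss <- outer(s, s, "==")
  gg <- outer(g, g, "==")
  ut <- upper.tri(ss)
  sum((ss == gg)[ut]) / sum(ut)
}

# Toy connection scenario: reference bodies 1 -> 2 with three connections
# c1..c3; the test volume splits body 2 so that c1, c2 resolve to (10, 20)
# and c3 to (10, 21).
toy_connectivity <- function() {
  G <- label_volume(array(c(1L, 1L, 1L, 2L, 2L, 2L), dim = c(6, 1, 1)))
  S <- label_volume(array(c(10L, 10L, 10L, 20L, 20L, 21L), dim = c(6, 1, 1)))
  syn <- data.frame(id = c("c1", "c2", "c3"),
                    pre_z = c(0L, 1L, 2L), pre_y = 0L, pre_x = 0L,
                    post_z = c(3L, 4L, 5L), post_y = 0L, post_x = 0L,
                    stringsAsFactors = FALSE)
  A <- match_segments(build_contingency(S, G, "synapse_endpoints",
                                        points = conneval:::synapse_endpoints(syn)))
  list(S = S, G = G, syn = syn, A = A,
       Sg = connection_graph(S, syn), Gg = connection_graph(G, syn))
}

# --- corruption-log replay oracle ------------------------------------------
# Predicts, from coordinates and the logged cuts/merges alone (never touching
# a volume), which label every endpoint carries after corruption, and from
# that the connectivity correctness the evaluator should report.

replay_endpoint_labels <- function(connections, log) {
  pre <- connections$pre_label
  post <- connections$post_label
  axcols_pre <- c("pre_z", "pre_y", "pre_x")
  axcols_post <- c("post_z", "post_y", "post_x")
  for (e in log) {
    if (e$op == "split") {
      hit <- pre == e$label & connections[[axcols_pre[e$axis]]] >= e$coord
      pre[hit] <- e$new_label
      hit <- post == e$label & connections[[axcols_post[e$axis]]] >= e$coord
      post[hit] <- e$new_label
    } else if (e$op == "merge") {
      pre[pre == e$lost] <- e$kept
      post[post == e$lost] <- e$kept
    } else stop("replay oracle cannot predict op ", e$op)
  }
  data.frame(id = connections$id, pre = pre, post = post,
             stringsAsFactors = FALSE)
}

# Greedy endpoint-overlap assignment with the documented tie rules (weight
# desc, then smaller test label, then smaller reference label), in base R.
replay_assignment <- function(g_labs, s_labs) {
  tab <- aggregate(list(n = rep(1L, length(g_labs))),
                   by = list(s = s_labs, g = g_labs), FUN = sum)
  tab <- tab[order(-tab$n, tab$s, tab$g), ]
  asg <- list()
  used_s <- character()
  for (i in seq_len(nrow(tab))) {
    ks <- as.character(tab$s[i]); kg <- as.character(tab$g[i])
    if (!kg %in% names(asg) && !ks %in% used_s) {
      asg[[kg]] <- tab$s[i]
      used_s <- c(used_s, ks)
    }
  }
  asg
}

predict_cc_from_log <- function(connections, log) {
  rl <- replay_endpoint_labels(connections, log)
  asg <- replay_assignment(c(connections$pre_label, connections$post_label),
                           c(rl$pre, rl$post))
  look <- function(g) {
    v <- asg[[as.character(g)]]
    if (is.null(v)) NA_integer_ else v
  }
  a_pre <- vapply(connections$pre_label, look, integer(1))
  a_post <- vapply(connections$post_label, look, integer(1))
  mean(!is.na(a_pre) & !is.na(a_post) & a_pre == rl$pre & a_post == rl$post)
}

predict_autapses_from_log <- function(connections, log) {
  rl <- replay_endpoint_labels(connections, log)
  sum(rl$pre == rl$post)
}

# Package-side connectivity correctness for a corrupted scene, matching on
# the endpoint domain (the route the replay oracle predicts).
scene_cc <- function(scene) {
  tep <- build_contingency(scene$test, scene$ground_truth, "synapse_endpoints",
                           points = conneval:::synapse_endpoints(scene$connections))
  A <- match_segments(tep, method = "greedy")
  Sg <- connection_graph(scene$test, scene$connections)
  Gg <- connection_graph(scene$ground_truth, scene$connections)
  connectivity_correctness(Sg, Gg, A)
}

# Do two labelings induce the same partition of the voxels (bijective
# label correspondence)?
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!identical(a == 0L, b == 0L)) return(FALSE)
  keep <- a != 0L
  pairs <- unique(cbind(a[keep], b[keep]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}
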