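#' Variation of information between two labelings
#'
#' VI(S, G) = H(S|G) + H(G|S), computed from a contingency table. The
#' conditional entropy H(S|G) is the over-segmentation component (how much
#' each reference body is shattered across test segments) and H(G|S) the
#' under-segmentation component (how much each test segment spans several
#' reference bodies). Entropies are in bits (logarithm base 2);
#' probabilities are comparison-point fractions from the table. VI is 0
#' iff the table is a bijection between label sets; both components are
#' always non-negative.
#'
#' @param t a `contingency_table` (see [build_contingency()]).
#' @return A `vi_score`: list with `oversegmentation`, `undersegmentation`
#'   and `total`, all in bits.
#' @export
vi <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$total == 0) stop("no comparison points")
  over <- cond_entropy_bits(t$counts$n, t$counts$g, t$total)
  under <- cond_entropy_bits(t$counts$n, t$counts$s, t$total)
  structure(list(oversegmentation = over, undersegmentation = under,
                 total = over + under), class = "vi_score")
}

#' @export
print.vi_score <- function(x, ...) {
  cat(sprintf("VI = %.6g bits (over %.6g, under %.6g)\n",
              x$total, x$oversegmentation, x$undersegmentation))
  invisible(x)
}

# H(A | B) in bits from joint counts n grouped by the conditioning label.
cond_entropy_bits <- function(n, by_lab, total) {
  marg <- rowsum(n, group = by_lab)
  nm <- marg[match(as.character(by_lab), rownames(marg)), 1]
  0 - sum((n / total) * log2(n / nm)) + 0   # + 0: never return -0
}

#' Rand index from a contingency table
#'
#' Pair-counting agreement over all unordered pairs of comparison points:
#' the fraction of pairs on which the two labelings agree (same segment in
#' both, or different segments in both). The adjusted variant applies the
#' Hubert-Arabie chance correction and may be negative.
#'
#' @param t a `contingency_table`.
#' @param adjusted apply the Hubert-Arabie chance correction.
#' @return A single number: in `[0, 1]` for the plain index.
#' @export
rand_index <- function(t, adjusted = FALSE) {
  stopifnot(inherits(t, "contingency_table"))
  N <- t$total
  if (N < 2) stop("rand_index needs at least 2 comparison points")
  n <- as.numeric(t$counts$n)
  a <- sum(choose(n, 2))                       # pairs together in both
  sameS <- sum(choose(as.numeric(ct_sizes_s(t)), 2))
  sameG <- sum(choose(as.numeric(ct_sizes_g(t)), 2))
  Tp <- choose(as.numeric(N), 2)
  if (!adjusted)
    return((Tp - sameS - sameG + 2 * a) / Tp)
  expected <- sameS * sameG / Tp
  denom <- (sameS + sameG) / 2 - expected
  if (denom == 0) return(1)                    # degenerate: no room for chance
  (a - expected) / denom
}

#' Per-body over-segmentation decomposition of VI
#'
#' Splits H(S|G) into one non-negative term per reference body g:
#' P(g) H(S | G = g), the body's contribution in bits to the
#' over-segmentation component. The terms sum to [vi()]'s
#' `oversegmentation` exactly. Apply to the transposed table (swap the
#' roles of S and G) to decompose under-segmentation per test segment.
#'
#' @param t a `contingency_table`.
#' @return Named numeric vector, one entry per reference label.
#' @export
body_vi_decomposition <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$total == 0) stop("no comparison points")
  N <- t$total
  dt <- copy(t$counts)
  marg <- dt[, list(ng = sum(n)), by = g]
  dt <- marg[dt, on = "g"]
  per <- dt[, list(v = -sum((n / N) * log2(n / ng)) + 0), by = g]
  setorder(per, g)
  stats::setNames(per$v, per$g)
}

#' Over- and under-segmentation score of one reference body
#'
#' For reference body `g`: the over score is its VI decomposition term
#' P(g) H(S | G = g); the under score sums, over the test segments s that
#' intersect it, P(s) times the binary entropy of membership in `g` within
#' s — how much the segments containing `g` also leak into other bodies.
#' Both are non-negative and in bits.
#'
#' @param t a `contingency_table`.
#' @param g a reference label present in the table.
#' @return List with `over` and `under` (bits).
#' @export
body_under_over <- function(t, g) {
  stopifnot(inherits(t, "contingency_table"))
  gl <- as.integer(g)
  rows <- t$counts[t$counts$g == gl]
  if (nrow(rows) == 0L) stop("reference label ", g, " not present in the table")
  N <- t$total
  ng <- sum(rows$n)
  over <- -sum((rows$n / N) * log2(rows$n / ng)) + 0
  ssz <- ct_sizes_s(t)
  ns <- as.numeric(ssz[as.character(rows$s)])
  q <- rows$n / ns
  hb <- ifelse(q <= 0 | q >= 1, 0, -q * log2(q) - (1 - q) * log2(1 - q))
  under <- sum((ns / N) * hb)
  list(over = over, under = under)
}

#' One-to-one assignment of reference segments to test segments
#'
#' Computes the partial injective mapping A from reference labels to test
#' labels that underlies the connectivity-correctness metric. `greedy`
#' sorts candidate (s, g) pairs by overlap weight descending (ties: smaller
#' test label, then smaller reference label) and accepts a pair when both
#' labels are still unused. `optimal` maximizes total overlap weight over
#' all one-to-one assignments (maximum-weight bipartite matching). When
#' every test segment overlaps exactly one reference segment — the typical
#' over-segmentation regime — the two coincide.
#'
#' @param t a `contingency_table`; its counts are the overlap weights, so
#'   match on the table whose domain the downstream metric scores
#'   (endpoints for connectivity, voxels otherwise).
#' @param method `"greedy"` or `"optimal"`.
#' @return An `assignment`: list with `pairs` (data.table `g`, `s`,
#'   `weight`) and `method`.
#' @export
match_segments <- function(t, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(inherits(t, "contingency_table"))
  if (nrow(t$counts) == 0L) stop("cannot match on an empty table")
  cand <- copy(t$counts)
  if (method == "greedy") {
    setorder(cand, -n, s, g)
    used_s <- new.env(parent = emptyenv())
    used_g <- new.env(parent = emptyenv())
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ks <- as.character(cand$s[i]); kg <- as.character(cand$g[i])
      if (is.null(used_s[[ks]]) && is.null(used_g[[kg]])) {
        keep[i] <- TRUE
        used_s[[ks]] <- TRUE
        used_g[[kg]] <- TRUE
      }
    }
    pairs <- cand[keep, list(g, s, weight = n)]
  } else {
    gs <- sort(unique(cand$g)); ss <- sort(unique(cand$s))
    gv <- paste0("g", cand$g); sv <- paste0("s", cand$s)
    graph <- igraph::graph_from_data_frame(
      data.frame(from = gv, to = sv),
      vertices = data.frame(name = c(paste0("g", gs), paste0("s", ss)),
                            type = rep(c(FALSE, TRUE), c(length(gs), length(ss)))),
      directed = FALSE)
    m <- igraph::max_bipartite_match(graph, weights = cand$n)$matching
    matched_s <- m[paste0("g", gs)]
    ok <- !is.na(matched_s)
    pairs <- data.table(g = gs[ok],
                        s = as.integer(sub("^s", "", matched_s[ok])))
    pairs <- cand[pairs, on = c("g", "s")][, list(g, s, weight = n)]
  }
  setorder(pairs, g)
  structure(list(pairs = pairs, method = method), class = "assignment")
}

#' @export
print.assignment <- function(x, ...) {
  cat(sprintf("<assignment> %d matched pair(s), method %s, total weight %g\n",
              nrow(x$pairs), x$method, sum(x$pairs$weight)))
  invisible(x)
}

# Lookup: test label assigned to each of `g` (NA where unmatched).
assignment_lookup <- function(A, g) {
  A$pairs$s[match(as.integer(g), A$pairs$g)]
}

#' Resolve synapse connections to a segment-level connection graph
#'
#' Each connection becomes a directed edge (pre label, post label) under
#' the given labeling; multiple connections between the same pair are kept
#' as distinct edges (a multiset), and the edge weight of a pair is its
#' number of connections. Connections with any endpoint on label 0 are
#' excluded and counted as unresolved.
#'
#' @param labeling a [label_volume()].
#' @param connections synapse table (see [read_synapses()]).
#' @return A `connection_graph`: list with `edges` (data.table `id`,
#'   `pre`, `post`), `unresolved` and `n_input`.
#' @export
connection_graph <- function(labeling, connections) {
  if (nrow(connections) == 0L) {
    return(structure(list(edges = data.table(id = character(), pre = integer(),
                                             post = integer()),
                          unresolved = 0L, n_input = 0L),
                     class = "connection_graph"))
  }
  pre <- label_at(labeling, as.matrix(connections[, c("pre_z", "pre_y", "pre_x")]))
  post <- label_at(labeling, as.matrix(connections[, c("post_z", "post_y", "post_x")]))
  ok <- pre != 0L & post != 0L
  structure(list(edges = data.table(id = connections$id[ok],
                                    pre = pre[ok], post = post[ok]),
                 unresolved = sum(!ok), n_input = nrow(connections)),
            class = "connection_graph")
}

#' @export
print.connection_graph <- function(x, ...) {
  cat(sprintf("<connection_graph> %d resolved connection(s) (%d unresolved), %d segment pair(s)\n",
              nrow(x$edges), x$unresolved,
              nrow(unique(x$edges[, list(pre, post)]))))
  invisible(x)
}

# Per ground-truth connection: is the identical connection preserved under
# the assignment? TRUE iff its test-side resolution is exactly
# (A(pre), A(post)).
matched_connections <- function(Sg, Gg, A) {
  e <- copy(Gg$edges)
  se <- Sg$edges
  e[, `:=`(s_pre = se$pre[match(id, se$id)], s_post = se$post[match(id, se$id)])]
  a_pre <- assignment_lookup(A, e$pre)
  a_post <- assignment_lookup(A, e$post)
  e[, matched := !is.na(s_pre) & !is.na(a_pre) & !is.na(a_post) &
                 s_pre == a_pre & s_post == a_post]
  e
}

#' Connectivity correctness
#'
#' The fraction of ground-truth synaptic connections preserved by the test
#' segmentation under a one-to-one segment assignment: a connection
#' between reference bodies (g_i, g_j) counts as preserved iff that same
#' physical connection resolves to (A(g_i), A(g_j)) in the test volume.
#' Sensitive to both error modes: a false split moves connections onto
#' unassigned fragments, and a false merge of g_1 and g_2 leaves at most
#' one of them assigned (injectivity), dropping every connection on the
#' other. Edges are direction-sensitive (pre to post).
#'
#' @param Sg `connection_graph` under the test labeling.
#' @param Gg `connection_graph` under the reference labeling, resolved
#'   from the same connection list.
#' @param A an `assignment` from [match_segments()].
#' @return Fraction in `[0, 1]`.
#' @export
connectivity_correctness <- function(Sg, Gg, A) {
  if (nrow(Gg$edges) == 0L) stop("no ground-truth connections")
  e <- matched_connections(Sg, Gg, A)
  sum(e$matched) / nrow(e)
}

#' Thresholded connectivity recall and precision
#'
#' Restricts attention to strong pathways: segment pairs connected by more
#' than `k` synapses (or at least `k` when `inclusive`). Recall is the
#' fraction of such ground-truth pairs whose preserved-connection count
#' also clears the threshold; precision divides the same numerator by the
#' number of test-segmentation pairs clearing the threshold.
#'
#' @inheritParams connectivity_correctness
#' @param k connection-count threshold.
#' @param inclusive compare with `>= k` instead of the default `> k`.
#' @return List with `recall` and `precision`; a side with no qualifying
#'   pairs is reported as `NA` (undefined), not 0.
#' @export
cc_thresholded <- function(Sg, Gg, A, k = 0L, inclusive = FALSE) {
  if (k < 0) stop("k must be non-negative")
  if (nrow(Gg$edges) == 0L) stop("no ground-truth connections")
  clears <- function(w) if (inclusive) w >= k else w > k
  e <- matched_connections(Sg, Gg, A)
  gpairs <- e[, list(w = .N, int_w = sum(matched)), by = list(pre, post)]
  num <- sum(clears(gpairs$int_w))
  den_rec <- sum(clears(gpairs$w))
  spairs <- Sg$edges[, list(w = .N), by = list(pre, post)]
  den_pre <- sum(clears(spairs$w))
  list(recall = if (den_rec > 0) num / den_rec else NA_real_,
       precision = if (den_pre > 0) num / den_pre else NA_real_)
}

#' Fragmentation score
#'
#' Number of distinct test segments minus number of distinct reference
#' segments in the comparison domain. For a typical over-segmentation this
#' is a lower bound on the merge edits needed to reach the reference; it
#' may be negative if the test volume is under-segmented.
#'
#' @param t a `contingency_table`.
#' @return Integer (possibly negative).
#' @export
frag <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  length(unique(t$counts$s)) - length(unique(t$counts$g))
}

# Smallest number of segments whose cumulative size reaches `percent`% of
# the total, sizes taken in descending order.
segments_to_threshold_count <- function(sizes, percent) {
  if (length(sizes) == 0L) stop("empty size map")
  if (percent <= 0 || percent > 100) stop("percent must be in (0, 100]")
  sz <- sort(as.numeric(sizes[sizes > 0]), decreasing = TRUE)
  cum <- cumsum(sz)
  as.integer(which(cum >= percent / 100 * cum[length(cum)])[1])
}

#' Thresholded fragmentation
#'
#' How many segments are needed for an X%-complete connectome: for each
#' volume, the minimal number of largest segments whose cumulative size
#' (voxels or synapse endpoints) reaches `percent` of the total, plus the
#' difference between test and reference counts.
#'
#' @param sizes_S,sizes_G named numeric vectors of segment sizes.
#' @param percent completeness threshold X in `(0, 100]`.
#' @return List with `count_S`, `count_G` and `difference`.
#' @export
frag_thresholded <- function(sizes_S, sizes_G, percent) {
  cs <- segments_to_threshold_count(sizes_S, percent)
  cg <- segments_to_threshold_count(sizes_G, percent)
  list(count_S = cs, count_G = cg, difference = cs - cg)
}

#' Per-body connection coverage
#'
#' For each reference body, the fraction of its incident ground-truth
#' connections (those with the body as pre or post site) preserved under
#' the assignment, as in [connectivity_correctness()]. Bodies with no
#' connections are omitted.
#'
#' @inheritParams connectivity_correctness
#' @return data.table with columns `g`, `n_connections`, `coverage`.
#' @export
body_connection_coverage <- function(Gg, Sg, A) {
  if (nrow(Gg$edges) == 0L) stop("no ground-truth connections")
  e <- matched_connections(Sg, Gg, A)
  long <- rbind(e[, list(g = pre, matched)],
                e[pre != post, list(g = post, matched)])
  out <- long[, list(n_connections = .N, coverage = mean(matched)), by = g]
  setorder(out, g)
  out[]
}

#' Rank reference bodies by their best single-segment overlap
#'
#' For each reference body, the largest fraction of its comparison points
#' covered by a single test segment — a volumetric analogue of the longest
#' error-free run. Ranked descending (ties: smaller reference label).
#'
#' @param t a `contingency_table`.
#' @return data.table with columns `g`, `s` (best-overlapping test
#'   segment, smallest label on ties), `fraction`.
#' @export
best_bodies_by_overlap <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (nrow(t$counts) == 0L) stop("empty contingency table")
  dt <- copy(t$counts)
  setorder(dt, g, -n, s)
  best <- dt[, list(s = s[1], nbest = n[1], size = sum(n)), by = g]
  best[, fraction := nbest / size]
  setorder(best, -fraction, g)
  best[, list(g, s, fraction)]
}

#' Subvolume-resolved variation of information
#'
#' Runs VI independently in every grid block, after local connected
#' components on both volumes restricted to the block, so each subvolume
#' is scored as an isolated segmentation and errors do not propagate
#' across blocks. Localizes where in the volume segmentation quality
#' degrades.
#'
#' @param S,G [label_volume()]s over the same bounding box.
#' @param grid a `grid_spec` over that box.
#' @return data.table with one row per ROI block: `iz, iy, ix`,
#'   `n` comparison points, `vi_over`, `vi_under`, `vi_total` (NA for
#'   blocks with an empty table).
#' @export
subvolume_vi <- function(S, G, grid) {
  if (!same_bbox(S, G)) stop("S and G must cover the same bounding box")
  res <- vector("list", nrow(grid$blocks))
  for (i in seq_len(nrow(grid$blocks))) {
    b <- grid$blocks[i]
    sb <- local_connected_components(vol_block(S, b))$volume
    gb <- local_connected_components(vol_block(G, b))$volume
    t <- build_contingency(sb, gb)
    if (t$total == 0) {
      res[[i]] <- data.table(iz = b$iz, iy = b$iy, ix = b$ix, n = 0L,
                             vi_over = NA_real_, vi_under = NA_real_,
                             vi_total = NA_real_)
    } else {
      v <- vi(t)
      res[[i]] <- data.table(iz = b$iz, iy = b$iy, ix = b$ix, n = t$total,
                             vi_over = v$oversegmentation,
                             vi_under = v$undersegmentation,
                             vi_total = v$total)
    }
  }
  rbindlist(res)
}
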