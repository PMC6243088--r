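#' Generate a synthetic segmentation scene
#'
#' Builds a densely packed toy connectome: segments are nearest-seed-point
#' regions (space-filling and face-connected, emulating tightly packed
#' neurites), and synaptic connections are point pairs straddling randomly
#' chosen segment-adjacency faces, sampled with weight inverse to the
#' smaller partner's volume so that connections concentrate on thin
#' processes — the regime where segmentation errors hurt connectivity
#' most. The ground truth contains no autapses by construction. The same
#' seed reproduces the scene bit-exactly.
#'
#' The connection table carries the ground-truth labels of both endpoints
#' (`pre_label`, `post_label`) as generator metadata, so corruption
#' outcomes can be predicted analytically from the corruption log.
#'
#' @param shape integer 3-vector (z, y, x) of the volume.
#' @param n_segments number of segments (>= 2).
#' @param n_connections number of synaptic connections to place.
#' @param seed integer seed; the only source of randomness.
#' @return A `synthetic_scene`: list with `ground_truth` and `test`
#'   ([label_volume()]s, initially identical), `connections` (synapse
#'   table), `corruption_log` (empty list), `seed`, `params`.
#' @export
generate_scene <- function(shape, n_segments, n_connections, seed) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) stop("shape must be 3 axes of >= 2 voxels")
  n_segments <- as.integer(n_segments)
  n_connections <- as.integer(n_connections)
  if (n_segments < 2L) stop("need at least 2 segments")
  nvox <- prod(shape)
  if (nvox < 8L * n_segments)
    stop(sprintf("volume of %d voxels is too small to host %d segments (need >= 8 voxels each)",
                 nvox, n_segments))
  with_seed(seed, {
    pts <- sample.int(nvox, n_segments)
    idx0 <- pts - 1L
    sz <- idx0 %% shape[1]
    sy <- (idx0 %/% shape[1]) %% shape[2]
    sx <- idx0 %/% (shape[1] * shape[2])
    gz <- rep.int(seq_len(shape[1]) - 1L, shape[2] * shape[3])
    gy <- rep.int(rep(seq_len(shape[2]) - 1L, each = shape[1]), shape[3])
    gx <- rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2])
    best_d <- rep(Inf, nvox)
    lab <- integer(nvox)
    for (k in seq_len(n_segments)) {
      d <- (gz - sz[k])^2 + (gy - sy[k])^2 + (gx - sx[k])^2
      upd <- d < best_d            # strict: ties keep the smaller label
      lab[upd] <- k
      best_d[upd] <- d[upd]
    }
    # lattice ties can pinch a cell apart; reattach voxels cut off from
    # their seed to whichever neighboring segment touches them
    comp <- cc_label6_cpp(lab, shape)
    stray <- comp != comp[pts][lab]
    if (any(stray)) {
      A <- array(lab, dim = shape)
      A[stray] <- 0L
      strayA <- array(stray, dim = shape)
      dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
      while (any(strayA)) {
        best <- array(0L, dim = shape)
        for (j in 1:6) {
          nb <- shift_arr(A, dirs[j, ])
          sel <- nb != 0L & (best == 0L | nb < best)
          best[sel] <- nb[sel]
        }
        fill <- strayA & best != 0L
        if (!any(fill)) stop("internal error: stray voxels could not be reattached")
        A[fill] <- best[fill]
        strayA[fill] <- FALSE
      }
      lab <- as.vector(A)
    }
    A <- array(lab, dim = shape)

    faces <- adjacency_faces(A)
    if (nrow(faces) == 0L) stop("no segment adjacencies; cannot place connections")
    sizes <- tabulate(lab, nbins = n_segments)
    wt <- 1 / pmin(sizes[faces$l1], sizes[faces$l2])
    pick <- sample.int(nrow(faces), n_connections,
                       replace = nrow(faces) < n_connections, prob = wt)
    flip <- runif(n_connections) < 0.5
    i_pre <- ifelse(flip, faces$i2[pick], faces$i1[pick])
    i_post <- ifelse(flip, faces$i1[pick], faces$i2[pick])
    pre <- coords_of(i_pre, shape)
    post <- coords_of(i_post, shape)
    connections <- data.frame(
      id = sprintf("syn-%06d", seq_len(n_connections)),
      pre_z = pre[, 1], pre_y = pre[, 2], pre_x = pre[, 3],
      post_z = post[, 1], post_y = post[, 2], post_x = post[, 3],
      pre_label = lab[i_pre], post_label = lab[i_post],
      stringsAsFactors = FALSE)
    gt <- label_volume(A)
    structure(list(ground_truth = gt, test = gt, connections = connections,
                   corruption_log = list(), seed = as.integer(seed),
                   params = list(shape = shape, n_segments = n_segments,
                                 n_connections = n_connections)),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %s voxels, %d segments, %d connections, %d corruption(s), seed %d\n",
              paste(x$params$shape, collapse = "x"), x$params$n_segments,
              nrow(x$connections), length(x$corruption_log), x$seed))
  invisible(x)
}

# All face-adjacent voxel pairs with different nonzero labels:
# data.table(i1, i2 (1-based linear indices), l1, l2).
adjacency_faces <- function(A) {
  d <- dim(A)
  res <- vector("list", 3L)
  steps <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    dv <- c(0L, 0L, 0L)
    dv[ax] <- 1L
    nb <- shift_arr(A, dv)
    hit <- which(A != 0L & nb != 0L & A != nb)
    res[[ax]] <- data.table(i1 = hit, i2 = hit + steps[ax],
                            l1 = A[hit], l2 = A[hit + steps[ax]])
  }
  rbindlist(res)
}

# 0-based global (z,y,x) coordinates of 1-based linear indices.
coords_of <- function(i, shape) {
  i0 <- i - 1L
  cbind(i0 %% shape[1], (i0 %/% shape[1]) %% shape[2], i0 %/% (shape[1] * shape[2]))
}

#' Corrupt a scene with random plane splits
#'
#' Applies `m` axis-aligned plane cuts. Each cut picks a segment of the
#' current test volume (probability proportional to size), an axis along
#' which the segment spans at least 4 voxels, and a cut coordinate from
#' the central half of that span, then moves the upper part to a fresh
#' label. Cuts whose parts would be disconnected are rejected and
#' redrawn, so each cut raises the segment count by exactly one. Cutting
#' through the interior (rather than shaving a face) emulates the
#' topologically meaningful splits produced by real segmentation errors.
#'
#' @param scene a `synthetic_scene`.
#' @param m number of cuts (>= 0).
#' @param seed integer seed for this corruption step.
#' @return The scene with `test` corrupted and the cuts appended to
#'   `corruption_log` (each entry records `label`, `axis`, `coord` — the
#'   global 0-based cut coordinate; voxels of the segment with
#'   `coordinate >= coord` get `new_label`).
#' @export
corrupt_split <- function(scene, m, seed) {
  stopifnot(inherits(scene, "synthetic_scene"))
  m <- as.integer(m)
  if (m < 0L) stop("m must be non-negative")
  if (m == 0L) return(scene)
  with_seed(seed, {
    V <- scene$test
    A <- V$data
    d <- dim(A)
    next_label <- max(A) + 1L
    for (cut in seq_len(m)) {
      done <- FALSE
      for (attempt in seq_len(200L)) {
        sizes <- tabulate(as.vector(A))
        cand <- which(sizes >= 8L)
        if (length(cand) == 0L) stop("no splittable segment left")
        labk <- cand[sample.int(length(cand), 1L, prob = sizes[cand])]
        idx <- which(A == labk)
        co <- coords_of(idx, d) + matrix(V$offset, length(idx), 3, byrow = TRUE)
        axes <- which(apply(co, 2, function(x) diff(range(x))) + 1L >= 4L)
        if (length(axes) == 0L) next
        ax <- axes[sample.int(length(axes), 1L)]
        rng <- range(co[, ax])
        ext <- rng[2] - rng[1] + 1L
        lo <- rng[1] + ceiling(ext / 4)
        hi <- rng[1] + floor(3 * ext / 4)
        if (lo > hi) next
        cc <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        upper <- co[, ax] >= cc
        if (!any(upper) || all(upper)) next
        if (!part_connected(idx[upper], d) || !part_connected(idx[!upper], d)) next
        A[idx[upper]] <- next_label
        scene$corruption_log[[length(scene$corruption_log) + 1L]] <-
          list(op = "split", label = labk, axis = ax, coord = cc,
               new_label = next_label)
        next_label <- next_label + 1L
        done <- TRUE
        break
      }
      if (!done) stop("could not find a valid plane cut after 200 attempts")
    }
    scene$test <- label_volume(A, offset = V$offset, resolution = V$resolution)
    scene
  })
}

# Is the voxel set (1-based linear indices) one 6-connected component?
part_connected <- function(idx, d) {
  co <- coords_of(idx, d)
  lo <- apply(co, 2, min)
  hi <- apply(co, 2, max)
  sub <- array(0L, dim = hi - lo + 1L)
  sub[cbind(co[, 1] - lo[1] + 1L, co[, 2] - lo[2] + 1L, co[, 3] - lo[3] + 1L)] <- 1L
  comp <- cc_label6_cpp(as.vector(sub), dim(sub))
  max(comp) == 1L
}

#' Corrupt a scene by falsely merging adjacent segment pairs
#'
#' Relabels each pair to a single label (the smaller of the two). Former
#' connections between the pair become autapses in the test volume, and
#' the one-to-one assignment behind connectivity correctness can keep at
#' most one of the two bodies matched.
#'
#' @param scene a `synthetic_scene`.
#' @param pairs 2-column matrix (or list of length-2 vectors) of adjacent
#'   segment labels in the current test volume.
#' @return The scene with `test` merged and the merges logged.
#' @export
corrupt_merge <- function(scene, pairs) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs) == 0L) return(scene)
  A <- scene$test$data
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    if (a == b) stop("cannot merge a segment with itself")
    faces <- adjacency_faces(A)
    adj <- faces[(l1 == a & l2 == b) | (l1 == b & l2 == a)]
    if (nrow(adj) == 0L)
      stop(sprintf("segments %d and %d are not face-adjacent", a, b))
    keep <- min(a, b); lose <- max(a, b)
    A[A == lose] <- keep
    scene$corruption_log[[length(scene$corruption_log) + 1L]] <-
      list(op = "merge", kept = keep, lost = lose)
  }
  scene$test <- label_volume(A, offset = scene$test$offset,
                             resolution = scene$test$resolution)
  scene
}

#' Corrupt a scene by random boundary shifts
#'
#' Randomly reassigns voxels near ground-truth inter-segment boundaries to
#' an adjacent segment, moving boundaries by up to `radius` voxels while
#' preserving the segment count. Only voxels within Euclidean distance
#' `radius` of a differently labeled voxel are eligible, so comparing
#' against a ground truth dilated with at least the same radius removes
#' the corruption entirely. Voxels hosting synapse endpoints are left in
#' place: boundary placement noise is thereby isolated from connectivity
#' errors, which the split and merge operators model explicitly.
#'
#' @param scene a `synthetic_scene`.
#' @param radius maximum shift in voxels (>= 0).
#' @param seed integer seed for this corruption step.
#' @return The scene with `test` shifted and the shift logged.
#' @export
corrupt_boundary_shift <- function(scene, radius, seed) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (radius < 0) stop("radius must be non-negative")
  if (radius == 0) return(scene)
  with_seed(seed, {
    V <- scene$test
    G <- scene$ground_truth
    d <- dim(V$data)
    dd <- dilate_gt_boundaries(G, radius)
    band <- G$data != 0L & dd$data == 0L
    band[lin_index(V, synapse_endpoints(scene$connections))] <- FALSE
    A <- V$data
    before_labels <- unique(as.vector(A))
    steps <- c(1L, -1L, d[1], -d[1], d[1] * d[2], -(d[1] * d[2]))
    dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
    for (sweep in seq_len(max(1L, floor(radius)))) {
      sel <- which(band & runif(length(A)) < 0.5)
      if (length(sel) == 0L) next
      dj <- sample.int(6L, length(sel), replace = TRUE)
      co <- coords_of(sel, d)
      tgt <- co + dirs[dj, , drop = FALSE]
      ok <- tgt[, 1] >= 0L & tgt[, 1] < d[1] & tgt[, 2] >= 0L & tgt[, 2] < d[2] &
            tgt[, 3] >= 0L & tgt[, 3] < d[3]
      sel <- sel[ok]; nlin <- sel + steps[dj[ok]]
      nb <- A[nlin]
      apply_ <- nb != 0L & nb != A[sel]
      A[sel[apply_]] <- nb[apply_]
    }
    missing <- setdiff(before_labels, unique(as.vector(A)))
    for (lb in missing) A[V$data == lb] <- lb   # never let a segment vanish
    scene$corruption_log[[length(scene$corruption_log) + 1L]] <-
      list(op = "boundary_shift", radius = radius)
    scene$test <- label_volume(A, offset = V$offset, resolution = V$resolution)
    scene
  })
}

#' Export a scene in the formats the evaluator reads
#'
#' Writes `<prefix>_gt.zarr` and `<prefix>_test.zarr` (zarr label
#' volumes), `<prefix>_synapses.json` and `<prefix>_log.json`.
#'
#' @param scene a `synthetic_scene`.
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
export_scene <- function(scene, prefix) {
  write_label_volume(scene$ground_truth, paste0(prefix, "_gt.zarr"))
  write_label_volume(scene$test, paste0(prefix, "_test.zarr"))
  write_synapses(scene$connections[, c("id", "pre_z", "pre_y", "pre_x",
                                       "post_z", "post_y", "post_x")],
                 paste0(prefix, "_synapses.json"))
  writeLines(jsonlite::toJSON(scene$corruption_log, auto_unbox = TRUE, digits = NA),
             paste0(prefix, "_log.json"))
  invisible(prefix)
}
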