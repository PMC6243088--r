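#' Orphan segment report
#'
#' An orphan is a segment whose size falls strictly below a threshold `K`
#' — too small to be a plausible complete neuron. Size is measured either
#' in synapse endpoints (pre and post sites resolved into the volume; the
#' default criterion, and segments carrying no endpoint at all count as
#' orphans) or in voxels. Requires no reference volume. When a grid is
#' supplied, orphans are binned by the block containing their voxel
#' centroid, giving the orphan-density heatmap.
#'
#' @param S a [label_volume()].
#' @param connections synapse table, required for the endpoint criterion.
#' @param K size threshold; segments with size < K are orphans.
#' @param kind `"synapse_endpoints"` or `"voxels"`.
#' @param grid optional `grid_spec` for the per-block density.
#' @return An `orphan_report`: list with `kind`, `K`, `orphan_labels`,
#'   `n_orphans`, `n_segments`, `sizes` (measured size per segment) and
#'   `per_block` (data.table `iz, iy, ix, n_orphans`, `NULL` without a
#'   grid).
#' @export
orphan_count <- function(S, connections = NULL, K = 10L,
                         kind = c("synapse_endpoints", "voxels"), grid = NULL) {
  kind <- match.arg(kind)
  vox <- segment_sizes(S)
  labs <- as.integer(names(vox))
  if (kind == "synapse_endpoints") {
    if (is.null(connections))
      stop("the synapse_endpoints criterion requires a connection list")
    ep <- label_at(S, synapse_endpoints(connections))
    ep <- ep[ep != 0L]
    cnt <- table(ep)
    sizes <- stats::setNames(rep(0L, length(labs)), labs)
    sizes[names(cnt)] <- as.integer(cnt)
  } else {
    sizes <- vox
  }
  orphan <- sizes < K
  per_block <- NULL
  if (!is.null(grid) && any(orphan)) {
    cen <- segment_centroids(S, labs[orphan])
    bi <- pmin(pmax((cen - matrix(grid$offset, nrow(cen), 3, byrow = TRUE)), 0L) %/%
                 matrix(grid$block_shape, nrow(cen), 3, byrow = TRUE),
               matrix(as.integer(ceiling(grid$shape / grid$block_shape)) - 1L,
                      nrow(cen), 3, byrow = TRUE))
    per_block <- data.table(iz = bi[, 1], iy = bi[, 2], ix = bi[, 3])[,
      list(n_orphans = .N), by = list(iz, iy, ix)]
    setorder(per_block, iz, iy, ix)
  } else if (!is.null(grid)) {
    per_block <- data.table(iz = integer(), iy = integer(), ix = integer(),
                            n_orphans = integer())
  }
  structure(list(kind = kind, K = as.integer(K),
                 orphan_labels = labs[orphan], n_orphans = sum(orphan),
                 n_segments = length(labs), sizes = sizes,
                 per_block = per_block),
            class = "orphan_report")
}

#' @export
print.orphan_report <- function(x, ...) {
  cat(sprintf("<orphan_report> %d of %d segment(s) below %d %s\n",
              x$n_orphans, x$n_segments, x$K, x$kind))
  invisible(x)
}

# Integer global (z,y,x) voxel centroid of each requested label.
segment_centroids <- function(v, labels) {
  d <- dim(v$data)
  gz <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  gy <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  gx <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  dt <- data.table(lab = as.vector(v$data), gz = gz, gy = gy, gx = gx)
  cen <- dt[lab %in% labels,
            list(cz = mean(gz), cy = mean(gy), cx = mean(gx)), by = lab]
  setorder(cen, lab)
  m <- as.matrix(cen[, list(cz, cy, cx)])
  storage.mode(m) <- "integer"
  m + matrix(v$offset, nrow(m), 3, byrow = TRUE)
}

#' Autapse (self-loop) report
#'
#' An autapse is a connection whose pre and post sites resolve to the same
#' nonzero segment. Neurons form few synapses onto themselves, so a
#' segment accumulating many self-loops is a strong false-merge signal;
#' because genuine autapses do occur, segments are ranked as outliers
#' rather than flagged as errors.
#'
#' @param S a [label_volume()].
#' @param connections nonempty synapse table.
#' @return List with `total`, `per_label` (data.table `lab`, `n_autapses`,
#'   ranked descending, ties by smaller label) and `unresolved`.
#' @export
self_loop_report <- function(S, connections) {
  if (is.null(connections) || nrow(connections) == 0L)
    stop("self_loop_report requires a nonempty connection list")
  gr <- connection_graph(S, connections)
  auto <- gr$edges[pre == post]
  per <- auto[, list(n_autapses = .N), by = list(lab = pre)]
  setorder(per, -n_autapses, lab)
  list(total = nrow(auto), per_label = per[], unresolved = gr$unresolved)
}

#' Segments needed to reach a volume threshold
#'
#' The minimal number of largest segments whose cumulative size reaches
#' `percent` of the total — a ground-truth-free indicator of relative
#' over-segmentation.
#'
#' @param sizes named numeric vector of segment sizes (voxels or synapse
#'   endpoints).
#' @param percent threshold X in `(0, 100]`.
#' @return Integer count.
#' @export
segments_to_threshold <- function(sizes, percent) {
  segments_to_threshold_count(sizes, percent)
}

#' Export per-block values as a heatmap table
#'
#' One row per ROI block in deterministic (z, then y, then x) order;
#' blocks without a value carry NA. Written as CSV with columns
#' `block_z, block_y, block_x, value` when a path is given.
#'
#' @param per_block data.table with columns `iz, iy, ix` and one value
#'   column (its name is taken as the value), e.g. the `per_block` field
#'   of [orphan_count()] or a column of [subvolume_vi()].
#' @param grid the `grid_spec` whose ROI blocks define the rows.
#' @param path optional CSV output path.
#' @return data.frame with columns `block_z, block_y, block_x, value`.
#' @export
heatmap_export <- function(per_block, grid, path = NULL) {
  rows <- grid$blocks[, list(iz, iy, ix)]
  setorder(rows, iz, iy, ix)
  if (is.null(per_block) || nrow(per_block) == 0L) {
    rows[, value := NA_real_]
  } else {
    pb <- as.data.table(per_block)
    valcol <- setdiff(names(pb), c("iz", "iy", "ix"))[1]
    rows <- pb[, c("iz", "iy", "ix", valcol), with = FALSE][rows,
      on = c("iz", "iy", "ix")]
    setnames(rows, valcol, "value")
    setorder(rows, iz, iy, ix)
  }
  out <- rows[, list(block_z = iz, block_y = iy, block_x = ix,
                     value = as.numeric(value))]
  setDF(out)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
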