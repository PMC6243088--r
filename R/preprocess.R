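#' Partition a bounding box into a regular grid of subvolumes
#'
#' Blocks tile the half-open box `[offset, offset + shape)`; blocks at the
#' upper faces are clipped. The returned grid carries every block; use
#' [restrict_grid()] (or an ROI file, [read_roi()]) to keep a subset as
#' the region of interest.
#'
#' @param bounds list with `offset` and `shape`, integer 3-vectors (z,y,x).
#' @param block_shape integer 3-vector of voxels per block.
#' @return A `grid_spec`: list with `block_shape`, `offset`, `shape` and a
#'   data.table `blocks` with 0-based block indices `iz, iy, ix`, global
#'   block origins `z0, y0, x0` and clipped block shapes `nz, ny, nx`.
#' @export
partition_grid <- function(bounds, block_shape) {
  offset <- as.integer(bounds$offset)
  shape <- as.integer(bounds$shape)
  block_shape <- as.integer(block_shape)
  if (any(shape <= 0L)) stop("empty bounds")
  if (any(block_shape <= 0L)) stop("block_shape must be positive")
  ngrid <- as.integer(ceiling(shape / block_shape))
  idx <- as.data.table(expand.grid(iz = seq_len(ngrid[1]) - 1L,
                                   iy = seq_len(ngrid[2]) - 1L,
                                   ix = seq_len(ngrid[3]) - 1L))
  setorder(idx, iz, iy, ix)
  blocks <- idx[, list(
    iz, iy, ix,
    z0 = offset[1] + iz * block_shape[1],
    y0 = offset[2] + iy * block_shape[2],
    x0 = offset[3] + ix * block_shape[3],
    nz = pmin(block_shape[1], offset[1] + shape[1] - (offset[1] + iz * block_shape[1])),
    ny = pmin(block_shape[2], offset[2] + shape[2] - (offset[2] + iy * block_shape[2])),
    nx = pmin(block_shape[3], offset[3] + shape[3] - (offset[3] + ix * block_shape[3])))]
  structure(list(block_shape = block_shape, offset = offset, shape = shape,
                 blocks = blocks), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d block(s) of %s voxels over box %s+%s\n",
              nrow(x$blocks), paste(x$block_shape, collapse = "x"),
              paste(x$offset, collapse = ","), paste(x$shape, collapse = "x")))
  invisible(x)
}

#' Restrict a grid to a region of interest
#' @param grid a `grid_spec` from [partition_grid()].
#' @param idx `n x 3` matrix of 0-based block indices `(iz, iy, ix)` to keep.
#' @return The `grid_spec` with `blocks` reduced to the listed indices.
#' @export
restrict_grid <- function(grid, idx) {
  idx <- matrix(as.integer(idx), ncol = 3L)
  want <- data.table(iz = idx[, 1], iy = idx[, 2], ix = idx[, 3])
  kept <- grid$blocks[want, on = c("iz", "iy", "ix"), nomatch = NULL]
  if (nrow(kept) < nrow(want)) stop("ROI lists block indices outside the grid")
  grid$blocks <- kept
  grid
}

grid_for_volume <- function(v, block_shape) {
  partition_grid(lv_bounds(v), block_shape)
}

# Extract one grid block of a volume as its own label_volume.
vol_block <- function(v, b) {
  rz <- (b$z0 - v$offset[1]) + seq_len(b$nz)
  ry <- (b$y0 - v$offset[2]) + seq_len(b$ny)
  rx <- (b$x0 - v$offset[3]) + seq_len(b$nx)
  label_volume(v$data[rz, ry, rx, drop = FALSE],
               offset = c(b$z0, b$y0, b$x0), resolution = v$resolution)
}

# Zero out voxels outside the grid's ROI blocks.
vol_restrict <- function(v, grid) {
  out <- array(0L, dim = dim(v$data))
  for (i in seq_len(nrow(grid$blocks))) {
    b <- grid$blocks[i]
    rz <- (b$z0 - v$offset[1]) + seq_len(b$nz)
    ry <- (b$y0 - v$offset[2]) + seq_len(b$ny)
    rx <- (b$x0 - v$offset[3]) + seq_len(b$nx)
    out[rz, ry, rx] <- v$data[rz, ry, rx]
  }
  label_volume(out, offset = v$offset, resolution = v$resolution)
}

#' Local connected components of a label volume
#'
#' Splits every nonzero label into its maximal face-connected
#' (6-connectivity) components and gives each component a fresh label, so
#' a subvolume can be treated as an isolated segmentation: errors that
#' originate elsewhere and merely pass through do not join distant pieces.
#'
#' @param V a [label_volume()].
#' @param label_offset integer added to every fresh component label, so
#'   components of different blocks get disjoint label ranges.
#' @return List with `volume` (relabeled [label_volume()]) and
#'   `provenance`, a data.table mapping each fresh label (`new`) to the
#'   original label it came from (`orig`).
#' @export
local_connected_components <- function(V, label_offset = 0L) {
  comp <- cc_label6_cpp(as.vector(V$data), dim(V$data))
  k <- if (length(comp)) max(comp) else 0L
  rep_idx <- match(seq_len(k), comp)  # first voxel of each component
  provenance <- data.table(new = seq_len(k) + as.integer(label_offset),
                           orig = as.vector(V$data)[rep_idx])
  relab <- comp
  nz <- comp != 0L
  relab[nz] <- comp[nz] + as.integer(label_offset)
  out <- label_volume(array(relab, dim = dim(V$data)),
                      offset = V$offset, resolution = V$resolution)
  list(volume = out, provenance = provenance)
}

#' Global connected components across grid blocks
#'
#' Given per-block locally relabeled volumes (from
#' [local_connected_components()] with disjoint label ranges), determines
#' which local components are joined by a face-connected pathway through
#' the region of interest, by union-find over pairs of face-adjacent
#' boundary voxels in neighboring ROI blocks whose original (provenance)
#' labels agree. Components of the same original label whose only
#' connection runs outside the ROI remain distinct — a segment that leaves
#' and re-enters the ROI is scored as two objects.
#'
#' Final labels are canonical: components are numbered by the smallest
#' global voxel index they contain, so the result is independent of the
#' block partition.
#'
#' @param blocks list of lists, each with `index` (0-based `c(iz, iy, ix)`),
#'   `volume` (locally relabeled block) and `provenance` (its relabeling
#'   table).
#' @param grid the `grid_spec` the blocks came from.
#' @return List with `map` (data.table `local` -> `final`) and
#'   `provenance` (data.table `final` -> `orig`).
#' @export
global_connected_components <- function(blocks, grid) {
  all_prov <- rbindlist(lapply(blocks, `[[`, "provenance"))
  if (nrow(all_prov) == 0L)
    return(list(map = data.table(local = integer(), final = integer()),
                provenance = data.table(final = integer(), orig = integer())))
  if (anyDuplicated(all_prov$new))
    stop("inconsistent provenance: local labels of different blocks overlap")
  maxlab <- max(all_prov$new)
  origof <- integer(maxlab)
  origof[all_prov$new] <- all_prov$orig

  parent <- seq_len(maxlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  key <- blocks_key(blocks)
  for (bi in seq_along(blocks)) {
    a <- blocks[[bi]]
    da <- dim(a$volume$data)
    for (ax in 1:3) {
      nidx <- a$index
      nidx[ax] <- nidx[ax] + 1L
      bj <- key[[paste(nidx, collapse = ",")]]
      if (is.null(bj)) next
      b <- blocks[[bj]]
      fa <- switch(ax, a$volume$data[da[1], , , drop = TRUE],
                       a$volume$data[, da[2], , drop = TRUE],
                       a$volume$data[, , da[3], drop = TRUE])
      fb <- switch(ax, b$volume$data[1, , , drop = TRUE],
                       b$volume$data[, 1, , drop = TRUE],
                       b$volume$data[, , 1, drop = TRUE])
      la <- as.vector(fa); lb <- as.vector(fb)
      touch <- la != 0L & lb != 0L & origof[pmax(la, 1L)] == origof[pmax(lb, 1L)]
      if (!any(touch)) next
      prs <- unique(data.table(la = la[touch], lb = lb[touch]))
      for (r in seq_len(nrow(prs))) {
        ra <- find(prs$la[r]); rb <- find(prs$lb[r])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }

  # canonical ordering: smallest global linear voxel index per merged component
  minlin <- rbindlist(lapply(blocks, function(bl) {
    d <- dim(bl$volume$data)
    o <- bl$volume$offset - grid$offset
    gs <- grid$shape
    gz <- rep.int(o[1] + seq_len(d[1]) - 1L, d[2] * d[3])
    gy <- rep.int(rep(o[2] + seq_len(d[2]) - 1L, each = d[1]), d[3])
    gx <- rep(o[3] + seq_len(d[3]) - 1L, each = d[1] * d[2])
    lin <- gz + gs[1] * (gy + gs[2] * gx)
    data.table(lab = as.vector(bl$volume$data), lin = lin)[lab != 0L,
      list(lin = min(lin)), by = lab]
  }))
  roots <- vapply(all_prov$new, find, integer(1))
  minlin[, lab := vapply(lab, find, integer(1))]
  rootkey <- minlin[, list(lin = min(lin)), by = lab]
  setorder(rootkey, lin)
  final_of_root <- stats::setNames(seq_len(nrow(rootkey)), rootkey$lab)
  map <- data.table(local = all_prov$new,
                    final = as.integer(final_of_root[as.character(roots)]))
  provenance <- unique(data.table(final = map$final, orig = all_prov$orig))
  if (anyDuplicated(provenance$final))
    stop("inconsistent provenance: merged components trace to different original labels")
  setorder(provenance, final)
  list(map = map, provenance = provenance)
}

blocks_key <- function(blocks) {
  key <- new.env(parent = emptyenv())
  for (i in seq_along(blocks))
    assign(paste(blocks[[i]]$index, collapse = ","), i, envir = key)
  key
}

#' Blockwise connected-component relabeling of a whole volume
#'
#' Convenience driver: partitions `V` over `grid` (ROI blocks only), runs
#' [local_connected_components()] per block with disjoint label ranges,
#' joins them with [global_connected_components()], and materializes the
#' relabeled volume. The voxel partition is identical to running connected
#' components on the unpartitioned ROI, and the final labels are canonical
#' (partition-independent).
#'
#' @param V a [label_volume()].
#' @param grid a `grid_spec`; defaults to a single block covering `V`.
#' @return List with `volume` (relabeled) and `provenance`
#'   (data.table `final` -> `orig`).
#' @export
connected_components_volume <- function(V, grid = NULL) {
  if (is.null(grid)) grid <- grid_for_volume(V, lv_shape(V))
  Vr <- vol_restrict(V, grid)
  blocks <- vector("list", nrow(grid$blocks))
  off <- 0L
  for (i in seq_len(nrow(grid$blocks))) {
    b <- grid$blocks[i]
    cc <- local_connected_components(vol_block(Vr, b), label_offset = off)
    off <- off + nrow(cc$provenance)
    blocks[[i]] <- list(index = c(b$iz, b$iy, b$ix),
                        volume = cc$volume, provenance = cc$provenance)
  }
  glob <- global_connected_components(blocks, grid)
  lut <- integer(if (nrow(glob$map)) max(glob$map$local) else 0L)
  lut[glob$map$local] <- glob$map$final
  out <- array(0L, dim = dim(Vr$data))
  for (i in seq_len(nrow(grid$blocks))) {
    b <- grid$blocks[i]
    rz <- (b$z0 - Vr$offset[1]) + seq_len(b$nz)
    ry <- (b$y0 - Vr$offset[2]) + seq_len(b$ny)
    rx <- (b$x0 - Vr$offset[3]) + seq_len(b$nx)
    loc <- blocks[[i]]$volume$data
    nz <- loc != 0L
    loc[nz] <- lut[loc[nz]]
    out[rz, ry, rx] <- loc
  }
  list(volume = label_volume(out, offset = Vr$offset, resolution = Vr$resolution),
       provenance = glob$provenance)
}

#' Erase ground-truth voxels near inter-segment boundaries
#'
#' Sets to 0 every nonzero voxel lying within Euclidean distance `radius`
#' (in voxel units) of a voxel carrying a *different* nonzero label.
#' Because comparison skips points where the reference is 0, this removes
#' the contribution of small boundary-placement differences to the voxel
#' metrics; it does not alter segment topology. Radius 0 is the identity.
#'
#' @param G reference [label_volume()].
#' @param radius non-negative dilation radius in voxels.
#' @return The dilated [label_volume()].
#' @export
dilate_gt_boundaries <- function(G, radius = 2) {
  if (radius < 0) stop("radius must be non-negative")
  if (radius == 0) return(G)
  r <- floor(radius)
  offs <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  offs <- offs[rowSums(offs^2) <= radius^2 & rowSums(offs != 0) > 0, , drop = FALSE]
  a <- G$data
  mark <- array(FALSE, dim = dim(a))
  for (i in seq_len(nrow(offs))) {
    nb <- shift_arr(a, offs[i, ])
    mark <- mark | (nb != 0L & a != 0L & nb != a)
  }
  a[mark] <- 0L
  label_volume(a, offset = G$offset, resolution = G$resolution)
}

#' Restrict comparison to the traced (ground-truthed) subset
#'
#' For sparse evaluation: voxels where the reference is 0 (untraced) are
#' set to 0 in the test volume as well, so downstream metrics only see the
#' traced subset.
#'
#' @param S test [label_volume()].
#' @param G reference [label_volume()], same bounding box.
#' @return List with the masked `S` and (unchanged) `G`.
#' @export
filter_sparse_bodies <- function(S, G) {
  if (!same_bbox(S, G)) stop("S and G must cover the same bounding box")
  s <- S$data
  s[G$data == 0L] <- 0L
  list(S = label_volume(s, offset = S$offset, resolution = S$resolution), G = G)
}

#' Remove small ground-truth segments
#'
#' Relabels to 0 every segment with fewer than `min_size` voxels. Used to
#' drop untrustworthy small orphan fragments from an imperfect ground
#' truth before scoring against it.
#'
#' @param G reference [label_volume()].
#' @param min_size minimum voxel count a segment must have to be kept.
#' @return The filtered [label_volume()].
#' @export
filter_small_orphans_gt <- function(G, min_size = 0L) {
  if (min_size < 0) stop("min_size must be non-negative")
  if (min_size == 0) return(G)
  sz <- segment_sizes(G)
  drop <- as.integer(names(sz)[sz < min_size])
  if (length(drop) == 0L) return(G)
  a <- G$data
  a[a %in% drop] <- 0L
  label_volume(a, offset = G$offset, resolution = G$resolution)
}

#' Downsample a label volume by mode pooling
#'
#' Each `factor^3` block maps to its most frequent nonzero label, ties
#' broken by the smallest label; all-background blocks map to 0. Offset is
#' integer-divided and resolution multiplied by the factor. Factor 1 is
#' the identity.
#'
#' @param V a [label_volume()].
#' @param factor integer downsampling factor, scalar or per-axis 3-vector.
#' @return The downsampled [label_volume()].
#' @export
downsample_labels <- function(V, factor) {
  f <- as.integer(if (length(factor) == 1L) rep(factor, 3L) else factor)
  if (any(f < 1L)) stop("factor must be >= 1")
  if (all(f == 1L)) return(V)
  d <- dim(V$data)
  nd <- as.integer(ceiling(d / f))
  gz <- rep.int((seq_len(d[1]) - 1L) %/% f[1], d[2] * d[3])
  gy <- rep.int(rep((seq_len(d[2]) - 1L) %/% f[2], each = d[1]), d[3])
  gx <- rep((seq_len(d[3]) - 1L) %/% f[3], each = d[1] * d[2])
  blk <- gz + nd[1] * (gy + nd[2] * gx)
  dt <- data.table(lab = as.vector(V$data), blk = blk)[lab != 0L,
    list(n = .N), by = list(blk, lab)]
  setorder(dt, blk, -n, lab)
  win <- dt[, list(lab = lab[1]), by = blk]
  out <- array(0L, dim = nd)
  out[win$blk + 1L] <- win$lab
  label_volume(out, offset = V$offset %/% f, resolution = V$resolution * f)
}

#' Downsample synapse coordinates to match [downsample_labels()]
#' @param syn synapse table (see [read_synapses()]).
#' @param factor integer factor, scalar or per-axis 3-vector (z, y, x).
#' @return The synapse table with integer-divided coordinates.
#' @export
downsample_synapses <- function(syn, factor) {
  f <- as.integer(if (length(factor) == 1L) rep(factor, 3L) else factor)
  out <- syn
  for (i in 1:3) {
    zc <- c("pre_z", "pre_y", "pre_x")[i]
    pc <- c("post_z", "post_y", "post_x")[i]
    out[[zc]] <- out[[zc]] %/% f[i]
    out[[pc]] <- out[[pc]] %/% f[i]
  }
  out
}
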