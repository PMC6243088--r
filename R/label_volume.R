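#' Label volumes
#'
#' A `label_volume` holds a 3D array of non-negative segment identifiers
#' together with its placement in the global voxel frame. Coordinates are
#' 0-based `(z, y, x)`; the volume occupies the half-open box
#' `[offset, offset + dim)`. Label 0 marks background and ignored voxels
#' (e.g. voxels erased by [dilate_gt_boundaries()]) and participates in no
#' metric.
#'
#' @param data 3D integer array of segment labels, indexed `[z, y, x]`.
#' @param offset integer 3-vector, global voxel coordinate of `data[1,1,1]`.
#' @param resolution numeric 3-vector, nanometres per voxel along (z, y, x).
#' @return An object of class `label_volume`.
#' @examples
#' v <- label_volume(array(1L, dim = c(4, 4, 4)))
#' label_at(v, c(0, 0, 0))
#' @export
label_volume <- function(data, offset = c(0L, 0L, 0L), resolution = c(8, 8, 8)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array of segment labels")
  if (!is.integer(data)) {
    if (any(data != floor(data))) stop("labels must be integers")
    storage.mode(data) <- "integer"
  }
  if (anyNA(data)) stop("labels must not contain NA")
  if (any(data < 0L)) stop("labels must be non-negative (0 = background/ignore)")
  offset <- as.integer(offset)
  resolution <- as.numeric(resolution)
  if (length(offset) != 3L || anyNA(offset)) stop("`offset` must be an integer 3-vector")
  if (length(resolution) != 3L || any(resolution <= 0)) stop("`resolution` must be positive")
  structure(list(data = data, offset = offset, resolution = resolution),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  labs <- unique_labels(x)
  cat(sprintf("<label_volume> %d x %d x %d voxels (z,y,x), offset (%s), %d segment(s)\n",
              d[1], d[2], d[3], paste(x$offset, collapse = ","), length(labs)))
  invisible(x)
}

lv_shape <- function(v) dim(v$data)

# half-open global bounding box
lv_bounds <- function(v) list(offset = v$offset, shape = dim(v$data))

same_bbox <- function(a, b) {
  identical(dim(a$data), dim(b$data)) && identical(a$offset, b$offset)
}

#' Nonzero labels present in a volume, ascending
#' @param v a [label_volume()].
#' @return Integer vector of distinct nonzero labels.
#' @export
unique_labels <- function(v) {
  u <- sort(unique(as.vector(v$data)))
  u[u != 0L]
}

#' Voxel counts per nonzero segment
#'
#' @param v a [label_volume()].
#' @return Named integer vector: voxel count per nonzero label, ascending
#'   label order.
#' @export
segment_sizes <- function(v) {
  dt <- data.table(lab = as.vector(v$data))[lab != 0L, .N, by = lab]
  setorder(dt, lab)
  stats::setNames(dt$N, dt$lab)
}

# Coerce points to an n x 3 integer matrix of global (z, y, x) coordinates.
as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L, byrow = TRUE)
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop("points must have 3 columns (z, y, x)")
  storage.mode(p) <- "integer"
  p
}

# 1-based linear (column-major) indices of global points within v;
# errors on the first out-of-bounds point, naming it.
lin_index <- function(v, p) {
  p <- as_points(p)
  d <- dim(v$data)
  rel <- sweep(p, 2L, v$offset)
  bad <- rel[, 1] < 0L | rel[, 1] >= d[1] |
         rel[, 2] < 0L | rel[, 2] >= d[2] |
         rel[, 3] < 0L | rel[, 3] >= d[3]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("point (%d, %d, %d) lies outside the volume bounds",
                 p[i, 1], p[i, 2], p[i, 3]))
  }
  rel[, 1] + d[1] * (rel[, 2] + d[2] * rel[, 3]) + 1L
}

#' Look up segment labels at global coordinates
#'
#' @param v a [label_volume()].
#' @param p a length-3 vector or an `n x 3` matrix of global 0-based
#'   `(z, y, x)` voxel coordinates.
#' @return Integer vector of labels (0 = background/ignored).
#' @export
label_at <- function(v, p) {
  v$data[lin_index(v, p)]
}

# Shift a 3D array by integer offset d = (dz, dy, dx): out[i] = a[i + d],
# zero-filled where i + d falls outside.
shift_arr <- function(a, d) {
  dm <- dim(a)
  out <- array(0L, dim = dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      if (d[ax] >= dm[ax]) return(out)
      src[[ax]] <- (1L + d[ax]):dm[ax]
      dst[[ax]] <- 1L:(dm[ax] - d[ax])
    } else {
      if (-d[ax] >= dm[ax]) return(out)
      src[[ax]] <- 1L:(dm[ax] + d[ax])
      dst[[ax]] <- (1L - d[ax]):dm[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
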