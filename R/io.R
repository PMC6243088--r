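#' Read and write label volumes as zarr arrays
#'
#' Volumes are stored as zarr v2 directory stores holding one uncompressed
#' little-endian integer dataset in C order with shape `(z, y, x)`, plus
#' `offset` and `resolution` attributes in `.zattrs`. Stores written here
#' are readable by any zarr v2 implementation, and stores produced
#' elsewhere are readable as long as they use an integer dtype and no
#' compressor.
#'
#' @param path directory of the zarr array.
#' @param v a [label_volume()].
#' @param chunk_shape integer 3-vector, voxels per chunk along (z, y, x).
#' @return `read_label_volume()` returns a [label_volume()];
#'   `write_label_volume()` returns `path` invisibly.
#' @export
read_label_volume <- function(path) {
  meta_path <- file.path(path, ".zarray")
  if (!file.exists(meta_path)) stop("not a zarr array (no .zarray): ", path)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  if (!is.null(meta$compressor) && length(meta$compressor) > 0)
    stop("unsupported zarr compressor; only uncompressed stores are read")
  if (!identical(meta$order, "C")) stop("only C-order zarr arrays are supported")
  shape <- as.integer(meta$shape)
  chunks <- as.integer(meta$chunks)
  if (length(shape) != 3L) stop("expected a 3D zarr array")
  dtype <- meta$dtype
  if (!dtype %in% c("<i4", "<i8", "<i2", "|i1", "|u1", "<u2"))
    stop("unsupported zarr dtype: ", dtype)
  fill <- as.integer(meta$fill_value %||% 0L)
  ngrid <- ceiling(shape / chunks)
  data <- array(fill, dim = shape)
  for (cz in seq_len(ngrid[1]) - 1L) for (cy in seq_len(ngrid[2]) - 1L)
    for (cx in seq_len(ngrid[3]) - 1L) {
      f <- file.path(path, paste(cz, cy, cx, sep = "."))
      if (!file.exists(f)) next
      vals <- read_zarr_chunk(f, prod(chunks), dtype)
      # stored C-order over (z,y,x): x fastest -> fill an (x,y,z) array, permute
      ch <- aperm(array(vals, dim = rev(chunks)), c(3, 2, 1))
      z <- cz * chunks[1]; y <- cy * chunks[2]; x <- cx * chunks[3]
      kz <- min(chunks[1], shape[1] - z); ky <- min(chunks[2], shape[2] - y)
      kx <- min(chunks[3], shape[3] - x)
      data[z + seq_len(kz), y + seq_len(ky), x + seq_len(kx)] <-
        ch[seq_len(kz), seq_len(ky), seq_len(kx)]
    }
  attrs_path <- file.path(path, ".zattrs")
  offset <- c(0L, 0L, 0L); resolution <- c(8, 8, 8)
  if (file.exists(attrs_path)) {
    at <- jsonlite::fromJSON(attrs_path, simplifyVector = TRUE)
    offset <- as.integer(at$offset %||% offset)
    resolution <- as.numeric(at$resolution %||% resolution)
  }
  label_volume(data, offset = offset, resolution = resolution)
}

read_zarr_chunk <- function(f, n, dtype) {
  con <- file(f, "rb")
  on.exit(close(con))
  switch(dtype,
    "<i4" = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    "<i2" = readBin(con, "integer", n = n, size = 2L, signed = TRUE, endian = "little"),
    "<u2" = readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "little"),
    "|i1" = readBin(con, "integer", n = n, size = 1L, signed = TRUE),
    "|u1" = readBin(con, "integer", n = n, size = 1L, signed = FALSE),
    "<i8" = {
      # labels are < 2^31 here; take the low word of each little-endian int64
      raw <- readBin(con, "integer", n = 2L * n, size = 4L, endian = "little")
      raw[seq(1L, length(raw), by = 2L)]
    })
}

#' @rdname read_label_volume
#' @export
write_label_volume <- function(v, path, chunk_shape = c(64L, 64L, 64L)) {
  stopifnot(inherits(v, "label_volume"))
  chunk_shape <- pmin(as.integer(chunk_shape), dim(v$data))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  shape <- dim(v$data)
  meta <- list(zarr_format = 2L, shape = shape, chunks = chunk_shape,
               dtype = "<i4", compressor = NULL, fill_value = 0L,
               order = "C", filters = NULL)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null", digits = NA),
             file.path(path, ".zarray"))
  writeLines(jsonlite::toJSON(list(offset = v$offset, resolution = v$resolution),
                              auto_unbox = FALSE, digits = NA),
             file.path(path, ".zattrs"))
  ngrid <- ceiling(shape / chunk_shape)
  for (cz in seq_len(ngrid[1]) - 1L) for (cy in seq_len(ngrid[2]) - 1L)
    for (cx in seq_len(ngrid[3]) - 1L) {
      ch <- array(0L, dim = chunk_shape)
      z <- cz * chunk_shape[1]; y <- cy * chunk_shape[2]; x <- cx * chunk_shape[3]
      kz <- min(chunk_shape[1], shape[1] - z); ky <- min(chunk_shape[2], shape[2] - y)
      kx <- min(chunk_shape[3], shape[3] - x)
      ch[seq_len(kz), seq_len(ky), seq_len(kx)] <-
        v$data[z + seq_len(kz), y + seq_len(ky), x + seq_len(kx)]
      con <- file(file.path(path, paste(cz, cy, cx, sep = ".")), "wb")
      writeBin(as.integer(aperm(ch, c(3, 2, 1))), con, size = 4L, endian = "little")
      close(con)
    }
  invisible(path)
}

#' Read and write synapse connection lists
#'
#' A synapse connection is one synaptic contact: a presynaptic site and a
#' postsynaptic site, each a global 0-based `(z, y, x)` voxel coordinate.
#' Supported formats: JSON (a list of `{id, pre: [z,y,x], post: [z,y,x]}`
#' objects) and CSV/TSV with columns `pre_z, pre_y, pre_x, post_z, post_y,
#' post_x` and an optional `id` column. Missing ids are generated.
#'
#' @param path file to read or write; format chosen by extension
#'   (`.json` vs `.csv`/`.tsv`).
#' @param syn a synapse `data.frame` as returned by `read_synapses()`.
#' @return `read_synapses()` returns a `data.frame` with columns `id`,
#'   `pre_z`, `pre_y`, `pre_x`, `post_z`, `post_y`, `post_x`.
#' @export
read_synapses <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    df <- data.table(
      id = vapply(seq_along(raw), function(i)
        as.character(raw[[i]]$id %||% sprintf("syn-%06d", i)), character(1)),
      pre_z = vapply(raw, function(r) as.integer(r$pre[[1]]), integer(1)),
      pre_y = vapply(raw, function(r) as.integer(r$pre[[2]]), integer(1)),
      pre_x = vapply(raw, function(r) as.integer(r$pre[[3]]), integer(1)),
      post_z = vapply(raw, function(r) as.integer(r$post[[1]]), integer(1)),
      post_y = vapply(raw, function(r) as.integer(r$post[[2]]), integer(1)),
      post_x = vapply(raw, function(r) as.integer(r$post[[3]]), integer(1)))
  } else {
    df <- data.table::fread(path)
    need <- c("pre_z", "pre_y", "pre_x", "post_z", "post_y", "post_x")
    if (!all(need %in% names(df)))
      stop("synapse table must have columns ", paste(need, collapse = ", "))
    if (!"id" %in% names(df)) df[, id := sprintf("syn-%06d", .I)]
    df[, id := as.character(id)]
    data.table::setcolorder(df, c("id", need))
  }
  as_synapses(df)
}

as_synapses <- function(df) {
  df <- as.data.table(df)
  bad <- df$pre_z == df$post_z & df$pre_y == df$post_y & df$pre_x == df$post_x
  if (any(bad))
    stop("connection ", df$id[which(bad)[1]], " has identical pre and post sites")
  if (anyDuplicated(df$id)) stop("connection ids must be unique")
  setDF(df)
  df
}

#' @rdname read_synapses
#' @export
write_synapses <- function(syn, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(seq_len(nrow(syn)), function(i) list(
      id = syn$id[i],
      pre = c(syn$pre_z[i], syn$pre_y[i], syn$pre_x[i]),
      post = c(syn$post_z[i], syn$post_y[i], syn$post_x[i])))
    writeLines(jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA), path)
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    data.table::fwrite(syn, path, sep = sep)
  }
  invisible(path)
}

# All endpoint coordinates of a synapse table: 2n x 3 matrix (pre rows
# first, then post rows), each connection contributing its pre and its
# post site as one comparison point each.
synapse_endpoints <- function(syn) {
  rbind(as.matrix(syn[, c("pre_z", "pre_y", "pre_x")]),
        as.matrix(syn[, c("post_z", "post_y", "post_x")]))
}

#' Read and write region-of-interest block lists
#'
#' The ROI file is JSON with fields `block_shape` (voxels per block along
#' z,y,x), `bounds_offset`, `bounds_shape` (the global box being tiled) and
#' `blocks`, a list of `[bz, by, bx]` 0-based block indices forming the
#' region of interest.
#'
#' @param path JSON file.
#' @param grid a [grid_spec] (see [partition_grid()]).
#' @return `read_roi()` returns a [grid_spec] restricted to the listed
#'   blocks.
#' @export
read_roi <- function(path) {
  r <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  grid <- partition_grid(bounds = list(offset = as.integer(r$bounds_offset),
                                       shape = as.integer(r$bounds_shape)),
                         block_shape = as.integer(r$block_shape))
  idx <- matrix(as.integer(as.matrix(r$blocks)), ncol = 3L)
  restrict_grid(grid, idx)
}

#' @rdname read_roi
#' @export
write_roi <- function(grid, path) {
  blocks <- as.matrix(grid$blocks[, list(iz, iy, ix)])
  dimnames(blocks) <- NULL
  writeLines(jsonlite::toJSON(list(
    block_shape = grid$block_shape,
    bounds_offset = grid$offset, bounds_shape = grid$shape,
    blocks = blocks), digits = NA), path)
  invisible(path)
}
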