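#' Run a full segmentation evaluation
#'
#' Drives the whole pipeline at summary, per-body and subvolume
#' granularity: load inputs, restrict to the region of interest, optional
#' sparse filtering and ground-truth orphan filtering, optional boundary
#' dilation of the reference, grid partitioning, local then global
#' connected components, per-block contingency tables merged into
#' whole-volume tables, and every applicable metric. Per-block stages obey
#' the merge contract, so results do not depend on the block shape. In
#' self-compare mode (no reference volume) only the ground-truth-free
#' statistics are computed.
#'
#' @param test test segmentation: a [label_volume()] or a zarr path.
#' @param groundtruth reference volume (or zarr path); `NULL` for
#'   self-compare mode.
#' @param synapses synapse table, or a JSON/CSV path (see
#'   [read_synapses()]); enables the endpoint-domain and connectivity
#'   metrics.
#' @param roi a `grid_spec` (e.g. [read_roi()]) restricting evaluation to
#'   its blocks; default: all of the test volume, tiled by `block_shape`.
#' @param block_shape grid block shape in voxels when `roi` is `NULL`.
#' @param dilation_radius reference boundary dilation radius in voxels
#'   (see [dilate_gt_boundaries()]); 0 disables.
#' @param sparse treat the reference as sparsely traced: mask the test
#'   volume where the reference is unlabeled.
#' @param gt_min_size drop reference segments smaller than this many
#'   voxels before scoring; 0 disables.
#' @param downsample integer mode-pooling factor applied to both volumes
#'   (and synapse coordinates) before evaluation; 1 disables.
#' @param self_compare evaluate `test` alone, without a reference.
#' @param connectivity compute the connectivity metrics; errors if
#'   requested without `synapses`.
#' @param orphan_k orphan threshold K (synapse endpoints per segment, or
#'   voxels when no synapses are given).
#' @param completeness completeness percentages X for the thresholded
#'   fragmentation / segments-to-threshold statistics.
#' @param cc_thresholds list of `list(k =, inclusive =)` settings for
#'   [cc_thresholded()].
#' @param match_method assignment method for [match_segments()].
#' @param top_n per-body lists are truncated to the worst/best `top_n`.
#' @return An `evaluation_report`: list with `schema_version`, `metadata`,
#'   `summary`, `bodies`, `subvolumes`, `unsupervised`. Serialize with
#'   [write_report()].
#' @export
run_evaluation <- function(test, groundtruth = NULL, synapses = NULL, roi = NULL,
                           block_shape = c(64L, 64L, 64L), dilation_radius = 2,
                           sparse = FALSE, gt_min_size = 0L, downsample = 1L,
                           self_compare = is.null(groundtruth),
                           connectivity = !is.null(synapses),
                           orphan_k = 10L, completeness = c(50, 75, 90),
                           cc_thresholds = list(list(k = 0L, inclusive = FALSE),
                                                list(k = 9L, inclusive = TRUE)),
                           match_method = c("greedy", "optimal"), top_n = 50L) {
  match_method <- match.arg(match_method)
  if (is.character(test)) test <- read_label_volume(test)
  if (is.character(groundtruth)) groundtruth <- read_label_volume(groundtruth)
  if (is.character(synapses)) synapses <- read_synapses(synapses)
  if (is.character(roi)) roi <- read_roi(roi)
  if (!self_compare && is.null(groundtruth))
    stop("supervised evaluation needs a reference volume; set self_compare = TRUE to evaluate the test volume alone")
  if (connectivity && is.null(synapses))
    stop("connectivity metrics require a synapse list")

  if (downsample > 1L) {
    test <- downsample_labels(test, downsample)
    if (!is.null(groundtruth)) groundtruth <- downsample_labels(groundtruth, downsample)
    if (!is.null(synapses)) synapses <- downsample_synapses(synapses, downsample)
  }
  grid <- roi %||% grid_for_volume(test, block_shape)
  S <- vol_restrict(test, grid)

  meta <- list(
    tool = "conneval", version = as.character(packageVersion("conneval")),
    schema = 1L,
    parameters = list(block_shape = grid$block_shape,
                      dilation_radius = dilation_radius, sparse = sparse,
                      gt_min_size = gt_min_size, downsample = downsample,
                      self_compare = self_compare, orphan_k = orphan_k,
                      completeness = completeness, match_method = match_method,
                      top_n = top_n),
    inputs = list(test_shape = lv_shape(S), test_offset = S$offset,
                  n_roi_blocks = nrow(grid$blocks),
                  n_synapses = if (is.null(synapses)) 0L else nrow(synapses)))

  unsup <- unsupervised_stats(S, synapses, orphan_k, completeness, grid)

  if (self_compare) {
    rep <- structure(list(schema_version = 1L, metadata = meta,
                          summary = list(unsupervised = unsup$summary),
                          bodies = unsup$bodies,
                          subvolumes = list(orphan_density = unsup$per_block),
                          unsupervised = unsup$summary),
                     class = "evaluation_report")
    return(rep)
  }

  G <- vol_restrict(groundtruth, grid)
  if (!same_bbox(S, G)) stop("test and reference volumes must cover the same bounding box")
  if (gt_min_size > 0L) G <- filter_small_orphans_gt(G, gt_min_size)
  if (sparse) S <- filter_sparse_bodies(S, G)$S

  # component structure is computed before boundary dilation: dilation is a
  # comparison-domain filter for the voxel metrics, not a topology change,
  # and the endpoint-domain metrics resolve against the undilated reference
  Scc <- connected_components_volume(S, grid)
  Gcc <- connected_components_volume(G, grid)
  Gvox <- Gcc$volume
  if (dilation_radius > 0) Gvox <- dilate_gt_boundaries(Gvox, dilation_radius)

  # blockwise voxel tables, merged: the parallelism seam
  tvox <- empty_contingency("voxels")
  for (i in seq_len(nrow(grid$blocks))) {
    b <- grid$blocks[i]
    tvox <- merge_contingency(tvox, build_contingency(vol_block(Scc$volume, b),
                                                      vol_block(Gvox, b)))
  }
  if (tvox$total == 0) stop("no comparison points: the volumes share no labeled voxels")

  summary <- list()
  vvox <- vi(tvox)
  summary$voxels <- list(
    n_points = tvox$total, ignored = tvox$ignored,
    n_test_segments = length(unique(tvox$counts$s)),
    n_reference_segments = length(unique(tvox$counts$g)),
    vi_over = vvox$oversegmentation, vi_under = vvox$undersegmentation,
    vi_total = vvox$total,
    rand = rand_index(tvox), adjusted_rand = rand_index(tvox, adjusted = TRUE),
    frag = frag(tvox),
    frag_thresholded = frag_threshold_block(ct_sizes_s(tvox), ct_sizes_g(tvox),
                                            completeness))

  bodies <- list()
  over_g <- body_vi_decomposition(tvox)
  under_s <- body_vi_decomposition(transpose_contingency(tvox))
  bodies$worst_oversegmented <- top_table(over_g, "vi_over_bits", top_n, Gcc$provenance)
  bodies$worst_undersegmented <- top_table(under_s, "vi_under_bits", top_n, Scc$provenance)
  bb <- best_bodies_by_overlap(tvox)
  bodies$best_by_overlap <- head(as.data.frame(bb), top_n)
  bodies$worst_by_overlap <- head(as.data.frame(bb[rev(seq_len(nrow(bb)))]), top_n)

  if (!is.null(synapses)) {
    tep <- build_contingency(Scc$volume, Gcc$volume, "synapse_endpoints",
                             points = synapse_endpoints(synapses))
    if (tep$total > 0) {
      vep <- vi(tep)
      summary$synapse_endpoints <- list(
        n_points = tep$total, ignored = tep$ignored,
        vi_over = vep$oversegmentation, vi_under = vep$undersegmentation,
        vi_total = vep$total,
        rand = rand_index(tep), frag = frag(tep),
        frag_thresholded = frag_threshold_block(ct_sizes_s(tep), ct_sizes_g(tep),
                                                completeness))
      ep_over <- body_vi_decomposition(tep)
      bodies$worst_oversegmented_synaptic <-
        top_table(ep_over, "vi_over_bits", top_n, Gcc$provenance)
    }
    if (connectivity) {
      Sg <- connection_graph(Scc$volume, synapses)
      Gg <- connection_graph(Gcc$volume, synapses)
      if (nrow(Gg$edges) == 0L)
        stop("no ground-truth connections resolve inside the ROI")
      A <- match_segments(tep, method = match_method)
      thr <- lapply(cc_thresholds, function(th) {
        r <- cc_thresholded(Sg, Gg, A, k = th$k, inclusive = isTRUE(th$inclusive))
        list(k = th$k, inclusive = isTRUE(th$inclusive),
             recall = r$recall, precision = r$precision)
      })
      summary$connectivity <- list(
        n_connections = Gg$n_input,
        n_resolved_reference = nrow(Gg$edges), unresolved_reference = Gg$unresolved,
        n_resolved_test = nrow(Sg$edges), unresolved_test = Sg$unresolved,
        cc = connectivity_correctness(Sg, Gg, A),
        thresholded = thr)
      cov <- body_connection_coverage(Gg, Sg, A)
      setorder(cov, coverage, g)
      bodies$worst_connection_coverage <- head(as.data.frame(cov), top_n)
    }
  }
  summary$unsupervised <- unsup$summary

  sv <- subvolume_vi(Scc$volume, Gvox, grid)
  subvolumes <- list(vi = as.data.frame(sv), orphan_density = unsup$per_block)

  structure(list(schema_version = 1L, metadata = meta, summary = summary,
                 bodies = bodies, subvolumes = subvolumes,
                 unsupervised = unsup$summary),
            class = "evaluation_report")
}

unsupervised_stats <- function(S, synapses, orphan_k, completeness, grid) {
  sizes <- segment_sizes(S)
  kind <- if (is.null(synapses)) "voxels" else "synapse_endpoints"
  orp <- orphan_count(S, synapses, K = orphan_k, kind = kind, grid = grid)
  summary <- list(
    n_segments = length(sizes),
    orphan_threshold = orp$K, orphan_kind = orp$kind,
    orphan_count = orp$n_orphans,
    segments_to_threshold_voxels = stats::setNames(
      lapply(completeness, function(p) segments_to_threshold(sizes, p)),
      paste0("pct", completeness)))
  if (!is.null(synapses)) {
    sl <- self_loop_report(S, synapses)
    summary$autapse_total <- sl$total
    summary$autapse_outliers <- head(as.data.frame(sl$per_label), 10L)
    ep_sizes <- orphan_count(S, synapses, K = orphan_k,
                             kind = "synapse_endpoints")$sizes
    summary$segments_to_threshold_endpoints <- stats::setNames(
      lapply(completeness, function(p)
        if (sum(ep_sizes) > 0) segments_to_threshold(ep_sizes, p) else NA_integer_),
      paste0("pct", completeness))
  }
  list(summary = summary,
       per_block = as.data.frame(heatmap_export(orp$per_block, grid)),
       bodies = list())
}

frag_threshold_block <- function(sizes_S, sizes_G, completeness) {
  stats::setNames(lapply(completeness, function(p) frag_thresholded(sizes_S, sizes_G, p)),
                  paste0("pct", completeness))
}

# Worst-first table from a per-label decomposition, with original labels
# attached when the volumes were relabeled by connected components.
top_table <- function(decomp, col, top_n, provenance = NULL) {
  dt <- data.table(label = as.integer(names(decomp)), value = as.numeric(decomp))
  setorder(dt, -value, label)
  setnames(dt, "value", col)
  if (!is.null(provenance) && nrow(provenance))
    dt[, orig_label := provenance$orig[match(label, provenance$final)]]
  head(as.data.frame(dt), top_n)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  if (!is.null(x$summary$voxels))
    cat(sprintf("  voxels: VI %.4f (over %.4f / under %.4f), Rand %.4f, frag %d\n",
                x$summary$voxels$vi_total, x$summary$voxels$vi_over,
                x$summary$voxels$vi_under, x$summary$voxels$rand,
                x$summary$voxels$frag))
  if (!is.null(x$summary$synapse_endpoints))
    cat(sprintf("  endpoints: VI %.4f, frag %d\n",
                x$summary$synapse_endpoints$vi_total, x$summary$synapse_endpoints$frag))
  if (!is.null(x$summary$connectivity))
    cat(sprintf("  connectivity correctness: %.4f over %d connection(s)\n",
                x$summary$connectivity$cc, x$summary$connectivity$n_resolved_reference))
  cat(sprintf("  unsupervised: %d segment(s), %d orphan(s)",
              x$summary$unsupervised$n_segments, x$summary$unsupervised$orphan_count))
  if (!is.null(x$summary$unsupervised$autapse_total))
    cat(sprintf(", %d autapse(s)", x$summary$unsupervised$autapse_total))
  cat("\n")
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' The payload is deterministic: identical inputs and parameters produce
#' byte-identical files (no timestamps are embedded).
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyVector = TRUE),
            class = "evaluation_report")
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Compare the summaries of two evaluation reports
#'
#' Flattens both summaries to named numbers, compares them on the shared
#' metrics, and orients each difference (lower is better for VI,
#' fragmentation, orphan and autapse counts; higher is better for Rand,
#' connectivity correctness, recall/precision and coverage). Metrics
#' present in only one report are dropped with a warning.
#'
#' @param a,b `evaluation_report`s (or paths to serialized reports).
#' @return data.frame with columns `metric`, `a`, `b`, `diff`, `better`
#'   (`"a"`, `"b"`, `"tie"`, or `NA` for unoriented metrics).
#' @export
compare_reports <- function(a, b) {
  if (is.character(a)) a <- read_report(a)
  if (is.character(b)) b <- read_report(b)
  fa <- flatten_numeric(a$summary)
  fb <- flatten_numeric(b$summary)
  shared <- intersect(names(fa), names(fb))
  only <- c(setdiff(names(fa), names(fb)), setdiff(names(fb), names(fa)))
  if (length(only))
    warning("metrics present in only one report were dropped: ",
            paste(only, collapse = ", "))
  if (length(shared) == 0L) {
    return(data.frame(metric = character(), a = numeric(), b = numeric(),
                      diff = numeric(), better = character()))
  }
  lower <- grepl("vi_|frag|orphan|autapse|ignored|unresolved|segments_to",
                 shared, ignore.case = TRUE)
  higher <- grepl("rand|\\bcc\\b|recall|precision|coverage|fraction",
                  shared, ignore.case = TRUE)
  dir <- ifelse(lower, -1, ifelse(higher, 1, NA))
  av <- fa[shared]; bv <- fb[shared]
  better <- rep(NA_character_, length(shared))
  cmp <- sign(bv - av) * dir
  better[!is.na(cmp) & cmp > 0] <- "b"
  better[!is.na(cmp) & cmp < 0] <- "a"
  better[!is.na(cmp) & cmp == 0] <- "tie"
  data.frame(metric = shared, a = as.numeric(av), b = as.numeric(bv),
             diff = as.numeric(bv - av), better = better,
             stringsAsFactors = FALSE)
}

flatten_numeric <- function(x, prefix = NULL) {
  out <- numeric(0)
  if (is.list(x) && !is.data.frame(x)) {
    nms <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x)) {
      out <- c(out, flatten_numeric(x[[i]], c(prefix, nms[i])))
    }
  } else if (is.numeric(x) && length(x) == 1L && !is.na(x)) {
    out <- stats::setNames(x, paste(prefix, collapse = "."))
  }
  out
}
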