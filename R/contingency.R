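#' Sparse contingency tables between two labelings
#'
#' The joint count of comparison points per (test label, reference label)
#' pair is the single sufficient statistic behind every supervised metric
#' here: VI, Rand, per-body decompositions, segment matching and
#' fragmentation are all functions of it. Tables are sparse (label ids may
#' be large and non-contiguous) and mergeable, so per-block tables built
#' independently can be combined into the whole-volume table — the seam
#' that lets evaluation run blockwise over arbitrarily large volumes.
#'
#' Comparison points are either all voxels of the shared bounding box or a
#' supplied set of coordinates (synapse endpoints). Points where either
#' labeling is 0 are excluded from the table; their number is kept in
#' `$ignored`.
#'
#' @param S test [label_volume()].
#' @param G reference [label_volume()] covering the same bounding box.
#' @param domain `"voxels"` or `"synapse_endpoints"`.
#' @param points for the endpoint domain, an `n x 3` matrix of global
#'   `(z, y, x)` coordinates (see [read_synapses()]); each synapse
#'   contributes its pre and its post site as one point each.
#' @return A `contingency_table`: list with `counts` (data.table `s`, `g`,
#'   `n`, sorted), `total`, `domain`, `ignored`.
#' @examples
#' G <- label_volume(array(rep(c(1L, 2L), each = 4), dim = c(2, 2, 2)))
#' S <- label_volume(array(c(10L, 10L, 10L, 10L, 20L, 20L, 21L, 21L), dim = c(2, 2, 2)))
#' build_contingency(S, G)
#' @export
build_contingency <- function(S, G, domain = c("voxels", "synapse_endpoints"),
                              points = NULL) {
  domain <- match.arg(domain)
  stopifnot(inherits(S, "label_volume"), inherits(G, "label_volume"))
  if (!same_bbox(S, G))
    stop("S and G must cover the same global bounding box (shape/offset mismatch)")
  if (domain == "voxels") {
    s <- as.vector(S$data)
    g <- as.vector(G$data)
  } else {
    if (is.null(points) || nrow(as_points(points)) == 0L)
      stop("synapse_endpoints domain requires a nonempty set of points")
    points <- as_points(points)
    s <- label_at(S, points)
    g <- label_at(G, points)
  }
  keep <- s != 0L & g != 0L
  counts <- data.table(s = s[keep], g = g[keep])[, list(n = .N), by = list(s, g)]
  setorder(counts, s, g)
  new_contingency(counts, domain, ignored = sum(!keep))
}

new_contingency <- function(counts, domain, ignored = 0L) {
  structure(list(counts = counts, total = sum(counts$n),
                 domain = domain, ignored = as.integer(ignored)),
            class = "contingency_table")
}

#' Empty contingency table
#' @param domain `"voxels"` or `"synapse_endpoints"`.
#' @return A `contingency_table` with no entries; the identity element of
#'   [merge_contingency()].
#' @export
empty_contingency <- function(domain = "voxels") {
  new_contingency(data.table(s = integer(), g = integer(), n = integer()), domain)
}

#' Merge two blockwise contingency tables
#'
#' Entrywise addition: the table of a whole volume equals the merge of the
#' tables of any blockwise partition of it. Merging is associative and
#' commutative, so per-block tables may be combined in any order (or in
#' parallel) without changing the result.
#'
#' @param a,b `contingency_table`s over the same comparison domain.
#' @return The combined `contingency_table`.
#' @export
merge_contingency <- function(a, b) {
  stopifnot(inherits(a, "contingency_table"), inherits(b, "contingency_table"))
  if (!identical(a$domain, b$domain))
    stop("cannot merge contingency tables over different comparison domains")
  counts <- rbind(a$counts, b$counts)[, list(n = sum(n)), by = list(s, g)]
  setorder(counts, s, g)
  new_contingency(counts, a$domain, ignored = a$ignored + b$ignored)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %d entries, %d %s (%d ignored), %d test x %d reference segments\n",
              nrow(x$counts), x$total, x$domain, x$ignored,
              length(unique(x$counts$s)), length(unique(x$counts$g))))
  invisible(x)
}

# Swap the roles of test and reference labels.
transpose_contingency <- function(t) {
  counts <- t$counts[, list(s = g, g = s, n = n)]
  setorder(counts, s, g)
  new_contingency(counts, t$domain, t$ignored)
}

# Marginal sizes (comparison-point counts) per reference / test label.
ct_sizes_g <- function(t) {
  m <- t$counts[, list(n = sum(n)), by = g]
  setorder(m, g)
  stats::setNames(m$n, m$g)
}

ct_sizes_s <- function(t) {
  m <- t$counts[, list(n = sum(n)), by = s]
  setorder(m, s)
  stats::setNames(m$n, m$s)
}
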