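#' Single-linkage dendrogram from a dissimilarity matrix
#'
#' Agglomerative clustering with the nearest-distance (single linkage) rule:
#' the distance between two clusters is the minimum pairwise dissimilarity
#' between their members. Starting from singletons, the closest pair of
#' clusters is merged repeatedly until one cluster remains; merge heights are
#' non-decreasing. Ties are broken deterministically in favour of the
#' lexicographically smallest pair of cluster indices (clusters keep the
#' position of their smaller constituent).
#'
#' @param d A `chem_dissim` object or a symmetric, zero-diagonal,
#'   non-negative numeric matrix with row and column names.
#' @return A `chem_dendrogram` object: `labels` plus a `merges` tibble with
#'   one row per merge (`step`, `height`, `cluster_a`, `cluster_b`,
#'   list-columns `members_a`, `members_b`, `members` of sorted leaf labels).
#'   Supports `tidy()`, `glance()`, `autoplot()`, `as.hclust()` and
#'   [to_newick()].
#' @examples
#' comp <- composition_from_counts(load_fixture("table3_counts"))
#' single_linkage(chem_dissimilarity(comp))
#' @export
single_linkage <- function(d) {
  if (inherits(d, "chem_dissim")) d <- d$matrix
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 2L) {
    rlang::abort("`d` must be a square matrix with n >= 2.",
                 class = "chemgroups_bad_input")
  }
  if (is.null(rownames(d))) {
    dimnames(d) <- list(paste0("S", seq_len(nrow(d))),
                        paste0("S", seq_len(nrow(d))))
  }
  if (any(d < 0) || any(abs(d - t(d)) > 1e-8) || any(diag(d) != 0)) {
    rlang::abort("`d` must be symmetric with zero diagonal and no negative entries.",
                 class = "chemgroups_bad_input")
  }
  labels <- rownames(d)
  n <- length(labels)

  # active clusters as leaf index sets; merged cluster keeps the smaller slot
  clusters <- as.list(seq_len(n))
  hid <- as.list(-seq_len(n)) # hclust-style id: negative leaf, positive step
  cur <- d
  active <- rep(TRUE, n)
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    best <- NULL
    for (ai in seq_along(act)) {
      for (aj in seq_along(act)) {
        if (aj <= ai) next
        i <- act[ai]; j <- act[aj]
        v <- cur[i, j]
        if (is.null(best) || v < best$v) best <- list(i = i, j = j, v = v)
      }
    }
    i <- best$i; j <- best$j
    lab <- function(k) paste0("{", paste(sort(labels[clusters[[k]]]),
                                         collapse = ","), "}")
    merges[[step]] <- tibble::tibble(
      step = step, height = best$v,
      cluster_a = lab(i), cluster_b = lab(j),
      members_a = list(sort(labels[clusters[[i]]])),
      members_b = list(sort(labels[clusters[[j]]])),
      members = list(sort(labels[c(clusters[[i]], clusters[[j]])])),
      id_a = hid[[i]], id_b = hid[[j]]
    )
    # single linkage: distance to the merged cluster is the minimum
    for (k in which(active)) {
      if (k == i || k == j) next
      cur[i, k] <- cur[k, i] <- min(cur[i, k], cur[j, k])
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    hid[[i]] <- step
    active[j] <- FALSE
  }
  structure(
    list(labels = labels, merges = dplyr::bind_rows(merges)),
    class = "chem_dendrogram"
  )
}

#' @export
print.chem_dendrogram <- function(x, ...) {
  cat(sprintf("Single-linkage dendrogram of %d leaves\n", length(x$labels)))
  print(dplyr::select(x$merges, "step", "cluster_a", "cluster_b", "height"))
  invisible(x)
}

#' @rdname single_linkage
#' @param x A `chem_dendrogram`.
#' @param ... Unused.
#' @export
tidy.chem_dendrogram <- function(x, ...) {
  dplyr::select(x$merges, "step", "cluster_a", "cluster_b", "height")
}

#' @rdname single_linkage
#' @export
glance.chem_dendrogram <- function(x, ...) {
  tibble::tibble(
    n_leaves = length(x$labels),
    n_merges = nrow(x$merges),
    height = max(x$merges$height)
  )
}

# leaf ordering that keeps each merge contiguous (for plotting / hclust)
.leaf_order <- function(tree) {
  merged <- vector("list", nrow(tree$merges))
  get_order <- function(id) {
    if (id < 0) return(-id)
    merged[[id]]
  }
  for (s in seq_len(nrow(tree$merges))) {
    m <- tree$merges[s, ]
    merged[[s]] <- c(get_order(m$id_a), get_order(m$id_b))
  }
  merged[[nrow(tree$merges)]]
}

#' @export
as.hclust.chem_dendrogram <- function(x, ...) {
  m <- x$merges
  structure(
    list(
      merge = cbind(m$id_a, m$id_b),
      height = m$height,
      order = .leaf_order(x),
      labels = x$labels,
      method = "single",
      dist.method = "chemical group L1 (%)",
      call = match.call()
    ),
    class = "hclust"
  )
}

#' Serialize a dendrogram as Newick
#'
#' Emits a rooted Newick string with ultrametric display branch lengths:
#' every branch length is half the height difference between parent and
#' child merge (leaves sit at height 0), so leaf-to-leaf path lengths equal
#' cophenetic merge heights.
#'
#' @param tree A `chem_dendrogram`.
#' @param digits Rounding for branch lengths (default 6).
#' @return A Newick string terminated by `";"`.
#' @examples
#' d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' to_newick(single_linkage(d)) # "(A:1,B:1);"
#' @export
to_newick <- function(tree, digits = 6) {
  if (!inherits(tree, "chem_dendrogram")) {
    rlang::abort("`tree` must be a chem_dendrogram.", class = "chemgroups_bad_input")
  }
  fmt <- function(x) formatC(x, digits = digits, format = "fg", flag = "#") |>
    sub("\\.?0*$", "", x = _)
  node <- function(id) {
    if (id < 0) return(list(nwk = tree$labels[-id], h = 0))
    m <- tree$merges[id, ]
    a <- node(m$id_a); b <- node(m$id_b)
    list(
      nwk = sprintf("(%s:%s,%s:%s)",
                    a$nwk, fmt((m$height - a$h) / 2),
                    b$nwk, fmt((m$height - b$h) / 2)),
      h = m$height
    )
  }
  paste0(node(nrow(tree$merges))$nwk, ";")
}

#' Write the merge table of a dendrogram as TSV
#'
#' @param tree A `chem_dendrogram`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_merges_tsv <- function(tree, path) {
  readr::write_tsv(tidy(tree), path)
  invisible(path)
}

#' @rdname single_linkage
#' @param object A `chem_dendrogram`.
#' @export
autoplot.chem_dendrogram <- function(object, ...) {
  ord <- .leaf_order(object)
  xpos <- stats::setNames(seq_along(ord), object$labels[ord])
  cl_x <- as.list(xpos[object$labels]) # per hclust id
  cl_h <- rep(0, length(object$labels))
  segs <- list()
  getx <- function(id) if (id < 0) xpos[object$labels[-id]] else node_x[id]
  geth <- function(id) if (id < 0) 0 else object$merges$height[id]
  node_x <- numeric(nrow(object$merges))
  for (s in seq_len(nrow(object$merges))) {
    m <- object$merges[s, ]
    xa <- getx(m$id_a); xb <- getx(m$id_b)
    ha <- geth(m$id_a); hb <- geth(m$id_b)
    node_x[s] <- mean(c(xa, xb))
    segs[[s]] <- tibble::tibble(
      x = c(xa, xb, xa), xend = c(xa, xb, xb),
      y = c(ha, hb, m$height), yend = c(m$height, m$height, m$height)
    )
  }
  leaves <- tibble::tibble(x = unname(xpos), label = names(xpos))
  ggplot2::ggplot(dplyr::bind_rows(segs)) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend
    )) +
    ggplot2::geom_text(
      data = leaves,
      ggplot2::aes(.data$x, -0.02 * max(object$merges$height), label = .data$label),
      vjust = 1
    ) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::labs(x = NULL, y = "dissimilarity (%)") +
    ggplot2::theme_minimal()
}
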