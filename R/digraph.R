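#' Order-pair directed graph of a reduced sequence
#'
#' Reads the reduced sequence as consecutive ordered pairs
#' (T(i), T(i+1)) and records each pair as a directed edge between group
#' codes. Nodes are the codes 1..8 that occur in the sequence; self-loops
#' (two consecutive residues from the same group) are legal edges. Besides
#' the binary adjacency matrix the multiplicity of every edge and the list
#' of 1-based source positions realizing it are kept, so that edge
#' occurrences can be mapped back onto residue coordinates.
#'
#' @param x A reduced sequence: digit string, integer vector of codes in
#'   1..8, or a one-row data frame carrying a `reduced` column.
#' @param id Optional sequence id (taken from the data frame if present).
#' @return A `chem_digraph` object with fields `id`, `adjacency` (8x8
#'   binary), `multiplicity` (8x8 counts, summing to L-1), `positions`
#'   (named list, `"uv"` -> integer source positions) and `nodes`.
#' @examples
#' build_digraph("624621")
#' @export
build_digraph <- function(x, id = NULL) {
  if (is.data.frame(x)) {
    .check_seqs(x, require = "reduced")
    if (nrow(x) != 1L) {
      rlang::abort("`x` must contain exactly one sequence; see `digraphs()`.",
                   class = "chemgroups_bad_input")
    }
    id <- id %||% x$id
    x <- x$reduced
  }
  codes <- .as_codes(x)
  if (length(codes) < 2L) {
    rlang::abort("Need a reduced sequence of length >= 2 to form order pairs.",
                 class = "chemgroups_bad_input")
  }
  from <- codes[-length(codes)]
  to <- codes[-1L]
  mult <- matrix(0L, 8, 8, dimnames = list(1:8, 1:8))
  for (i in seq_along(from)) {
    mult[from[i], to[i]] <- mult[from[i], to[i]] + 1L
  }
  key <- paste0(from, to)
  positions <- split(seq_along(from), key)
  structure(
    list(
      id = id %||% "seq",
      adjacency = (mult > 0L) + 0L,
      multiplicity = mult,
      positions = positions,
      nodes = sort(unique(codes))
    ),
    class = "chem_digraph"
  )
}

#' Order-pair digraphs for a table of sequences
#'
#' @param seqs A data frame with columns `id` and `reduced` (or `sequence`,
#'   which is reduced first).
#' @return A named list of `chem_digraph` objects, one per row.
#' @export
digraphs <- function(seqs) {
  if (!"reduced" %in% names(seqs)) seqs <- reduce_sequences(seqs)
  .check_seqs(seqs, require = "reduced")
  gs <- purrr::map2(seqs$reduced, seqs$id, build_digraph)
  stats::setNames(gs, seqs$id)
}

#' @export
print.chem_digraph <- function(x, ...) {
  cat(sprintf("Order-pair digraph '%s': %d nodes, %d edges, total multiplicity %d\n",
              x$id, length(x$nodes), sum(x$adjacency), sum(x$multiplicity)))
  invisible(x)
}

#' Edge set of an order-pair digraph
#'
#' @param g A `chem_digraph`.
#' @return A tibble of ordered pairs (`from`, `to`) with adjacency 1, plus
#'   the compact `edge` label (e.g. `"82"` for the edge 8 -> 2).
#' @export
edge_set <- function(g) {
  idx <- which(g$adjacency == 1L, arr.ind = TRUE)
  tibble::tibble(
    from = as.integer(idx[, 1]), to = as.integer(idx[, 2])
  ) |>
    dplyr::arrange(.data$from, .data$to) |>
    dplyr::mutate(edge = paste0(.data$from, .data$to))
}

#' @rdname build_digraph
#' @param ... Unused.
#' @export
tidy.chem_digraph <- function(x, ...) {
  edge_set(x) |>
    dplyr::mutate(
      multiplicity = as.integer(x$multiplicity[cbind(from, to)]),
      positions = unname(x$positions[.data$edge])
    )
}

#' @rdname build_digraph
#' @export
glance.chem_digraph <- function(x, ...) {
  tibble::tibble(
    id = x$id,
    n_nodes = length(x$nodes),
    n_edges = sum(x$adjacency),
    length = sum(x$multiplicity) + 1L
  )
}

#' Compare edge sets between two groups of digraphs
#'
#' Contrasts two sets of sequences through their order-pair digraphs. An
#' edge is *unique to group A* when it is present in every member of A and
#' in no member of B (and vice versa); it is *common to all* when present
#' in every member of both groups.
#'
#' @param group_a,group_b Non-empty lists of `chem_digraph` objects (or a
#'   single `chem_digraph`).
#' @return A tibble with one row per edge present in at least one digraph:
#'   `from`, `to`, `edge`, presence counts `n_a`/`n_b`, logical
#'   `in_all_a`/`in_all_b`/`in_any_a`/`in_any_b`, and `status` in
#'   `"unique_to_a"`, `"unique_to_b"`, `"common_to_all"`, `"partial"`.
#' @examples
#' a <- build_digraph("1212821")
#' b <- build_digraph("1212731")
#' compare_edge_sets(a, b)
#' @export
compare_edge_sets <- function(group_a, group_b) {
  as_group <- function(g, nm) {
    if (inherits(g, "chem_digraph")) g <- list(g)
    if (!is.list(g) || length(g) == 0L ||
        !all(vapply(g, inherits, TRUE, "chem_digraph"))) {
      rlang::abort(sprintf("`%s` must be a non-empty list of chem_digraph objects.", nm),
                   class = "chemgroups_bad_input")
    }
    g
  }
  group_a <- as_group(group_a, "group_a")
  group_b <- as_group(group_b, "group_b")
  count_mat <- function(gs) Reduce(`+`, purrr::map(gs, "adjacency"))
  na <- count_mat(group_a); nb <- count_mat(group_b)
  idx <- which(na + nb > 0L, arr.ind = TRUE)
  out <- tibble::tibble(
    from = as.integer(idx[, 1]),
    to = as.integer(idx[, 2]),
    edge = paste0(.data$from, .data$to),
    n_a = as.integer(na[idx]),
    n_b = as.integer(nb[idx])
  ) |>
    dplyr::mutate(
      in_all_a = .data$n_a == length(group_a),
      in_any_a = .data$n_a > 0L,
      in_all_b = .data$n_b == length(group_b),
      in_any_b = .data$n_b > 0L,
      status = dplyr::case_when(
        in_all_a & !in_any_b ~ "unique_to_a",
        in_all_b & !in_any_a ~ "unique_to_b",
        in_all_a & in_all_b ~ "common_to_all",
        TRUE ~ "partial"
      )
    ) |>
    dplyr::arrange(.data$from, .data$to)
  out
}

#' Export an order-pair digraph as DOT
#'
#' @param g A `chem_digraph`.
#' @param path Output file.
#' @param multiplicity Label edges with their multiplicities.
#' @return `path`, invisibly.
#' @export
write_dot <- function(g, path, multiplicity = FALSE) {
  ed <- tidy(g)
  lines <- c(
    sprintf("digraph \"%s\" {", g$id),
    sprintf("  %d [label=\"%d: %s\"];", g$nodes, g$nodes,
            .group_names[g$nodes]),
    if (multiplicity) {
      sprintf("  %d -> %d [label=\"%d\"];", ed$from, ed$to, ed$multiplicity)
    } else {
      sprintf("  %d -> %d;", ed$from, ed$to)
    },
    "}"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write adjacency or multiplicity matrix as labeled TSV
#'
#' @param g A `chem_digraph`.
#' @param path Output file.
#' @param what `"adjacency"` or `"multiplicity"`.
#' @return `path`, invisibly.
#' @export
write_adjacency_tsv <- function(g, path, what = c("adjacency", "multiplicity")) {
  what <- match.arg(what)
  m <- g[[what]]
  readr::write_tsv(tibble::as_tibble(m, rownames = "from"), path)
  invisible(path)
}

#' @rdname build_digraph
#' @param object A `chem_digraph`.
#' @export
autoplot.chem_digraph <- function(object, ...) {
  theta <- seq(0, 2 * pi, length.out = 9)[1:8] + pi / 2
  layout <- tibble::tibble(code = 1:8, x = cos(theta), y = sin(theta))
  ed <- tidy(object) |>
    dplyr::left_join(layout, by = c(from = "code")) |>
    dplyr::left_join(layout, by = c(to = "code"), suffix = c("", "_to"))
  straight <- dplyr::filter(ed, .data$from != .data$to)
  # pull arrows back from the node so heads stay visible
  shrink <- 0.12
  straight <- dplyr::mutate(
    straight,
    dx = .data$x_to - .data$x, dy = .data$y_to - .data$y,
    len = sqrt(.data$dx^2 + .data$dy^2),
    x1 = .data$x + shrink * .data$dx / .data$len,
    y1 = .data$y + shrink * .data$dy / .data$len,
    x2 = .data$x_to - shrink * .data$dx / .data$len,
    y2 = .data$y_to - shrink * .data$dy / .data$len
  )
  loops <- dplyr::filter(ed, .data$from == .data$to)
  nodes <- dplyr::filter(layout, .data$code %in% object$nodes)
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = straight,
      ggplot2::aes(x = .data$x1, y = .data$y1, xend = .data$x2, yend = .data$y2),
      arrow = ggplot2::arrow(length = ggplot2::unit(2.5, "mm")),
      colour = "grey30"
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 9, colour = "steelblue") +
    ggplot2::geom_text(data = nodes, ggplot2::aes(.data$x, .data$y,
                                                  label = .data$code),
                       colour = "white", fontface = "bold") +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::labs(title = object$id) +
    ggplot2::theme_void()
  if (nrow(loops) > 0) {
    p <- p + ggplot2::geom_point(
      data = dplyr::mutate(loops, x = 1.18 * .data$x, y = 1.18 * .data$y),
      ggplot2::aes(.data$x, .data$y),
      shape = 21, size = 5, colour = "grey30"
    )
  }
  p
}
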