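# Bounded DFS over simple directed cycles. Each cycle is discovered exactly
# once: the DFS is rooted at its smallest node and may only visit larger
# nodes, so the recorded path is already the canonical rotation.
.dfs_cycles <- function(adj, min_len, max_len) {
  found <- list()
  nodes <- which(rowSums(adj) + colSums(adj) > 0)
  for (s in nodes) {
    path <- integer(max_len)
    on_path <- rep(FALSE, 8L)
    rec <- function(u, depth) {
      if (adj[u, s] == 1L && depth >= min_len) {
        found[[length(found) + 1L]] <<- path[seq_len(depth)]
      }
      if (depth == max_len) return(invisible())
      for (v in which(adj[u, ] == 1L)) {
        if (v > s && !on_path[v]) {
          path[depth + 1L] <<- v
          on_path[v] <<- TRUE
          rec(v, depth + 1L)
          on_path[v] <<- FALSE
        }
      }
    }
    path[1L] <- s
    on_path[s] <- TRUE
    rec(s, 1L)
    on_path[s] <- FALSE
  }
  found
}

#' Canonical form of a directed cycle
#'
#' Rotates a simple directed cycle so that it starts at its smallest node
#' code; the closing repeat of the first node is omitted. Rotations of the
#' same directed cycle map to the same canonical form.
#'
#' @param nodes Integer vector of node codes visited in order (a trailing
#'   repeat of the first node is accepted and stripped), or a digit string.
#' @return Integer vector in canonical rotation.
#' @examples
#' canonical_cycle(c(3, 6, 2, 3)) # 2 3 6
#' @export
canonical_cycle <- function(nodes) {
  nodes <- .as_codes(nodes)
  if (length(nodes) > 1L && nodes[1] == nodes[length(nodes)]) {
    nodes <- nodes[-length(nodes)]
  }
  if (anyDuplicated(nodes)) {
    rlang::abort("Not a simple cycle: repeated intermediate node.",
                 class = "chemgroups_bad_input")
  }
  k <- which.min(nodes)
  if (k > 1L) nodes <- c(nodes[k:length(nodes)], nodes[seq_len(k - 1L)])
  nodes
}

.cycle_tibble <- function(node_lists) {
  if (length(node_lists) == 0L) {
    return(tibble::tibble(
      cycle = character(), closed = character(),
      length = integer(), nodes = list()
    ))
  }
  tibble::tibble(
    cycle = vapply(node_lists, paste, "", collapse = ""),
    closed = vapply(node_lists, function(n) paste(c(n, n[1]), collapse = ""), ""),
    length = lengths(node_lists),
    nodes = node_lists
  ) |> dplyr::arrange(.data$length, .data$cycle)
}

#' Enumerate bounded-length simple directed cycles
#'
#' Finds every simple directed cycle of the order-pair digraph whose edge
#' count lies between `min_len` and `max_len`. A simple cycle visits each
#' intermediate node at most once, so cycles never exceed 8 edges on the
#' 8-node group alphabet; the defaults 3..6 match the lengths used for
#' subdomain analysis. Each cycle is reported once in canonical form
#' (smallest node first, closing repeat omitted).
#'
#' @param g A `chem_digraph`.
#' @param min_len,max_len Cycle length bounds, `1 <= min_len <= max_len <= 8`.
#'   `min_len = 1` admits self-loops, `2` back-and-forth pairs.
#' @return A tibble with `cycle` (canonical digit string, e.g. `"236"`),
#'   `closed` (with the closing repeat, `"2362"`), `length` and the `nodes`
#'   list-column.
#' @examples
#' g <- build_digraph(c(2, 3, 6, 2))
#' enumerate_cycles(g)
#' @export
enumerate_cycles <- function(g, min_len = 3L, max_len = 6L) {
  if (!inherits(g, "chem_digraph")) {
    rlang::abort("`g` must be a chem_digraph.", class = "chemgroups_bad_input")
  }
  if (!(min_len >= 1L && min_len <= max_len && max_len <= 8L)) {
    rlang::abort("Need 1 <= min_len <= max_len <= 8.",
                 class = "chemgroups_bad_length_bounds")
  }
  .cycle_tibble(.dfs_cycles(g$adjacency, as.integer(min_len), as.integer(max_len)))
}

#' Is a cycle present in a digraph?
#'
#' Presence is edge-set-wise: a cycle is present when every one of its edges
#' occurs somewhere in the sequence as a consecutive order pair, not
#' necessarily as one contiguous traversal.
#'
#' @param cycle Node codes (vector or digit string, closing repeat optional).
#' @param g A `chem_digraph`.
#' @return `TRUE` or `FALSE`.
#' @export
cycle_present <- function(cycle, g) {
  nodes <- canonical_cycle(cycle)
  from <- nodes
  to <- c(nodes[-1L], nodes[1L])
  all(g$adjacency[cbind(from, to)] == 1L)
}

#' Group-unique cycles between two sets of digraphs
#'
#' A cycle is unique to group A when it is present (edge-set-wise) in every
#' member of A and in no member of B. Cycles present in all of A are exactly
#' the cycles of the intersection of the A edge sets.
#'
#' @param group_a,group_b Non-empty lists of `chem_digraph` objects (or a
#'   single digraph).
#' @param min_len,max_len Cycle length bounds as in [enumerate_cycles()].
#' @return A list with cycle tibbles `unique_to_a` and `unique_to_b`.
#' @export
unique_cycles <- function(group_a, group_b, min_len = 3L, max_len = 6L) {
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
  inter_adj <- function(gs) {
    Reduce(function(a, b) a * b, purrr::map(gs, "adjacency"))
  }
  side <- function(own, other) {
    cand <- .dfs_cycles(inter_adj(own), as.integer(min_len), as.integer(max_len))
    keep <- purrr::keep(cand, function(nodes) {
      from <- nodes
      to <- c(nodes[-1L], nodes[1L])
      !any(vapply(other, function(g) all(g$adjacency[cbind(from, to)] == 1L), TRUE))
    })
    .cycle_tibble(keep)
  }
  list(
    unique_to_a = side(group_a, group_b),
    unique_to_b = side(group_b, group_a)
  )
}

#' Subdomain windows realizing a cycle in a sequence
#'
#' Maps a cycle back onto residue coordinates: a window `[start, end]`
#' (1-based inclusive) is a candidate when it contains at least one
#' occurrence of every edge of the cycle, taking the edge occurrence at the
#' source position and extending the window to cover the target residue of
#' its rightmost edge (`end` = max source position + 1). Of all candidate
#' windows formed by choosing one occurrence per edge, only the minimal ones
#' (those not containing another candidate) are returned, sorted by start.
#'
#' @param cycle Node codes (vector or digit string).
#' @param g A `chem_digraph` in which the cycle is present.
#' @return A tibble with `start`, `end` and a `positions` list-column giving
#'   the chosen source position of every cycle edge (named by edge label).
#' @examples
#' cycle_subdomains(c(2, 3, 6), build_digraph(c(2, 3, 1, 6, 2, 3, 6, 2)))
#' @export
cycle_subdomains <- function(cycle, g) {
  nodes <- canonical_cycle(cycle)
  if (!cycle_present(nodes, g)) {
    rlang::abort("Cycle is not present in the digraph.",
                 class = "chemgroups_cycle_absent")
  }
  edges <- paste0(nodes, c(nodes[-1L], nodes[1L]))
  # sliding window over the pooled, sorted edge occurrences: every locally
  # minimal span covering all edges is a minimal candidate window
  occ <- dplyr::bind_rows(purrr::map(edges, function(e) {
    tibble::tibble(edge = e, pos = g$positions[[e]])
  })) |> dplyr::arrange(.data$pos, .data$edge)
  need <- unique(edges)
  have <- integer(0)
  counts <- stats::setNames(rep(0L, length(need)), need)
  lo <- 1L
  wins <- list()
  for (hi in seq_len(nrow(occ))) {
    counts[occ$edge[hi]] <- counts[occ$edge[hi]] + 1L
    while (counts[occ$edge[lo]] > 1L) {
      counts[occ$edge[lo]] <- counts[occ$edge[lo]] - 1L
      lo <- lo + 1L
    }
    if (all(counts > 0L)) {
      span <- occ[lo:hi, ]
      chosen <- span[!duplicated(span$edge, fromLast = TRUE), ]
      wins[[length(wins) + 1L]] <- tibble::tibble(
        start = occ$pos[lo], end = occ$pos[hi] + 1L,
        positions = list(stats::setNames(chosen$pos, chosen$edge)[need])
      )
      # retire the left endpoint to look for the next minimal window
      counts[occ$edge[lo]] <- counts[occ$edge[lo]] - 1L
      lo <- lo + 1L
    }
  }
  out <- dplyr::bind_rows(wins)
  if (nrow(out) == 0L) return(out)
  # drop any window containing another candidate (defensive; the sweep
  # already yields minimal windows)
  keep <- vapply(seq_len(nrow(out)), function(i) {
    !any(out$start >= out$start[i] & out$end <= out$end[i] &
           (out$start > out$start[i] | out$end < out$end[i]))
  }, TRUE)
  dplyr::arrange(out[keep, ], .data$start)
}

#' Cycle report across sequences
#'
#' Enumerates cycles per digraph and tabulates presence across all of them.
#'
#' @param graphs A named list of `chem_digraph` objects (see [digraphs()]).
#' @param min_len,max_len Bounds as in [enumerate_cycles()].
#' @return A tibble with `cycle`, `length` and one logical presence column
#'   per sequence id.
#' @export
cycle_report <- function(graphs, min_len = 3L, max_len = 6L) {
  per <- purrr::imap(graphs, function(g, nm) {
    dplyr::mutate(enumerate_cycles(g, min_len, max_len), id = nm)
  })
  all_cycles <- dplyr::bind_rows(per) |>
    dplyr::distinct(.data$cycle, .data$length)
  pres <- purrr::map(per, function(tb) all_cycles$cycle %in% tb$cycle)
  dplyr::bind_cols(all_cycles, tibble::as_tibble(pres)) |>
    dplyr::arrange(.data$length, .data$cycle)
}
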