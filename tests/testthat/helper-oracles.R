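# Independent oracles and small generators used across the suite.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

random_seq_table <- function(n_seqs, len_range = c(30, 90)) {
  tibble::tibble(
    id = paste0("s", seq_len(n_seqs)),
    sequence = vapply(
      sample(len_range[1]:len_range[2], n_seqs, replace = TRUE),
      random_protein, ""
    )
  )
}

random_adjacency <- function(p = 0.35, self_loops = TRUE) {
  m <- matrix(as.integer(stats::runif(64) < p), 8, 8,
              dimnames = list(1:8, 1:8))
  if (!self_loops) diag(m) <- 0L
  m
}

# wrap a bare adjacency matrix as a digraph object for the enumerator
digraph_from_adjacency <- function(adj) {
  structure(
    list(id = "adj", adjacency = adj, multiplicity = adj,
         positions = list(), nodes = sort(which(rowSums(adj) + colSums(adj) > 0))),
    class = "chem_digraph"
  )
}

# brute-force cycle oracle: closed simple walks started from EVERY node,
# deduplicated after rotating each to start at its smallest node
oracle_cycles <- function(adj, min_len, max_len) {
  found <- character(0)
  walk <- function(start, path) {
    u <- path[length(path)]
    if (adj[u, start] == 1L && length(path) >= min_len &&
        length(path) <= max_len) {
      k <- which.min(path)
      canon <- if (k > 1) c(path[k:length(path)], path[seq_len(k - 1)]) else path
      found[[length(found) + 1]] <<- paste(canon, collapse = "")
    }
    if (length(path) < max_len) {
      for (v in 1:8) {
        if (adj[u, v] == 1L && !(v %in% path)) walk(start, c(path, v))
      }
    }
  }
  for (s in 1:8) walk(s, s)
  sort(unique(found))
}

# L1 dissimilarity summed group by group, independent of the package path
oracle_dissimilarity <- function(pa, pb) {
  total <- 0
  for (k in 1:8) total <- total + abs(unname(pa[k]) - unname(pb[k]))
  total
}

# all-combinations subdomain oracle: one occurrence per cycle edge,
# window = [min pos, max pos + 1], keep only minimal windows
oracle_subdomains <- function(positions_per_edge) {
  combos <- expand.grid(positions_per_edge)
  wins <- unique(data.frame(
    start = apply(combos, 1, min),
    end = apply(combos, 1, max) + 1
  ))
  keep <- vapply(seq_len(nrow(wins)), function(i) {
    !any(wins$start >= wins$start[i] & wins$end <= wins$end[i] &
           (wins$start > wins$start[i] | wins$end < wins$end[i]))
  }, TRUE)
  wins <- wins[keep, ]
  wins[order(wins$start), ]
}

# printed 8-group percent table for the five cytochromes (4 decimals)
printed_group_percents <- rbind(
  PpcA = c(10.9890, 27.4725, 4.3956, 36.2637, 4.3956, 10.9890, 3.2967, 2.1978),
  PpcB = c(8.7912, 23.0769, 4.3956, 35.1648, 3.2967, 10.9890, 10.9890, 3.2967),
  PpcC = c(9.4737, 22.1053, 4.2105, 42.1053, 5.2632, 9.4737, 6.3158, 1.0526),
  PpcD = c(9.7826, 25.0000, 3.2609, 41.3043, 1.0870, 10.8696, 6.5217, 2.1739),
  PpcE = c(6.6667, 24.4444, 6.6667, 34.4444, 3.3333, 8.8889, 13.3333, 2.2222)
)

# printed pairwise dissimilarity matrix (upper triangle, 4 decimals)
printed_dissimilarity <- local({
  m <- matrix(0, 5, 5, dimnames = list(rownames(printed_group_percents),
                                       rownames(printed_group_percents)))
  m[upper.tri(m)] <- c(
    17.5824,
    19.4563, 19.1787,
    16.5313, 18.1080, 11.8535,
    24.6642, 12.0391, 25.9649, 25.0242
  )
  m + t(m)
})
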