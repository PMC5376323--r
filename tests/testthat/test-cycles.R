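complete_adjacency <- function(n = 8, self_loops = FALSE) {
  m <- matrix(0L, 8, 8, dimnames = list(1:8, 1:8))
  m[1:n, 1:n] <- 1L
  if (!self_loops) diag(m) <- 0L
  m
}

test_that("canonicalization is rotation-invariant and idempotent", {
  expect_identical(canonical_cycle(c(3, 6, 2)), c(2L, 3L, 6L))
  expect_identical(canonical_cycle(c(6, 2, 3)), c(2L, 3L, 6L))
  expect_identical(canonical_cycle("2362"), c(2L, 3L, 6L)) # closing repeat stripped
  expect_identical(canonical_cycle(canonical_cycle(c(7, 2, 1, 6, 4, 5))),
                   c(1L, 6L, 4L, 5L, 7L, 2L))
  expect_error(canonical_cycle(c(1, 2, 1, 3)), class = "chemgroups_bad_input")
})

test_that("the triangle digraph has exactly its two orientations as 3-cycles", {
  g <- digraph_from_adjacency(complete_adjacency(3))
  cyc <- enumerate_cycles(g, 3, 3)
  expect_setequal(cyc$cycle, c("123", "132"))
  expect_identical(cyc$closed[cyc$cycle == "123"], "1231")
})

test_that("a single-cycle graph yields its canonical cycle only", {
  g <- digraph_from_adjacency({
    m <- matrix(0L, 8, 8, dimnames = list(1:8, 1:8))
    m[2, 3] <- m[3, 6] <- m[6, 2] <- 1L
    m
  })
  cyc <- enumerate_cycles(g, 3, 6)
  expect_identical(cyc$cycle, "236")
  expect_identical(cyc$length, 3L)
})

test_that("the complete 8-node digraph carries the closed-form cycle counts", {
  g <- digraph_from_adjacency(complete_adjacency(8))
  counts <- table(enumerate_cycles(g, 3, 6)$length)
  expected <- vapply(3:6, function(k) choose(8, k) * factorial(k - 1), 0)
  expect_identical(as.integer(counts[c("3", "4", "5", "6")]), as.integer(expected))
  expect_identical(sum(as.integer(counts)), 5236L)
})

test_that("short bounds admit self-loops and back-and-forth pairs", {
  g <- build_digraph(c(4, 4, 2, 4))
  expect_identical(enumerate_cycles(g, 1, 1)$cycle, "4")
  expect_setequal(enumerate_cycles(g, 1, 2)$cycle, c("4", "24"))
  expect_identical(nrow(enumerate_cycles(g, 3, 6)), 0L)
  expect_error(enumerate_cycles(g, 6, 3), class = "chemgroups_bad_length_bounds")
  expect_error(enumerate_cycles(g, 0, 3), class = "chemgroups_bad_length_bounds")
})

test_that("enumeration equals the brute-force oracle on random digraphs", {
  withr::local_seed(61)
  for (i in 1:40) {
    adj <- random_adjacency(p = stats::runif(1, 0.15, 0.5))
    g <- digraph_from_adjacency(adj)
    expect_identical(sort(enumerate_cycles(g, 3, 6)$cycle),
                     oracle_cycles(adj, 3, 6))
    expect_identical(sort(enumerate_cycles(g, 1, 4)$cycle),
                     oracle_cycles(adj, 1, 4))
  }
})

test_that("enumeration agrees with an independent graph library", {
  withr::local_seed(62)
  # cycles through each edge (s, t) are the simple t -> s paths closed by it
  igraph_cycles <- function(adj, min_len, max_len) {
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
    out <- character(0)
    for (s in 1:8) {
      for (t in which(adj[s, ] == 1L)) {
        if (t == s) {
          if (min_len <= 1) out <- c(out, as.character(s))
          next
        }
        paths <- igraph::all_simple_paths(ig, from = t, to = s, mode = "out",
                                          cutoff = max_len - 1)
        for (p in paths) {
          nodes <- c(s, as.integer(p))
          nodes <- nodes[-length(nodes)]
          if (length(nodes) >= min_len && length(nodes) <= max_len) {
            out <- c(out, paste(canonical_cycle(nodes), collapse = ""))
          }
        }
      }
    }
    sort(unique(out))
  }
  for (i in 1:6) {
    adj <- random_adjacency(p = 0.3, self_loops = FALSE)
    g <- digraph_from_adjacency(adj)
    expect_identical(sort(enumerate_cycles(g, 3, 6)$cycle),
                     igraph_cycles(adj, 3, 6))
  }
})

test_that("group-unique cycles need all edges in-group and none across", {
  a <- digraph_from_adjacency({
    m <- matrix(0L, 8, 8, dimnames = list(1:8, 1:8))
    m[1, 2] <- m[2, 3] <- m[3, 1] <- 1L
    m
  })
  b <- digraph_from_adjacency({
    m <- matrix(0L, 8, 8, dimnames = list(1:8, 1:8))
    m[1, 2] <- m[2, 1] <- 1L
    m
  })
  uc <- unique_cycles(list(a), list(b), 3, 6)
  expect_identical(uc$unique_to_a$cycle, "123")
  expect_identical(nrow(uc$unique_to_b), 0L)
  # swapping the groups swaps the outputs
  swapped <- unique_cycles(list(b), list(a), 3, 6)
  expect_identical(swapped$unique_to_b$cycle, "123")
  expect_identical(nrow(swapped$unique_to_a), 0L)
  expect_error(unique_cycles(list(), list(a)), class = "chemgroups_bad_input")
})

test_that("group-unique cycles match a brute-force membership check", {
  withr::local_seed(63)
  for (i in 1:10) {
    ga <- purrr::map(1:2, ~ digraph_from_adjacency(random_adjacency(0.35)))
    gb <- purrr::map(1:2, ~ digraph_from_adjacency(random_adjacency(0.35)))
    uc <- unique_cycles(ga, gb, 3, 5)
    # oracle: enumerate every cycle of every A member, keep those present in
    # all of A and no member of B
    all_a <- sort(unique(unlist(purrr::map(
      ga, ~ enumerate_cycles(.x, 3, 5)$cycle
    ))))
    keep <- purrr::keep(all_a, function(cy) {
      all(purrr::map_lgl(ga, ~ cycle_present(cy, .x))) &&
        !any(purrr::map_lgl(gb, ~ cycle_present(cy, .x)))
    })
    expect_identical(uc$unique_to_a$cycle, keep[order(nchar(keep), keep)])
  }
})

test_that("single-occurrence edges force one subdomain window", {
  # edges 23, 36, 62 occurring once at source positions 13, 30, 47
  codes <- rep(1L, 48)
  codes[13:14] <- c(2L, 3L)
  codes[30:31] <- c(3L, 6L)
  codes[47:48] <- c(6L, 2L)
  g <- build_digraph(codes)
  win <- cycle_subdomains("236", g)
  expect_identical(nrow(win), 1L)
  expect_identical(win$start, 13L)
  expect_identical(win$end, 48L)
  expect_identical(sort(names(win$positions[[1]])), sort(c("23", "36", "62")))
})

test_that("repeated edges yield only minimal windows", {
  # edge 23 occurs early and late; the late occurrence gives a tighter window
  g <- build_digraph(c(2, 3, 1, 1, 3, 6, 2, 3, 6, 2))
  win <- cycle_subdomains("236", g)
  oracle <- oracle_subdomains(list(`23` = g$positions[["23"]],
                                   `36` = g$positions[["36"]],
                                   `62` = g$positions[["62"]]))
  expect_identical(win$start, as.integer(oracle$start))
  expect_identical(win$end, as.integer(oracle$end))
})

test_that("subdomain windows match the all-combinations oracle on random input", {
  withr::local_seed(64)
  tried <- 0
  for (i in 1:60) {
    codes <- sample(1:5, sample(20:60, 1), replace = TRUE)
    g <- build_digraph(codes)
    cyc <- enumerate_cycles(g, 3, 4)
    if (nrow(cyc) == 0) next
    cy <- cyc$nodes[[sample(nrow(cyc), 1)]]
    edges <- paste0(cy, c(cy[-1], cy[1]))
    win <- cycle_subdomains(cy, g)
    oracle <- oracle_subdomains(g$positions[edges])
    expect_identical(win$start, as.integer(oracle$start))
    expect_identical(win$end, as.integer(oracle$end))
    expect_true(all(win$start <= win$end))
    # every reported window, re-scanned, contains every cycle edge
    for (w in seq_len(nrow(win))) {
      sub <- codes[win$start[w]:win$end[w]]
      pairs <- paste0(sub[-length(sub)], sub[-1])
      expect_true(all(edges %in% pairs))
    }
    tried <- tried + 1
  }
  expect_gte(tried, 20)
})

test_that("absent cycles are rejected", {
  g <- build_digraph(c(1, 2, 1))
  expect_error(cycle_subdomains("123", g), class = "chemgroups_cycle_absent")
})

test_that("the cycle report tabulates presence per sequence", {
  seqs <- tibble::tibble(
    id = c("a", "b"),
    reduced = c("23623", "2312")
  )
  rep <- cycle_report(digraphs(seqs), 3, 6)
  expect_true("236" %in% rep$cycle)
  expect_true(rep$a[rep$cycle == "236"])
  expect_false(rep$b[rep$cycle == "236"])
})
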