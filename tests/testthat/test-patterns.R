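test_that("exact pattern hits are found with their positions", {
  seqs <- tibble::tibble(id = "x", sequence = "ALAAD")
  hits <- find_pattern(seqs, "44441")
  expect_identical(hits$start, 1L)
  expect_identical(hits$match, "ALAAD")
  expect_identical(hits$n_mismatch, 0L)
  expect_identical(hits$mismatches[[1]], integer(0))
})

test_that("mismatch positions land where the residues leave the group", {
  # F (aromatic) breaks an aliphatic run at pattern index 2
  hits <- find_pattern(tibble::tibble(id = "x", sequence = "AFAAD"),
                       "44441", max_mismatch = 1)
  expect_identical(hits$mismatches[[1]], 2L)
  # T (hydroxyl) and K (basic) deviate at indices 2 and 6
  hits <- find_pattern(tibble::tibble(id = "x", sequence = "CTGCHK"),
                       "624621", max_mismatch = 2)
  expect_identical(hits$mismatches[[1]], c(2L, 6L))
  # H (basic) at pattern index 4 of the aliphatic-acidic pentamer
  hits <- find_pattern(tibble::tibble(id = "x", sequence = "AVAHD"),
                       "44441", max_mismatch = 1)
  expect_identical(hits$mismatches[[1]], 4L)
  # A (aliphatic) breaks the all-basic tetramer at index 3
  hits <- find_pattern(tibble::tibble(id = "x", sequence = "HKAH"),
                       "2222", max_mismatch = 1)
  expect_identical(hits$mismatches[[1]], 3L)
  # zero budget rejects the same windows
  expect_identical(
    nrow(find_pattern(tibble::tibble(id = "x", sequence = "AFAAD"), "44441")),
    0L
  )
})

test_that("every fixture pattern occurrence matches within its deviations", {
  tb8 <- load_fixture("table8_patterns")
  expected_mismatches <- list(
    `624621.PpcD` = c(2L, 6L),
    `44441.PpcA` = 2L,
    `44441.PpcD` = 4L,
    `44441.PpcE` = 1L, # G for A still aliphatic? G is group 4 -> no mismatch
    `2222.PpcA` = 3L,
    `2222.PpcE` = integer(0) # R for K stays basic
  )
  for (i in seq_len(nrow(tb8))) {
    row <- tb8[i, ]
    hits <- find_pattern(
      tibble::tibble(id = row$id, sequence = row$residues),
      row$pattern, max_mismatch = 2
    )
    expect_identical(hits$start, 1L)
    key <- paste(row$pattern, row$id, sep = ".")
    if (key %in% c("624621.PpcD", "44441.PpcA", "44441.PpcD", "2222.PpcA")) {
      expect_identical(hits$mismatches[[1]], expected_mismatches[[key]])
    } else {
      # all remaining printed occurrences are chemically exact
      expect_identical(hits$n_mismatch, 0L)
    }
  }
})

test_that("a mismatch budget of k accepts every window", {
  withr::local_seed(71)
  seqs <- random_seq_table(1, c(30, 50))
  k <- 4L
  hits <- find_pattern(seqs, rep(1L, k), max_mismatch = k)
  expect_identical(nrow(hits), nchar(seqs$sequence) - k + 1L)
})

test_that("pattern search is directional", {
  seqs <- tibble::tibble(id = "x", reduced = "12345")
  expect_identical(nrow(find_pattern(seqs, "123")), 1L)
  expect_identical(nrow(find_pattern(seqs, "321")), 0L)
  # reversing both the sequence and the pattern restores the hit
  rev_seqs <- tibble::tibble(id = "x", reduced = "54321")
  expect_identical(nrow(find_pattern(rev_seqs, "321")), 1L)
})

test_that("oversized patterns are rejected", {
  expect_error(
    find_pattern(tibble::tibble(id = "x", reduced = "12"), "123"),
    class = "chemgroups_bad_input"
  )
})

test_that("conserved k-mers are the exact intersection across sequences", {
  seqs <- tibble::tibble(id = c("a", "b"), reduced = c("1234", "3123"))
  expect_identical(conserved_kmers(seqs, 3)$pattern, "123")
  # k = 1: the groups present in every sequence
  expect_setequal(conserved_kmers(seqs, 1)$pattern, c("1", "2", "3"))
  expect_error(conserved_kmers(seqs[0, ], 3), class = "chemgroups_bad_input")
  expect_error(conserved_kmers(seqs, 5), class = "chemgroups_bad_input")
})

test_that("conserved k-mers match a brute-force intersection on random sets", {
  withr::local_seed(72)
  for (i in 1:15) {
    seqs <- reduce_sequences(random_seq_table(sample(2:4, 1), c(10, 40)))
    k <- sample(1:3, 1)
    brute <- Reduce(intersect, lapply(seqs$reduced, function(r) {
      n <- nchar(r)
      unique(substring(r, 1:(n - k + 1), k:n))
    }))
    expect_setequal(conserved_kmers(seqs, k)$pattern, brute)
  }
})

test_that("adding sequences can only shrink the conserved set", {
  withr::local_seed(73)
  for (i in 1:10) {
    a <- reduce_sequences(random_seq_table(2, c(20, 40)))
    b <- reduce_sequences(dplyr::mutate(random_seq_table(2, c(20, 40)),
                                        id = paste0("t", id)))
    both <- dplyr::bind_rows(a, b)
    expect_true(all(
      conserved_kmers(both, 2)$pattern %in% conserved_kmers(a, 2)$pattern
    ))
  }
})

test_that("group-specific k-mers exclude anything seen across the contrast", {
  a <- tibble::tibble(id = "a", reduced = "222")
  b <- tibble::tibble(id = "b", reduced = "444")
  gs <- group_specific_kmers(a, b, 3)
  expect_identical(gs$specific_to_a$pattern, "222")
  expect_identical(gs$specific_to_b$pattern, "444")
  # identical groups leave nothing specific
  same <- group_specific_kmers(a, a, 3)
  expect_identical(nrow(same$specific_to_a), 0L)
  expect_identical(nrow(same$specific_to_b), 0L)
  expect_error(group_specific_kmers(a[0, ], b, 3), class = "chemgroups_bad_input")
})

test_that("group-specific k-mers match brute force on random instances", {
  withr::local_seed(74)
  for (i in 1:10) {
    a <- reduce_sequences(random_seq_table(2, c(15, 30)))
    b <- reduce_sequences(dplyr::mutate(random_seq_table(2, c(15, 30)),
                                        id = paste0("t", id)))
    k <- 2
    kmers <- function(r) {
      n <- nchar(r)
      unique(substring(r, 1:(n - k + 1), k:n))
    }
    cons_a <- Reduce(intersect, lapply(a$reduced, kmers))
    pool_b <- unique(unlist(lapply(b$reduced, kmers)))
    gs <- group_specific_kmers(a, b, k)
    expect_setequal(gs$specific_to_a$pattern, setdiff(cons_a, pool_b))
  }
})

test_that("residue conservation is flagged only for identical realizations", {
  seqs <- tibble::tibble(
    id = c("a", "b"),
    sequence = c("HKKHAA", "HKKHGG")
  )
  cons <- conserved_kmers(seqs, 4)
  expect_true(cons$residue_conserved[cons$pattern == "2222"])
  expect_false(cons$residue_conserved[cons$pattern == "2244"])
})
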