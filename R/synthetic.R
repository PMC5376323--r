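#' Generate a random sequence with controlled group composition
#'
#' Draws a protein sequence whose chemical-group composition is fixed
#' exactly (counts mode) or matched by largest-remainder rounding of target
#' percents (percent mode). Within each group, residues are chosen uniformly
#' among the group members; the residue order is then shuffled. The same
#' seed always yields the same sequence; randomness is local and never
#' touches the global RNG state of the caller.
#'
#' @param length Sequence length (counts mode infers it when `NULL`).
#' @param counts Integer vector of 8 per-group counts summing to `length`.
#' @param percents Numeric vector of 8 target percents summing to 100.
#' @param id Sequence id for the output row.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A one-row tibble with `id` and `sequence`.
#' @examples
#' generate_sequence(counts = c(20, 10, 10, 20, 5, 5, 5, 5), seed = 1)
#' @export
generate_sequence <- function(length = NULL, counts = NULL, percents = NULL,
                              id = "synth1", seed = NULL) {
  if (is.null(counts) == is.null(percents)) {
    rlang::abort("Supply exactly one of `counts` or `percents`.",
                 class = "chemgroups_bad_spec")
  }
  if (!is.null(percents)) {
    if (length(percents) != 8L || any(percents < 0) ||
        abs(sum(percents) - 100) > 1e-9) {
      rlang::abort("`percents` must be 8 non-negative values summing to 100.",
                   class = "chemgroups_bad_spec")
    }
    if (is.null(length) || length < 1L) {
      rlang::abort("Percent mode needs a positive `length`.",
                   class = "chemgroups_bad_spec")
    }
    # largest-remainder rounding of target percents to integer counts
    exact <- percents / 100 * length
    counts <- floor(exact)
    short <- length - sum(counts)
    if (short > 0L) {
      top <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
      counts[top] <- counts[top] + 1L
    }
  }
  counts <- as.integer(counts)
  if (length(counts) != 8L || any(counts < 0) || anyNA(counts)) {
    rlang::abort("`counts` must be 8 non-negative integers.",
                 class = "chemgroups_bad_spec")
  }
  if (is.null(length)) length <- sum(counts)
  if (length < 1L || sum(counts) != length) {
    rlang::abort("Counts must sum to a positive `length`.",
                 class = "chemgroups_bad_spec")
  }
  draw <- function() {
    residues <- unlist(purrr::map2(.group_members, counts, function(m, n) {
      if (n == 0L) character(0) else sample(m, n, replace = TRUE)
    }))
    paste(sample(residues), collapse = "")
  }
  seq <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  tibble::tibble(id = id, sequence = seq)
}

#' Generate several sequences from a specification table
#'
#' @param spec A data frame with columns `id`, `length` (optional in counts
#'   mode) and either `g1`..`g8` counts or `p1`..`p8` percents.
#' @param seed Integer seed; per-row seeds are derived from it.
#' @return A tibble with `id` and `sequence`, one row per spec row.
#' @export
generate_sequences <- function(spec, seed = NULL) {
  if (!is.data.frame(spec) || nrow(spec) == 0L) {
    rlang::abort("`spec` must be a non-empty data frame.",
                 class = "chemgroups_bad_spec")
  }
  counts_mode <- all(paste0("g", 1:8) %in% names(spec))
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(spec)) else
    as.list(as.integer(seed) + seq_len(nrow(spec)) - 1L)
  purrr::map_dfr(seq_len(nrow(spec)), function(i) {
    r <- spec[i, ]
    if (counts_mode) {
      generate_sequence(
        length = if ("length" %in% names(r)) r$length else NULL,
        counts = unlist(r[paste0("g", 1:8)]),
        id = r$id, seed = seeds[[i]]
      )
    } else {
      generate_sequence(
        length = r$length, percents = unlist(r[paste0("p", 1:8)]),
        id = r$id, seed = seeds[[i]]
      )
    }
  })
}

#' Load a packaged fixture table
#'
#' The cytochrome c7 worked-example tables ship with the package as
#' plain-text TSV: `"table1_lengths"` (sequence metadata and lengths),
#' `"table3_counts"` (per-amino-acid counts per sequence) and
#' `"table8_patterns"` (chemically conserved pattern occurrences).
#'
#' @param name One of `"table1_lengths"`, `"table3_counts"`,
#'   `"table8_patterns"`.
#' @return A tibble.
#' @examples
#' load_fixture("table1_lengths")
#' @export
load_fixture <- function(name) {
  files <- c(
    table1_lengths = "table1_lengths.tsv",
    table3_counts = "table3_counts.tsv",
    table8_patterns = "table8_patterns.tsv"
  )
  if (length(name) != 1L || !name %in% names(files)) {
    rlang::abort(sprintf(
      "Unknown fixture. Available: %s.",
      paste(names(files), collapse = ", ")
    ), class = "chemgroups_unknown_fixture")
  }
  path <- system.file("extdata", files[[name]], package = "chemgroups",
                      mustWork = TRUE)
  # patterns are digit strings over the group alphabet, never numbers
  types <- if (name == "table8_patterns") readr::cols(pattern = "c") else
    readr::cols()
  readr::read_tsv(path, show_col_types = FALSE, col_types = types) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), as.integer))
}
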