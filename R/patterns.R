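#' Search a chemical pattern in reduced sequences
#'
#' Scans every window of length k for matches to a pattern over the group
#' alphabet, tolerating up to `max_mismatch` positions whose group code
#' differs from the pattern. Matching is at the chemical-group level, so a
#' pattern like `"624621"` finds any hexamer whose residues fall in the
#' groups Sulfur, Basic, Aliphatic, Sulfur, Basic, Acidic — e.g. `CKGCHE`
#' exactly, or `CTGCHK` with two group deviations.
#'
#' @param seqs A data frame with columns `id` and `reduced` (a `sequence`
#'   column, if present, is used to report the matched residues; sequences
#'   without `reduced` are reduced first).
#' @param pattern Digit string or integer vector over 1..8.
#' @param max_mismatch Maximum number of mismatching positions (default 0).
#' @return A tibble of hits sorted by `id` then `start` (1-based): `id`,
#'   `start`, `match` (residues when available, else codes), `codes`,
#'   `n_mismatch` and the list-column `mismatches` of 1-based within-pattern
#'   indices.
#' @examples
#' seqs <- reduce_sequences(tibble::tibble(id = "x", sequence = "AFAAD"))
#' find_pattern(seqs, "44441", max_mismatch = 1)
#' @export
find_pattern <- function(seqs, pattern, max_mismatch = 0L) {
  if (!"reduced" %in% names(seqs)) seqs <- reduce_sequences(seqs)
  .check_seqs(seqs, require = "reduced")
  pat <- .as_codes(pattern)
  k <- length(pat)
  if (any(nchar(seqs$reduced) < k)) {
    rlang::abort("Pattern is longer than a sequence.",
                 class = "chemgroups_bad_input")
  }
  has_res <- "sequence" %in% names(seqs)
  purrr::pmap_dfr(
    list(seqs$id, seqs$reduced,
         if (has_res) toupper(seqs$sequence) else seqs$reduced),
    function(id, red, res) {
      codes <- .as_codes(red)
      starts <- seq_len(length(codes) - k + 1L)
      hits <- purrr::map(starts, function(s) {
        mm <- which(codes[s:(s + k - 1L)] != pat)
        if (length(mm) <= max_mismatch) mm else NULL
      })
      keep <- !vapply(hits, is.null, TRUE)
      tibble::tibble(
        id = id,
        start = starts[keep],
        match = stringr::str_sub(res, starts[keep], starts[keep] + k - 1L),
        codes = stringr::str_sub(red, starts[keep], starts[keep] + k - 1L),
        n_mismatch = lengths(hits[keep]),
        mismatches = hits[keep]
      )
    }
  ) |> dplyr::arrange(.data$id, .data$start)
}

.kmer_set <- function(red, k) {
  n <- nchar(red)
  if (n < k) return(character(0))
  unique(stringr::str_sub(red, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Chemically conserved k-mers
#'
#' The set of reduced k-mers (exact group-level matches) occurring in every
#' input sequence. A k-mer is additionally flagged residue-conserved when
#' all its occurrences across all sequences realize the same residue string.
#'
#' @param seqs A data frame with `id` and `reduced` (or `sequence`).
#' @param k Word length, `k >= 1`.
#' @return A tibble with `pattern` (digit string), `n_occurrences` (total
#'   across sequences) and `residue_conserved`.
#' @examples
#' seqs <- tibble::tibble(id = c("a", "b"), reduced = c("1234", "3123"))
#' conserved_kmers(seqs, 3)
#' @export
conserved_kmers <- function(seqs, k) {
  if (!is.data.frame(seqs) || nrow(seqs) == 0L) {
    rlang::abort("`seqs` must be a non-empty data frame.",
                 class = "chemgroups_bad_input")
  }
  if (!"reduced" %in% names(seqs)) seqs <- reduce_sequences(seqs)
  .check_seqs(seqs, require = "reduced")
  k <- as.integer(k)
  if (k < 1L || any(nchar(seqs$reduced) < k)) {
    rlang::abort("Need 1 <= k <= min sequence length.",
                 class = "chemgroups_bad_input")
  }
  shared <- Reduce(intersect, purrr::map(seqs$reduced, .kmer_set, k = k))
  if (length(shared) == 0L) {
    return(tibble::tibble(pattern = character(), n_occurrences = integer(),
                          residue_conserved = logical()))
  }
  has_res <- "sequence" %in% names(seqs)
  info <- purrr::map_dfr(sort(shared), function(p) {
    hits <- find_pattern(seqs, p)
    tibble::tibble(
      pattern = p,
      n_occurrences = nrow(hits),
      residue_conserved = has_res && dplyr::n_distinct(hits$match) == 1L
    )
  })
  info
}

#' Group-specific k-mers between two sequence sets
#'
#' A k-mer is specific to group A when it is conserved in A (present in
#' every member) and absent from every member of B.
#'
#' @param group_a,group_b Non-empty data frames with `id` and `reduced`
#'   (or `sequence`).
#' @param k Word length.
#' @return A list with tibbles `specific_to_a` and `specific_to_b` (columns
#'   as in [conserved_kmers()], computed within the owning group).
#' @examples
#' a <- tibble::tibble(id = "a", reduced = "222")
#' b <- tibble::tibble(id = "b", reduced = "444")
#' group_specific_kmers(a, b, 3)
#' @export
group_specific_kmers <- function(group_a, group_b, k) {
  prep <- function(g, nm) {
    if (!is.data.frame(g) || nrow(g) == 0L) {
      rlang::abort(sprintf("`%s` must be a non-empty data frame.", nm),
                   class = "chemgroups_bad_input")
    }
    if (!"reduced" %in% names(g)) g <- reduce_sequences(g)
    g
  }
  group_a <- prep(group_a, "group_a")
  group_b <- prep(group_b, "group_b")
  pool <- function(g) unique(unlist(purrr::map(g$reduced, .kmer_set, k = k)))
  side <- function(own, other) {
    cons <- conserved_kmers(own, k)
    dplyr::filter(cons, !.data$pattern %in% pool(other))
  }
  list(
    specific_to_a = side(group_a, group_b),
    specific_to_b = side(group_b, group_a)
  )
}
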