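# The eight-group reduced alphabet. Member sets partition the 20 standard
# amino acids; codes 1..8 are the node labels used throughout the package.
.group_members <- list(
  c("D", "E"),
  c("R", "H", "K"),
  c("Y", "F", "W"),
  c("I", "L", "V", "A", "G"),
  "P",
  c("M", "C"),
  c("S", "T"),
  c("Q", "N")
)

.group_names <- c(
  "Acidic", "Basic", "Aromatic", "Aliphatic",
  "Cyclic", "SulfurContaining", "HydroxylContaining", "AcidicAmide"
)

# residue -> group code lookup, built once at load
.residue_group <- {
  m <- unlist(.group_members)
  stats::setNames(rep(seq_along(.group_members), lengths(.group_members)), m)
}

.standard_aa <- sort(names(.residue_group))

#' The eight amino acid chemical groups
#'
#' Returns the reduced-alphabet table used by every other function in the
#' package: the 20 standard amino acids partitioned into 8 chemical groups by
#' side-chain nature. Group codes 1 to 8 stand for Acidic \{D,E\}, Basic
#' \{R,H,K\}, Aromatic \{Y,F,W\}, Aliphatic \{I,L,V,A,G\}, Cyclic \{P\},
#' Sulfur-containing \{M,C\}, Hydroxyl-containing \{S,T\} and Acidic amide
#' \{Q,N\}.
#'
#' @return A tibble with columns `code` (integer 1-8), `name`, `members`
#'   (list-column of one-letter residue codes) and `residues` (the members
#'   collapsed to a string).
#' @examples
#' chemical_groups()
#' @export
chemical_groups <- function() {
  tibble::tibble(
    code = seq_along(.group_members),
    name = .group_names,
    members = .group_members,
    residues = vapply(.group_members, paste, "", collapse = "")
  )
}

#' Look up one chemical group by code
#'
#' @param code A single integer in 1..8.
#' @return A one-row tibble as in [chemical_groups()].
#' @examples
#' decode_group(7) # Hydroxyl-containing, S/T
#' @export
decode_group <- function(code) {
  if (length(code) != 1L || is.na(code) || code != as.integer(code) ||
      code < 1L || code > 8L) {
    rlang::abort("`code` must be a single integer in 1..8.",
                 class = "chemgroups_bad_group_code")
  }
  chemical_groups()[as.integer(code), ]
}

#' Encode residues as chemical group codes
#'
#' Vectorised residue-level encoding. Input is uppercased before validation;
#' any character outside the 20 standard one-letter codes (including B, J, O,
#' U, X, Z and the gap character `-`) is rejected with an error naming the
#' character and its position, unless `nonstandard = "skip"`, in which case
#' offending positions are dropped with a warning.
#'
#' @param residues Character vector of single residues, or a single string
#'   (which is split into residues).
#' @param nonstandard `"error"` (default) or `"skip"`.
#' @return Integer vector of group codes in 1..8. Under `"skip"` the dropped
#'   1-based positions are attached as attribute `"dropped"`.
#' @examples
#' encode_residues("CKGCHE") # 6 2 4 6 2 1
#' @export
encode_residues <- function(residues, nonstandard = c("error", "skip")) {
  nonstandard <- match.arg(nonstandard)
  if (length(residues) == 1L && nchar(residues) > 1L) {
    residues <- stringr::str_split_1(residues, "")
  }
  residues <- toupper(residues)
  codes <- unname(.residue_group[residues])
  bad <- which(is.na(codes))
  if (length(bad) > 0L) {
    if (nonstandard == "error") {
      rlang::abort(
        sprintf(
          "Nonstandard residue '%s' at position %d (and %d further offending position%s).",
          residues[bad[1]], bad[1], length(bad) - 1L,
          if (length(bad) == 2L) "" else "s"
        ),
        class = "chemgroups_nonstandard_residue"
      )
    }
    rlang::warn(sprintf(
      "Dropped %d nonstandard residue(s) at position(s) %s.",
      length(bad), paste(bad, collapse = ", ")
    ))
    codes <- as.integer(codes[-bad])
    attr(codes, "dropped") <- bad
    return(codes)
  }
  as.integer(codes)
}

.check_seqs <- function(seqs, require = "sequence") {
  if (!is.data.frame(seqs) || !all(c("id", require) %in% names(seqs))) {
    rlang::abort(
      sprintf("`seqs` must be a data frame with columns `id` and `%s`.", require),
      class = "chemgroups_bad_input"
    )
  }
  if (nrow(seqs) == 0L) {
    rlang::abort("`seqs` has no rows.", class = "chemgroups_bad_input")
  }
  if (anyDuplicated(seqs$id)) {
    rlang::abort("Sequence ids must be unique.", class = "chemgroups_bad_input")
  }
  if (require == "sequence" && any(!nzchar(seqs$sequence) | is.na(seqs$sequence))) {
    rlang::abort("Empty sequence.", class = "chemgroups_bad_input")
  }
  invisible(seqs)
}

#' Reduce amino acid sequences to chemical group code strings
#'
#' Applies the 8-group encoding position by position. The reduced sequence is
#' returned as a digit string (e.g. `"CKGCHE"` becomes `"624621"`), parallel
#' to the residues: code i depends only on residue i and length is preserved
#' (unless nonstandard residues are skipped).
#'
#' @param seqs A data frame with columns `id` and `sequence`.
#' @param nonstandard Policy for residues outside the standard alphabet, see
#'   [encode_residues()].
#' @return The input tibble with an added character column `reduced` and, when
#'   `nonstandard = "skip"`, a list-column `dropped` of removed positions.
#' @examples
#' reduce_sequences(tibble::tibble(id = "x", sequence = "ALAAD"))
#' @export
reduce_sequences <- function(seqs, nonstandard = c("error", "skip")) {
  nonstandard <- match.arg(nonstandard)
  .check_seqs(seqs)
  out <- tibble::as_tibble(seqs)
  out$sequence <- toupper(out$sequence)
  enc <- purrr::map(out$sequence, encode_residues, nonstandard = nonstandard)
  out$reduced <- vapply(enc, paste, "", collapse = "")
  if (nonstandard == "skip") {
    out$dropped <- purrr::map(enc, ~ attr(.x, "dropped") %||% integer(0))
  }
  if (any(!nzchar(out$reduced))) {
    rlang::abort("A sequence reduced to length zero.", class = "chemgroups_bad_input")
  }
  out
}

#' Per-position encoding in long form
#'
#' @param seqs A data frame with columns `id` and `sequence`.
#' @inheritParams reduce_sequences
#' @return A tibble with one row per retained residue: `id`, `position`
#'   (1-based in the original sequence), `residue`, `code`.
#' @export
reduce_long <- function(seqs, nonstandard = c("error", "skip")) {
  nonstandard <- match.arg(nonstandard)
  .check_seqs(seqs)
  purrr::map2_dfr(seqs$id, toupper(seqs$sequence), function(id, s) {
    codes <- encode_residues(s, nonstandard = nonstandard)
    pos <- seq_len(nchar(s))
    dropped <- attr(codes, "dropped")
    if (!is.null(dropped)) pos <- pos[-dropped]
    tibble::tibble(
      id = id, position = pos,
      residue = stringr::str_split_1(s, "")[pos],
      code = as.integer(codes)
    )
  })
}

# Accepts a digit string or an integer vector of codes; returns integer codes.
.as_codes <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- as.integer(stringr::str_split_1(x, ""))
  }
  x <- as.integer(x)
  if (length(x) == 0L || anyNA(x) || any(x < 1L | x > 8L)) {
    rlang::abort("Group codes must be integers in 1..8.",
                 class = "chemgroups_bad_codes")
  }
  x
}
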