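# Column order of the amino acid count table mirrors the chemical groups:
# acidic, basic, aromatic, aliphatic, cyclic, sulfur, hydroxyl, acidic amide.
.aa_order <- c(
  "D", "E", "R", "H", "K", "Y", "F", "W", "I", "L",
  "V", "A", "G", "P", "M", "C", "S", "T", "Q", "N"
)

#' Count amino acid occurrences per sequence
#'
#' @param seqs A data frame with columns `id` and `sequence`.
#' @return A tibble with `id`, one integer column per standard amino acid
#'   (grouped by chemical group: D,E | R,H,K | Y,F,W | I,L,V,A,G | P | M,C |
#'   S,T | Q,N) and `length`. Counts sum to `length` row-wise.
#' @examples
#' count_amino_acids(tibble::tibble(id = "x", sequence = "CKGCHE"))
#' @export
count_amino_acids <- function(seqs) {
  .check_seqs(seqs)
  counts <- t(vapply(
    toupper(seqs$sequence),
    function(s) {
      ch <- stringr::str_split_1(s, "")
      bad <- setdiff(unique(ch), .standard_aa)
      if (length(bad) > 0L) {
        rlang::abort(
          sprintf("Nonstandard residue '%s' in sequence.", bad[1]),
          class = "chemgroups_nonstandard_residue"
        )
      }
      table(factor(ch, levels = .aa_order))
    },
    integer(20)
  ))
  out <- tibble::as_tibble(counts)
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  dplyr::bind_cols(
    tibble::tibble(id = seqs$id), out,
    tibble::tibble(length = as.integer(nchar(seqs$sequence)))
  )
}

.composition_from_count_matrix <- function(ids, counts8, lengths) {
  percents <- counts8 / lengths * 100
  tibble::tibble(
    id = rep(ids, each = 8L),
    length = rep(as.integer(lengths), each = 8L),
    code = rep(1:8, length(ids)),
    name = rep(.group_names, length(ids)),
    count = as.integer(t(counts8)),
    percent = as.numeric(t(percents))
  )
}

#' Chemical group composition of sequences
#'
#' For each sequence, the number of residues falling in each of the 8
#' chemical groups and the corresponding score per hundred residues
#' (count / length x 100). Percents sum to 100 per sequence.
#'
#' @param seqs A data frame with columns `id` and `sequence`, or one already
#'   carrying a `reduced` digit-string column (the sequence column is then
#'   not needed).
#' @return A long tibble: `id`, `length`, `code` (1-8), `name`, `count`,
#'   `percent`.
#' @examples
#' group_composition(tibble::tibble(id = "x", sequence = "ALAAD"))
#' @export
group_composition <- function(seqs) {
  if (is.data.frame(seqs) && !"reduced" %in% names(seqs)) {
    seqs <- reduce_sequences(seqs)
  }
  .check_seqs(seqs, require = "reduced")
  counts8 <- t(vapply(
    seqs$reduced,
    function(r) table(factor(.as_codes(r), levels = 1:8)),
    integer(8)
  ))
  .composition_from_count_matrix(seqs$id, counts8, nchar(seqs$reduced))
}

#' Group composition from an amino acid count table
#'
#' Computes the 8-group composition directly from per-amino-acid counts
#' (one row per sequence, as produced by [count_amino_acids()] or loaded
#' with [load_fixture()]), without needing the sequences themselves. Group
#' counts are the sums of their member amino acid counts.
#'
#' @param counts A data frame with `id` and one column per standard amino
#'   acid. An optional `length` column is validated against the row sums.
#' @return A long composition tibble as in [group_composition()].
#' @examples
#' composition_from_counts(load_fixture("table3_counts"))
#' @export
composition_from_counts <- function(counts) {
  if (!is.data.frame(counts) || !"id" %in% names(counts) ||
      !all(.aa_order %in% names(counts))) {
    rlang::abort(
      "`counts` needs an `id` column and one column per standard amino acid.",
      class = "chemgroups_bad_input"
    )
  }
  aam <- as.matrix(counts[, .aa_order])
  if (any(aam < 0) || anyNA(aam)) {
    rlang::abort("Negative or missing amino acid counts.",
                 class = "chemgroups_bad_input")
  }
  lens <- rowSums(aam)
  if (any(lens == 0)) {
    rlang::abort("All-zero count row (zero-length sequence).",
                 class = "chemgroups_bad_input")
  }
  if ("length" %in% names(counts) && any(counts$length != lens)) {
    rlang::abort("`length` column disagrees with the amino acid count sums.",
                 class = "chemgroups_bad_input")
  }
  counts8 <- t(apply(aam, 1L, function(r) {
    vapply(.group_members, function(m) sum(r[m]), numeric(1))
  }))
  .composition_from_count_matrix(counts$id, counts8, lens)
}

#' Composition table in wide form
#'
#' @param composition A long composition tibble from [group_composition()] or
#'   [composition_from_counts()].
#' @param value `"percent"` (default) or `"count"`.
#' @return A tibble with `id`, `length` and columns `G1`..`G8`.
#' @export
composition_wide <- function(composition, value = c("percent", "count")) {
  value <- match.arg(value)
  composition |>
    dplyr::mutate(group = paste0("G", .data$code)) |>
    tidyr::pivot_wider(
      id_cols = c("id", "length"), names_from = "group",
      values_from = dplyr::all_of(value)
    )
}

.percent_matrix <- function(composition) {
  wide <- composition_wide(composition)
  m <- as.matrix(wide[, paste0("G", 1:8)])
  rownames(m) <- wide$id
  m
}

#' Chemical dissimilarity between two sequences
#'
#' The L1 distance between two 8-group percent-composition vectors: the sum
#' over the 8 groups of the absolute percent differences. Ranges from 0
#' (identical group composition) to 200.
#'
#' @param composition A long composition tibble.
#' @param id_a,id_b Ids of the two sequences to compare.
#' @return A single number in percent units.
#' @examples
#' comp <- composition_from_counts(load_fixture("table3_counts"))
#' dissimilarity(comp, "PpcA", "PpcB") # 17.5824
#' @export
dissimilarity <- function(composition, id_a, id_b) {
  p <- .percent_matrix(composition)
  missing <- setdiff(c(id_a, id_b), rownames(p))
  if (length(missing) > 0L) {
    rlang::abort(sprintf("Unknown sequence id '%s'.", missing[1]),
                 class = "chemgroups_bad_input")
  }
  sum(abs(p[id_a, ] - p[id_b, ]))
}

#' Pairwise chemical dissimilarity matrix
#'
#' @param composition A long composition tibble covering at least two
#'   sequences with unique ids.
#' @return A `chem_dissim` object wrapping the symmetric, zero-diagonal
#'   matrix of pairwise L1 percent dissimilarities; supports `as.matrix()`,
#'   `as.dist()`, `tidy()`, `glance()` and `autoplot()`.
#' @examples
#' comp <- composition_from_counts(load_fixture("table3_counts"))
#' chem_dissimilarity(comp)
#' @export
chem_dissimilarity <- function(composition) {
  p <- .percent_matrix(composition)
  if (nrow(p) < 2L) {
    rlang::abort("Need at least two sequences.", class = "chemgroups_bad_input")
  }
  if (anyDuplicated(rownames(p))) {
    rlang::abort("Duplicate sequence ids.", class = "chemgroups_bad_input")
  }
  d <- as.matrix(stats::dist(p, method = "manhattan"))
  dimnames(d) <- list(rownames(p), rownames(p))
  structure(list(labels = rownames(p), matrix = d), class = "chem_dissim")
}

#' @export
as.matrix.chem_dissim <- function(x, ...) x$matrix

#' @export
as.dist.chem_dissim <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$matrix, diag = diag, upper = upper)
}

#' @export
print.chem_dissim <- function(x, digits = 4, ...) {
  cat(sprintf("Chemical group dissimilarity matrix (%d sequences, %% units)\n",
              length(x$labels)))
  print(round(x$matrix, digits))
  invisible(x)
}

#' @rdname chem_dissimilarity
#' @param x A `chem_dissim` object.
#' @param ... Unused.
#' @export
tidy.chem_dissim <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(upper.tri(x$matrix), arr.ind = TRUE)
  tibble::tibble(
    id_a = x$labels[idx[, 1]],
    id_b = x$labels[idx[, 2]],
    dissimilarity = x$matrix[idx]
  ) |> dplyr::arrange(.data$id_a, .data$id_b)
}

#' @rdname chem_dissimilarity
#' @export
glance.chem_dissim <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  tibble::tibble(
    n = length(x$labels),
    min = min(off), max = max(off), mean = mean(off)
  )
}

#' @rdname chem_dissimilarity
#' @param object A `chem_dissim` object.
#' @export
autoplot.chem_dissim <- function(object, ...) {
  df <- tidyr::expand_grid(
    id_a = factor(object$labels, levels = object$labels),
    id_b = factor(object$labels, levels = rev(object$labels))
  )
  df$dissimilarity <- object$matrix[cbind(
    as.character(df$id_a), as.character(df$id_b)
  )]
  ggplot2::ggplot(df, ggplot2::aes(.data$id_a, .data$id_b,
                                   fill = .data$dissimilarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$dissimilarity)
    ), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "D (%)") +
    ggplot2::theme_minimal()
}

#' Write a composition table or dissimilarity matrix as TSV
#'
#' @param x A long composition tibble or a `chem_dissim` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_composition_tsv <- function(x, path) {
  if (inherits(x, "chem_dissim")) {
    df <- tibble::as_tibble(x$matrix, rownames = "id")
  } else {
    df <- composition_wide(x)
  }
  readr::write_tsv(df, path)
  invisible(path)
}
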