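#' Read protein sequences from FASTA
#'
#' Multi-record FASTA with wrapped or unwrapped lines and CRLF endings.
#' Record ids are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("No such file: %s", path), class = "chemgroups_io_error")
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) rlang::abort(
      sprintf("Malformed FASTA '%s': %s", path, conditionMessage(e)),
      class = "chemgroups_io_error"
    )
  )
  if (length(set) == 0L) {
    rlang::abort("Empty FASTA file.", class = "chemgroups_io_error")
  }
  ids <- stringr::str_extract(names(set), "^\\S+")
  if (anyDuplicated(ids)) {
    rlang::abort("Duplicate record ids in FASTA.", class = "chemgroups_io_error")
  }
  seqs <- tibble::tibble(id = ids, sequence = unname(as.character(set)))
  .check_seqs(seqs)
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs A data frame with `id` and `sequence`.
#' @param path Output file.
#' @param width Line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  .check_seqs(seqs)
  lines <- purrr::map2(seqs$id, seqs$sequence, function(id, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", id), stringr::str_sub(s, starts, starts + width - 1L))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Extract a 1-based inclusive residue range
#'
#' @param seqs A data frame with `id` and `sequence`.
#' @param start,end 1-based inclusive bounds; `end = NULL` runs to the end.
#' @return The tibble with sequences cut to the range.
#' @export
sequence_range <- function(seqs, start = 1L, end = NULL) {
  .check_seqs(seqs)
  if (start < 1L || (!is.null(end) && end < start)) {
    rlang::abort("Need 1 <= start <= end.", class = "chemgroups_bad_input")
  }
  dplyr::mutate(
    tibble::as_tibble(seqs),
    sequence = stringr::str_sub(.data$sequence, start,
                                end %||% nchar(.data$sequence))
  ) |> .check_seqs()
}

#' Run the full chemical-group characterization
#'
#' Orchestrates the whole pipeline over a set of sequences: 8-group
#' encoding, group composition and pairwise dissimilarity, single-linkage
#' tree, per-sequence order-pair digraphs, bounded cycle report, conserved
#' k-mers and (optionally) a two-group edge/cycle/k-mer contrast. All
#' tables are written as TSV under `output_dir` together with a Newick
#' tree, per-sequence DOT files and a versioned JSON summary.
#'
#' @param seqs A data frame with `id` and `sequence`, or a FASTA path.
#' @param output_dir Directory to create/write into.
#' @param range Optional `c(start, end)` 1-based inclusive residue range
#'   applied to every sequence before analysis.
#' @param min_cycle,max_cycle Cycle length bounds (default 3..6).
#' @param k Conserved k-mer length (default 4).
#' @param group_a,group_b Optional character vectors of sequence ids
#'   defining a two-group contrast.
#' @param nonstandard Residue policy, see [encode_residues()].
#' @return Invisibly, a list with the computed objects and written paths.
#' @export
run_characterize <- function(seqs, output_dir, range = NULL,
                             min_cycle = 3L, max_cycle = 6L, k = 4L,
                             group_a = NULL, group_b = NULL,
                             nonstandard = c("error", "skip")) {
  nonstandard <- match.arg(nonstandard)
  if (is.character(seqs) && length(seqs) == 1L) seqs <- read_fasta(seqs)
  if (min_cycle > max_cycle) {
    rlang::abort("`min_cycle` must not exceed `max_cycle`.",
                 class = "chemgroups_bad_input")
  }
  if (!is.null(range)) seqs <- sequence_range(seqs, range[1], range[2])
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(output_dir, f)
  paths <- character(0)

  reduced <- reduce_sequences(seqs, nonstandard = nonstandard)
  readr::write_tsv(dplyr::select(reduced, "id", "reduced"), out("reduced.tsv"))
  paths <- c(paths, out("reduced.tsv"))

  comp <- group_composition(reduced)
  write_composition_tsv(comp, out("composition.tsv"))
  paths <- c(paths, out("composition.tsv"))

  dmat <- NULL; tree <- NULL
  if (nrow(seqs) >= 2L) {
    dmat <- chem_dissimilarity(comp)
    write_composition_tsv(dmat, out("dissimilarity.tsv"))
    tree <- single_linkage(dmat)
    writeLines(to_newick(tree), out("tree.nwk"))
    write_merges_tsv(tree, out("merges.tsv"))
    paths <- c(paths, out("dissimilarity.tsv"), out("tree.nwk"), out("merges.tsv"))
  } else {
    rlang::warn("Single sequence: dissimilarity and tree stages skipped.")
  }

  gs <- digraphs(reduced)
  for (g in gs) {
    write_dot(g, out(paste0(g$id, ".dot")))
    write_adjacency_tsv(g, out(paste0(g$id, "_adjacency.tsv")))
    paths <- c(paths, out(paste0(g$id, ".dot")), out(paste0(g$id, "_adjacency.tsv")))
  }

  cyc <- cycle_report(gs, min_cycle, max_cycle)
  readr::write_tsv(cyc, out("cycles.tsv"))
  paths <- c(paths, out("cycles.tsv"))

  km <- conserved_kmers(reduced, k)
  readr::write_tsv(km, out("conserved_kmers.tsv"))
  paths <- c(paths, out("conserved_kmers.tsv"))

  contrast <- NULL
  if (!is.null(group_a) && !is.null(group_b)) {
    missing <- setdiff(c(group_a, group_b), seqs$id)
    if (length(missing) > 0L) {
      rlang::abort(sprintf("Unknown group id '%s'.", missing[1]),
                   class = "chemgroups_bad_input")
    }
    ga <- gs[group_a]; gb <- gs[group_b]
    edges <- compare_edge_sets(ga, gb)
    readr::write_tsv(
      dplyr::select(edges, -"in_any_a", -"in_any_b"),
      out("edge_comparison.tsv")
    )
    uc <- unique_cycles(ga, gb, min_cycle, max_cycle)
    readr::write_tsv(
      dplyr::bind_rows(
        dplyr::mutate(dplyr::select(uc$unique_to_a, "cycle", "length"),
                      unique_to = "a"),
        dplyr::mutate(dplyr::select(uc$unique_to_b, "cycle", "length"),
                      unique_to = "b")
      ),
      out("unique_cycles.tsv")
    )
    paths <- c(paths, out("edge_comparison.tsv"), out("unique_cycles.tsv"))
    contrast <- list(edges = edges, cycles = uc)
  }

  summary <- list(
    schema_version = "1.0",
    n_sequences = nrow(seqs),
    ids = seqs$id,
    lengths = nchar(seqs$sequence),
    cycle_bounds = c(min_cycle, max_cycle),
    k = k,
    n_cycles = nrow(cyc),
    n_conserved_kmers = nrow(km),
    outputs = basename(paths)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  paths <- c(paths, out("summary.json"))

  invisible(list(
    sequences = reduced, composition = comp, dissimilarity = dmat,
    tree = tree, graphs = gs, cycles = cyc, kmers = km,
    contrast = contrast, paths = paths
  ))
}
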