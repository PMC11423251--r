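#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT format (one set per line: name, description,
#' then one or more gene identifiers). Duplicate genes within a set are
#' dropped with a warning; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene ids, with a
#'   `descriptions` attribute carrying the second GMT column.
#' @export
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("PG\tproteoglycans\tGPC1\tSDC1", f)
#' read_gmt(f)
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    pg_abort(sprintf("GMT file '%s' is empty.", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad) > 0) {
    pg_abort(sprintf(
      "Malformed GMT line %d in '%s': need name, description and >= 1 gene.",
      bad[1], path
    ))
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    pg_abort(sprintf(
      "Duplicate gene-set name(s) in '%s': %s",
      path, paste(unique(names_[duplicated(names_)]), collapse = ", ")
    ))
  }
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    dup <- duplicated(genes)
    if (any(dup)) {
      pg_warn(sprintf(
        "Set '%s': %d duplicate gene id(s) collapsed.", f[[1]], sum(dup)
      ))
    }
    genes[!dup]
  })
  names(sets) <- names_
  attr(sets, "descriptions") <- setNames(
    vapply(fields, `[[`, character(1), 2), names_
  )
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors (as from [read_gmt()]).
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions;
#'   defaults to the set name.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    pg_abort("`sets` must be a named list.")
  }
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a validated interactome from an edge table
#'
#' An interactome is an undirected, confidence-weighted protein-protein
#' interaction graph stored as a tibble with columns `node_a`, `node_b`,
#' `confidence`. Self-loops are dropped with a warning; duplicate unordered
#' pairs are collapsed keeping the maximum confidence.
#'
#' @param edges Data frame with columns `node_a`, `node_b`, `confidence`.
#' @return A tibble of class `pg_interactome` with one row per unordered
#'   node pair, sorted for determinism.
#' @export
as_interactome <- function(edges) {
  edges <- as_tibble(edges)
  need <- c("node_a", "node_b", "confidence")
  if (!all(need %in% names(edges))) {
    pg_abort("`edges` needs columns node_a, node_b, confidence.")
  }
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  if (!is.numeric(edges$confidence) || anyNA(edges$confidence) ||
      any(edges$confidence < 0 | edges$confidence > 1)) {
    pg_abort("Edge confidences must be numeric in [0, 1].")
  }
  loops <- edges$node_a == edges$node_b
  if (any(loops)) {
    pg_warn(sprintf("Dropped %d self-loop edge(s).", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical unordered orientation, then max-confidence per pair
  flip <- edges$node_a > edges$node_b
  tmp <- edges$node_a[flip]
  edges$node_a[flip] <- edges$node_b[flip]
  edges$node_b[flip] <- tmp
  ndup <- nrow(edges) - nrow(distinct(edges, .data$node_a, .data$node_b))
  if (ndup > 0) {
    pg_warn(sprintf(
      "Collapsed %d duplicate edge(s), keeping maximum confidence.", ndup
    ))
  }
  edges <- edges |>
    group_by(.data$node_a, .data$node_b) |>
    summarise(confidence = max(.data$confidence), .groups = "drop") |>
    arrange(.data$node_a, .data$node_b)
  class(edges) <- c("pg_interactome", class(edges))
  edges
}

#' Read a confidence-weighted interactome edge list
#'
#' Expects a tab-separated file with a header row `node_a`, `node_b`,
#' `confidence` (confidence in `[0, 1]`). Validation and the duplicate-pair
#' policy are those of [as_interactome()]; a confidence outside `[0, 1]` is
#' reported with its line number.
#'
#' @param path Path to a TSV edge list.
#' @return A `pg_interactome` tibble.
#' @export
read_interactome <- function(path) {
  edges <- readr::read_tsv(
    path,
    col_types = readr::cols(
      node_a = readr::col_character(),
      node_b = readr::col_character(),
      confidence = readr::col_double()
    ),
    progress = FALSE
  )
  bad <- which(is.na(edges$confidence) |
                 edges$confidence < 0 | edges$confidence > 1)
  if (length(bad) > 0) {
    pg_abort(sprintf(
      "Line %d of '%s': confidence outside [0, 1].", bad[1] + 1L, path
    ))
  }
  as_interactome(edges)
}

#' Write an interactome edge list
#'
#' @param net A `pg_interactome` (or compatible data frame).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_interactome <- function(net, path) {
  readr::write_tsv(as_tibble(net)[, c("node_a", "node_b", "confidence")], path,
                   progress = FALSE)
  invisible(path)
}

# deterministic TSV writer used by the pipeline stages
write_stage_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
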