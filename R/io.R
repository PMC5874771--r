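# Readers/writers for the tabular formats and the JSON snapshot.
#
# Canonical tabular dialect: UTF-8 TSV with a header row and "." for absent
# fields; CSV accepted via `delim = ","`. Readers either load a row or
# quarantine it with a reason — never a partial silent load.

read_table_file <- function(path, delim = "\t") {
  readr::read_delim(path, delim = delim, na = c("", "NA", "."),
                    col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE)
}

#' Read a gene list TSV
#'
#' Expects a header with `accession` (required) and optional `symbol`,
#' `chrom`, `start`, `end`, `strand` columns.
#'
#' @param path TSV file path.
#' @param delim Field delimiter; `"\t"` (default) or `","`.
#' @return A gene tibble as from [gene_table()].
#' @export
read_gene_list <- function(path, delim = "\t") {
  x <- read_table_file(path, delim)
  if (!"accession" %in% names(x)) {
    abort(paste0(path, ": missing required column 'accession'"),
          class = "gmx_format_error")
  }
  dup <- which(duplicated(x$accession) | duplicated(x$accession, fromLast = TRUE))
  if (length(dup) > 0) {
    abort(paste0(path, ": duplicate accession(s) in data row(s) ",
                 paste(sort(dup), collapse = ", ")),
          class = "gmx_duplication_error")
  }
  for (nm in c("start", "end")) {
    if (nm %in% names(x)) {
      num <- suppressWarnings(as.numeric(x[[nm]]))
      bad <- which(!is.na(x[[nm]]) & is.na(num))
      if (length(bad) > 0) {
        abort(paste0(path, ": non-numeric ", nm, " in data row(s) ",
                     paste(bad, collapse = ", ")),
              class = "gmx_format_error")
      }
      x[[nm]] <- num
    }
  }
  gene_table(x)
}

iso_date_ok <- function(x) {
  !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}", x) &
    !is.na(suppressWarnings(as.Date(substr(x, 1, 10))))
}

#' Read and validate long-format descriptor values
#'
#' Each row is checked against its descriptor's pattern (declared id, a
#' non-negative number, whole numbers for `count` descriptors, an ISO date
#' when a timestamp is present). Failing rows are quarantined with a reason,
#' never silently dropped or loaded: accepted + quarantined = input rows.
#'
#' @param path TSV with columns `gene`, `descriptor`, `value`, optional
#'   `source`, `timestamp`.
#' @param descriptors Descriptor catalog ([descriptor_table()]).
#' @param delim Field delimiter.
#' @return List with `accepted` (value tibble) and `rejects` (tibble: `row`,
#'   `gene`, `descriptor`, `reason`).
#' @export
read_descriptor_values <- function(path, descriptors, delim = "\t") {
  descriptors <- descriptor_table(descriptors)
  x <- read_table_file(path, delim)
  need <- c("gene", "descriptor", "value")
  if (!all(need %in% names(x))) {
    abort(paste0(path, ": missing required column(s): ",
                 paste(setdiff(need, names(x)), collapse = ", ")),
          class = "gmx_format_error")
  }
  if (!"source" %in% names(x)) x$source <- NA_character_
  if (!"timestamp" %in% names(x)) x$timestamp <- NA_character_

  num <- suppressWarnings(as.numeric(x$value))
  kind <- descriptors$value_kind[match(x$descriptor, descriptors$id)]
  reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, why) reason <<- ifelse(is.na(reason) & cond, why, reason)
  flag(is.na(x$gene) | !nzchar(x$gene %||% ""), "missing gene accession")
  flag(is.na(x$descriptor), "missing descriptor id")
  flag(!is.na(x$descriptor) & is.na(kind), "unknown descriptor id")
  flag(is.na(x$value), "missing value")
  flag(!is.na(x$value) & is.na(num), "non-numeric value")
  flag(!is.na(num) & num < 0, "negative value")
  flag(!is.na(num) & !is.na(kind) & kind == "count" & num != floor(num),
       "non-integer value for count descriptor")
  flag(!is.na(x$timestamp) & !iso_date_ok(x$timestamp),
       "timestamp is not an ISO-8601 date")

  ok <- is.na(reason)
  accepted <- tibble(gene = x$gene[ok], descriptor = x$descriptor[ok],
                     value = num[ok], source = x$source[ok],
                     timestamp = x$timestamp[ok])
  rejects <- tibble(row = which(!ok), gene = x$gene[!ok],
                    descriptor = x$descriptor[!ok], reason = reason[!ok])
  list(accepted = accepted, rejects = rejects)
}

# -- JSON snapshot -----------------------------------------------------------

SNAPSHOT_REQUIRED <- c("version_id", "created", "genes", "descriptors", "cells")

#' Export a dataset version (or bare matrix) as a JSON snapshot
#'
#' The snapshot is a single JSON document `{version_id, created, provenance,
#' genes[], descriptors[], tracks[], cells[]}` that [import_matrix()] reads
#' back to an identical logical content.
#'
#' @param x A `dataset_version` or `heat_matrix` (a bare matrix is wrapped as
#'   version `"unversioned"`).
#' @param path Optional file to write; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
export_matrix <- function(x, path = NULL) {
  v <- if (inherits(x, "dataset_version")) x
       else dataset_version(x, "unversioned")
  m <- v$matrix
  doc <- list(
    version_id = v$version_id,
    created = v$created,
    provenance = v$provenance,
    genes = m$genes,
    descriptors = m$descriptors,
    tracks = if (nrow(m$tracks) == 0) list() else
      lapply(seq_len(nrow(m$tracks)), function(i) list(
        id = m$tracks$id[i],
        descriptor_ids = as.list(m$tracks$descriptor_ids[[i]]),
        description = m$tracks$description[i]
      )),
    cells = m$cells
  )
  json <- jsonlite::toJSON(doc, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(as.character(json))
}

#' Import a JSON snapshot
#'
#' @param x JSON string or path to a snapshot file.
#' @return A `dataset_version` whose matrix round-trips [export_matrix()]
#'   bit-exactly on the logical content.
#' @export
import_matrix <- function(x) {
  doc <- tryCatch(
    jsonlite::fromJSON(x, simplifyVector = TRUE),
    error = function(e) abort(paste0("snapshot is not valid JSON: ",
                                     conditionMessage(e)),
                              class = "gmx_validation_error")
  )
  for (key in SNAPSHOT_REQUIRED) {
    if (!key %in% names(doc)) {
      abort(paste0("snapshot schema violation at $.", key, ": missing"),
            class = "gmx_validation_error")
    }
  }
  as_records <- function(d, cols, where) {
    if (is.null(d) || length(d) == 0) {
      return(as_tibble(setNames(rep(list(character()), length(cols)), cols)))
    }
    if (!is.data.frame(d)) {
      abort(paste0("snapshot schema violation at $.", where,
                   ": expected an array of objects"),
            class = "gmx_validation_error")
    }
    miss <- setdiff(cols[1], names(d))  # first column is the required key
    if (length(miss) > 0) {
      abort(paste0("snapshot schema violation at $.", where, "[].", miss[1],
                   ": missing"),
            class = "gmx_validation_error")
    }
    as_tibble(d)
  }
  genes <- as_records(doc$genes, c("accession"), "genes")
  descriptors <- as_records(doc$descriptors, c("id"), "descriptors")
  cells <- doc$cells
  if (!is.null(cells) && length(cells) > 0) {
    if (!is.data.frame(cells) || !all(c("gene", "descriptor", "value") %in% names(cells))) {
      abort("snapshot schema violation at $.cells[]: need gene, descriptor, value",
            class = "gmx_validation_error")
    }
  } else {
    cells <- NULL
  }
  tracks <- NULL
  if (!is.null(doc$tracks) && length(doc$tracks) > 0) {
    tr <- doc$tracks
    tracks <- tibble(
      id = as.character(tr$id),
      descriptor_ids = lapply(tr$descriptor_ids, unlist),
      description = as.character(tr$description %||% NA_character_)
    )
  }
  m <- heat_matrix(genes, descriptors, tracks, cells)
  dataset_version(m, doc$version_id, doc$created,
                  doc$provenance %||% NA_character_)
}

#' Write a tibble as canonical TSV
#'
#' @param x Data frame; list columns are flattened to comma-separated text.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_canonical <- function(x, path) {
  x <- as_tibble(x)
  for (nm in names(x)) {
    if (is.list(x[[nm]])) {
      x[[nm]] <- vapply(x[[nm]], function(v) paste(v, collapse = ","), character(1))
    }
  }
  readr::write_tsv(x, path, na = ".")
  invisible(path)
}
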