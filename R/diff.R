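#' Snapshot a heat matrix as an immutable dataset version
#'
#' Versioned snapshots are how the curation history is kept honest: each
#' refresh produces a new version, and [diff_versions()] reports exactly what
#' moved between two of them.
#'
#' @param matrix A `heat_matrix`.
#' @param version_id Unique version label.
#' @param created ISO-8601 date string (defaults to today).
#' @param provenance Free-text notes.
#' @return An object of class `dataset_version`.
#' @export
dataset_version <- function(matrix, version_id, created = format(Sys.Date()),
                            provenance = NA_character_) {
  stopifnot(inherits(matrix, "heat_matrix"))
  if (!is.character(version_id) || length(version_id) != 1 || !nzchar(version_id)) {
    abort("version_id must be a non-empty string", class = "gmx_validation_error")
  }
  structure(list(version_id = version_id, created = as.character(created),
                 matrix = matrix, provenance = as.character(provenance)),
            class = "dataset_version")
}

#' @export
print.dataset_version <- function(x, ...) {
  cat(sprintf("<dataset_version> %s (%s): ", x$version_id, x$created))
  print(x$matrix)
  invisible(x)
}

as_heat_matrix <- function(x) {
  if (inherits(x, "dataset_version")) x$matrix
  else if (inherits(x, "heat_matrix")) x
  else abort("expected a heat_matrix or dataset_version", class = "gmx_validation_error")
}

#' Diff two dataset versions
#'
#' Computes the set differences of genes and descriptors and every cell whose
#' value differs between the two versions, including absent-to-present and
#' present-to-absent transitions (absence is encoded as `NA`). The report is
#' self-contained: it also carries the full added gene/descriptor rows and
#' the new cells' source/timestamp so [apply_diff()] can replay it onto the
#' old version. Diffing is value-level: a cell whose source annotation alone
#' changed is not reported.
#'
#' `diff_versions(a, a)` is empty; swapping the arguments swaps the
#' added/removed roles and the old/new columns.
#'
#' @param a,b `dataset_version` (or bare `heat_matrix`) old and new.
#' @return An object of class `diff_report` with components `added_genes`,
#'   `removed_genes`, `added_descriptors`, `removed_descriptors`,
#'   `changed_cells` (tibble: `gene`, `descriptor`, `old`, `new`,
#'   `new_source`, `new_timestamp`), plus `added_gene_entries` and
#'   `added_descriptor_entries`.
#' @export
diff_versions <- function(a, b) {
  ma <- as_heat_matrix(a); mb <- as_heat_matrix(b)
  added_genes   <- setdiff(mb$genes$accession, ma$genes$accession)
  removed_genes <- setdiff(ma$genes$accession, mb$genes$accession)
  added_desc    <- setdiff(mb$descriptors$id, ma$descriptors$id)
  removed_desc  <- setdiff(ma$descriptors$id, mb$descriptors$id)

  key <- function(cells) paste(cells$gene, cells$descriptor, sep = "\r")
  ca <- ma$cells; cb <- mb$cells
  all_keys <- union(key(ca), key(cb))
  old <- setNames(rep(NA_real_, length(all_keys)), all_keys)
  new <- old
  new_source <- setNames(rep(NA_character_, length(all_keys)), all_keys)
  new_timestamp <- new_source
  old[key(ca)] <- ca$value
  new[key(cb)] <- cb$value
  new_source[key(cb)] <- cb$source
  new_timestamp[key(cb)] <- cb$timestamp
  changed <- xor(is.na(old), is.na(new)) | (!is.na(old) & !is.na(new) & old != new)
  parts <- strsplit(all_keys[changed], "\r", fixed = TRUE)
  changed_cells <- tibble(
    gene = vapply(parts, `[[`, "", 1),
    descriptor = vapply(parts, `[[`, "", 2),
    old = unname(old[changed]),
    new = unname(new[changed]),
    new_source = unname(new_source[changed]),
    new_timestamp = unname(new_timestamp[changed])
  )
  changed_cells <- arrange(changed_cells, .data$gene, .data$descriptor)

  structure(list(
    added_genes = added_genes, removed_genes = removed_genes,
    added_descriptors = added_desc, removed_descriptors = removed_desc,
    changed_cells = changed_cells,
    added_gene_entries = mb$genes[mb$genes$accession %in% added_genes, ],
    added_descriptor_entries = mb$descriptors[mb$descriptors$id %in% added_desc, ]
  ), class = "diff_report")
}

#' @export
print.diff_report <- function(x, ...) {
  cat(sprintf(paste0("<diff_report> +%d/-%d genes, +%d/-%d descriptors, ",
                     "%d changed cells\n"),
              length(x$added_genes), length(x$removed_genes),
              length(x$added_descriptors), length(x$removed_descriptors),
              nrow(x$changed_cells)))
  invisible(x)
}

#' Is a diff report empty?
#' @param report A `diff_report`.
#' @return `TRUE` when the two versions were identical in logical content.
#' @export
diff_is_empty <- function(report) {
  stopifnot(inherits(report, "diff_report"))
  length(report$added_genes) == 0 && length(report$removed_genes) == 0 &&
    length(report$added_descriptors) == 0 && length(report$removed_descriptors) == 0 &&
    nrow(report$changed_cells) == 0
}

#' Apply a diff report to a matrix (patch)
#'
#' Replays a [diff_versions()] report onto the old matrix, reproducing the
#' new version's logical content (genes, descriptors, cell values).
#'
#' @param a The old `dataset_version` or `heat_matrix`.
#' @param report A `diff_report` from `diff_versions(a, b)`.
#' @return A `heat_matrix` equal in logical content to `b`.
#' @export
apply_diff <- function(a, report) {
  stopifnot(inherits(report, "diff_report"))
  m <- as_heat_matrix(a)
  genes <- m$genes[!m$genes$accession %in% report$removed_genes, ]
  genes <- bind_rows(genes, report$added_gene_entries)
  descs <- m$descriptors[!m$descriptors$id %in% report$removed_descriptors, ]
  descs <- bind_rows(descs, report$added_descriptor_entries)

  cells <- m$cells[m$cells$gene %in% genes$accession &
                     m$cells$descriptor %in% descs$id, ]
  ch <- report$changed_cells
  drop_key <- paste(ch$gene, ch$descriptor, sep = "\r")
  cells <- cells[!paste(cells$gene, cells$descriptor, sep = "\r") %in% drop_key, ]
  adds <- ch[!is.na(ch$new), ]
  cells <- bind_rows(cells, tibble(
    gene = adds$gene, descriptor = adds$descriptor, value = adds$new,
    source = adds$new_source, timestamp = adds$new_timestamp
  ))
  # drop tracks referencing removed descriptors
  tracks <- m$tracks
  if (nrow(tracks) > 0) {
    keep <- vapply(tracks$descriptor_ids, function(d) all(d %in% descs$id), logical(1))
    tracks <- tracks[keep, ]
  }
  heat_matrix(genes, descs, tracks, cells)
}
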