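# Source-adapter contract: the offline stand-in for scheduled public-database
# connectors. An adapter declares which descriptors it serves and exposes a
# fetch function over accessions; refresh merges its records into a new
# dataset version atomically (a misbehaving adapter aborts the refresh and
# leaves the version store untouched).

#' Define a source adapter
#'
#' @param source_id Source label stamped into fetched records.
#' @param descriptor_ids Descriptor ids this adapter serves.
#' @param fetch `function(accessions)` returning a tibble of descriptor
#'   values (`gene`, `descriptor`, `value`, optional `source`, `timestamp`)
#'   restricted to the requested accessions and served descriptors.
#' @param refresh_interval Informational cadence label (e.g. `"P1M"`); no
#'   scheduler is implemented.
#' @return An object of class `source_adapter`.
#' @export
source_adapter <- function(source_id, descriptor_ids, fetch,
                           refresh_interval = "P1M") {
  if (length(descriptor_ids) < 1) {
    abort("adapter must serve at least one descriptor", class = "gmx_validation_error")
  }
  stopifnot(is.function(fetch))
  structure(list(source_id = source_id,
                 descriptor_ids = as.character(descriptor_ids),
                 fetch = fetch,
                 refresh_interval = refresh_interval),
            class = "source_adapter")
}

#' File/table-backed fixture adapter
#'
#' Serves descriptor values from an in-memory table — the offline equivalent
#' of a public-database connector with a frozen underlying snapshot (fetch is
#' idempotent by construction).
#'
#' @param source_id Source label.
#' @param table Value tibble (`gene`, `descriptor`, `value`, optional
#'   `timestamp`).
#' @param timestamp Default timestamp stamped on records lacking one.
#' @return A `source_adapter`.
#' @export
fixture_adapter <- function(source_id, table, timestamp = format(Sys.Date())) {
  table <- as_tibble(table)
  source_adapter(
    source_id,
    unique(table$descriptor),
    fetch = function(accessions) {
      hit <- table[table$gene %in% accessions, ]
      hit$source <- source_id
      if (!"timestamp" %in% names(hit) || all(is.na(hit$timestamp))) {
        hit$timestamp <- timestamp
      }
      hit
    }
  )
}

#' Refresh a dataset version from a source adapter
#'
#' Fetches the adapter's records for the requested accessions, validates them
#' against the adapter contract (only requested accessions, only served
#' descriptors, non-negative values), merges them into a fresh snapshot and
#' diffs it against the previous version. Atomic: any contract violation
#' aborts before a new version exists, and the previous version is never
#' modified.
#'
#' @param adapter A [source_adapter()].
#' @param accessions Accessions to refresh (must be declared in `current`).
#' @param current The current `dataset_version`.
#' @param version_id Id for the new version (default: current id +
#'   `"+<source>"`).
#' @param created ISO date of the new version.
#' @return List with `version` (new `dataset_version`) and `diff`
#'   (`diff_report` old -> new).
#' @export
run_adapter_refresh <- function(adapter, accessions, current,
                                version_id = NULL,
                                created = format(Sys.Date())) {
  stopifnot(inherits(adapter, "source_adapter"),
            inherits(current, "dataset_version"))
  m <- current$matrix
  unknown <- setdiff(accessions, m$genes$accession)
  if (length(unknown) > 0) {
    abort(paste0("refresh requested for undeclared accession(s): ",
                 paste(unknown, collapse = ", ")),
          class = "gmx_reference_error")
  }
  fetched <- as_tibble(adapter$fetch(accessions))
  if (nrow(fetched) > 0) {
    need <- c("gene", "descriptor", "value")
    if (!all(need %in% names(fetched))) {
      abort("adapter contract violation: fetched records lack gene/descriptor/value",
            class = "gmx_contract_error")
    }
    if (!all(fetched$gene %in% accessions)) {
      abort("adapter contract violation: record for unrequested accession",
            class = "gmx_contract_error")
    }
    if (!all(fetched$descriptor %in% adapter$descriptor_ids)) {
      abort("adapter contract violation: record for unserved descriptor",
            class = "gmx_contract_error")
    }
    if (!all(fetched$descriptor %in% m$descriptors$id)) {
      abort("adapter contract violation: record for descriptor not in the matrix",
            class = "gmx_contract_error")
    }
    if (anyNA(fetched$value) || any(fetched$value < 0)) {
      abort("adapter contract violation: missing or negative value",
            class = "gmx_contract_error")
    }
    if (anyDuplicated(paste(fetched$gene, fetched$descriptor, sep = "\r"))) {
      abort("adapter contract violation: duplicate (gene, descriptor) record",
            class = "gmx_contract_error")
    }
    if (!"source" %in% names(fetched) || anyNA(fetched$source)) {
      fetched$source <- adapter$source_id
    }
    if (!"timestamp" %in% names(fetched)) fetched$timestamp <- created
  }
  cells <- m$cells
  if (nrow(fetched) > 0) {
    drop <- paste(cells$gene, cells$descriptor, sep = "\r") %in%
      paste(fetched$gene, fetched$descriptor, sep = "\r")
    cells <- bind_rows(cells[!drop, ], normalize_cells(fetched))
  }
  new_matrix <- heat_matrix(m$genes, m$descriptors, m$tracks, cells)
  new_version <- dataset_version(
    new_matrix,
    version_id %||% paste0(current$version_id, "+", adapter$source_id),
    created,
    provenance = paste0("refresh from ", adapter$source_id)
  )
  list(version = new_version, diff = diff_versions(current, new_version))
}
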