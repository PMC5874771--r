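#' @importFrom rlang abort %||%
#' @importFrom dplyr filter mutate select arrange bind_rows group_by summarise
#'   count
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats setNames
NULL

# -- constructors ------------------------------------------------------------

VALUE_KINDS <- c("count", "level", "score", "boolean", "expression")

#' Declare the gene rows of a heat matrix
#'
#' Normalizes a data frame of protein-coding genes into the canonical gene
#' table: one row per curated accession with optional symbol, chromosome and
#' 1-based inclusive coordinates. Accessions must be unique and non-empty;
#' `start <= end` is enforced whenever both are present.
#'
#' @param x A data frame with at least an `accession` column; `symbol`,
#'   `chrom`, `start`, `end` and `strand` (`+`, `-` or `unknown`) are optional.
#' @return A tibble with columns `accession`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
gene_table <- function(x) {
  x <- as_tibble(x)
  if (!"accession" %in% names(x)) {
    abort("gene table must have an `accession` column", class = "gmx_format_error")
  }
  acc <- as.character(x$accession)
  if (anyNA(acc) || any(!nzchar(acc))) {
    abort("gene accessions must be non-empty", class = "gmx_validation_error")
  }
  if (anyDuplicated(acc)) {
    dup <- unique(acc[duplicated(acc)])
    abort(paste0("duplicate gene accession(s): ", paste(dup, collapse = ", ")),
          class = "gmx_duplication_error")
  }
  out <- tibble(
    accession = acc,
    symbol = as.character(x[["symbol"]] %||% NA_character_),
    chrom  = as.character(x[["chrom"]] %||% NA_character_),
    start  = as.double(x[["start"]] %||% NA_real_),
    end    = as.double(x[["end"]] %||% NA_real_),
    strand = as.character(x[["strand"]] %||% "unknown")
  )
  out$strand[is.na(out$strand)] <- "unknown"
  bad_strand <- !out$strand %in% c("+", "-", "unknown")
  if (any(bad_strand)) {
    abort(paste0("invalid strand value(s): ",
                 paste(unique(out$strand[bad_strand]), collapse = ", ")),
          class = "gmx_validation_error")
  }
  bad <- !is.na(out$start) & !is.na(out$end) & out$start > out$end
  if (any(bad)) {
    abort(paste0("start > end for gene(s): ",
                 paste(out$accession[bad], collapse = ", ")),
          class = "gmx_validation_error")
  }
  out
}

#' Declare the descriptor columns of a heat matrix
#'
#' A descriptor is one evidence column (e.g. `PE`, `DB`, `CF`, `S2`...`S7`,
#' `AB`, `B`, `I`, `S9`). Its `value_kind` fixes what the stored numbers mean
#' and is used by the input validators (counts must be whole numbers).
#'
#' @param x A data frame with an `id` column; `label`, `value_kind` (one of
#'   `count`, `level`, `score`, `boolean`, `expression`), `owner` and
#'   `scheme_id` are optional (`value_kind` defaults to `"level"`,
#'   `scheme_id` to `"auto"`).
#' @return A tibble with columns `id`, `label`, `value_kind`, `owner`,
#'   `scheme_id`.
#' @export
descriptor_table <- function(x) {
  x <- as_tibble(x)
  if (!"id" %in% names(x)) {
    abort("descriptor table must have an `id` column", class = "gmx_format_error")
  }
  id <- as.character(x$id)
  if (anyNA(id) || any(!nzchar(id))) {
    abort("descriptor ids must be non-empty", class = "gmx_validation_error")
  }
  if (anyDuplicated(id)) {
    abort(paste0("duplicate descriptor id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")),
          class = "gmx_duplication_error")
  }
  kind <- as.character(x[["value_kind"]] %||% "level")
  kind[is.na(kind)] <- "level"
  if (!all(kind %in% VALUE_KINDS)) {
    abort(paste0("value_kind must be one of: ", paste(VALUE_KINDS, collapse = ", ")),
          class = "gmx_validation_error")
  }
  tibble(
    id = id,
    label = as.character(x[["label"]] %||% id),
    value_kind = kind,
    owner = as.character(x[["owner"]] %||% NA_character_),
    scheme_id = { s <- as.character(x[["scheme_id"]] %||% "auto"); s[is.na(s)] <- "auto"; s }
  )
}

#' Group descriptors into ordered tracks
#'
#' @param x A data frame with columns `id` and `descriptor_ids` (a list column
#'   of character vectors, or a comma-separated string), plus optional
#'   `description`. `NULL` yields an empty track table.
#' @param descriptors The descriptor table the ids must resolve against.
#' @return A tibble with columns `id`, `descriptor_ids` (list), `description`.
#' @export
track_table <- function(x = NULL, descriptors = NULL) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(tibble(id = character(), descriptor_ids = list(), description = character()))
  }
  x <- as_tibble(x)
  ids <- as.character(x$id)
  if (anyDuplicated(ids)) abort("duplicate track ids", class = "gmx_duplication_error")
  dlist <- x$descriptor_ids
  if (!is.list(dlist)) dlist <- strsplit(as.character(dlist), ",[ ]*")
  dlist <- lapply(dlist, as.character)
  for (i in seq_along(dlist)) {
    d <- dlist[[i]]
    if (length(d) == 0) abort(paste0("track ", ids[i], " is empty"), class = "gmx_validation_error")
    if (anyDuplicated(d)) abort(paste0("track ", ids[i], " repeats a descriptor"),
                                class = "gmx_validation_error")
    if (!is.null(descriptors) && !all(d %in% descriptors$id)) {
      abort(paste0("track ", ids[i], " references unknown descriptor(s): ",
                   paste(setdiff(d, descriptors$id), collapse = ", ")),
            class = "gmx_reference_error")
    }
  }
  tibble(id = ids, descriptor_ids = dlist,
         description = as.character(x[["description"]] %||% NA_character_))
}

normalize_cells <- function(values) {
  if (is.null(values) || (is.data.frame(values) && nrow(values) == 0)) {
    return(tibble(gene = character(), descriptor = character(), value = double(),
                  source = character(), timestamp = character()))
  }
  values <- as_tibble(values)
  need <- c("gene", "descriptor", "value")
  if (!all(need %in% names(values))) {
    abort(paste0("descriptor values need columns: ", paste(need, collapse = ", ")),
          class = "gmx_format_error")
  }
  tibble(
    gene = as.character(values$gene),
    descriptor = as.character(values$descriptor),
    value = as.double(values$value),
    source = as.character(values[["source"]] %||% NA_character_),
    timestamp = as.character(values[["timestamp"]] %||% NA_character_)
  )
}

#' Assemble a genes-by-descriptors heat matrix
#'
#' The heat matrix is the central container: an ordered gene list, an ordered
#' descriptor list, optional tracks, and a sparse cell table of descriptor
#' values. A missing cell means "no data", which is distinct from a stored
#' value of 0 (a stored 0 is kept as provenance and only rendered like
#' absence by the colour quantizer).
#'
#' @param genes,descriptors,tracks,values Passed through [gene_table()],
#'   [descriptor_table()], [track_table()] and cell normalization. `values`
#'   needs columns `gene`, `descriptor`, `value` (non-negative), optional
#'   `source` and `timestamp`.
#' @return An object of class `heat_matrix` with components `genes`,
#'   `descriptors`, `tracks`, `cells` (all tibbles).
#' @examples
#' m <- heat_matrix(
#'   data.frame(accession = c("P1", "P2")),
#'   data.frame(id = c("PE", "CF")),
#'   values = data.frame(gene = "P1", descriptor = "PE", value = 1)
#' )
#' glance(m)
#' @export
heat_matrix <- function(genes, descriptors, tracks = NULL, values = NULL) {
  genes <- gene_table(genes)
  descriptors <- descriptor_table(descriptors)
  tracks <- track_table(tracks, descriptors)
  cells <- normalize_cells(values)

  bad_gene <- !cells$gene %in% genes$accession
  if (any(bad_gene)) {
    abort(paste0("descriptor value references undeclared gene(s): ",
                 paste(unique(cells$gene[bad_gene]), collapse = ", ")),
          class = "gmx_reference_error")
  }
  bad_desc <- !cells$descriptor %in% descriptors$id
  if (any(bad_desc)) {
    abort(paste0("descriptor value references undeclared descriptor(s): ",
                 paste(unique(cells$descriptor[bad_desc]), collapse = ", ")),
          class = "gmx_reference_error")
  }
  if (anyNA(cells$value) || any(cells$value < 0)) {
    abort("descriptor values must be non-negative numbers", class = "gmx_validation_error")
  }
  key <- paste(cells$gene, cells$descriptor, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort(paste0("duplicate (gene, descriptor) cell(s): ",
                 paste(gsub("\r", "/", dup), collapse = ", ")),
          class = "gmx_duplication_error")
  }
  structure(list(genes = genes, descriptors = descriptors,
                 tracks = tracks, cells = cells),
            class = "heat_matrix")
}

#' @export
print.heat_matrix <- function(x, ...) {
  cat(sprintf("<heat_matrix> %d genes x %d descriptors, %d populated cells, %d tracks\n",
              nrow(x$genes), nrow(x$descriptors), nrow(x$cells), nrow(x$tracks)))
  invisible(x)
}

#' @export
dim.heat_matrix <- function(x) c(nrow(x$genes), nrow(x$descriptors))

# value lookup: named numeric vector over genes for one descriptor (NA = absent)
descriptor_column <- function(m, descriptor) {
  if (!descriptor %in% m$descriptors$id) {
    abort(paste0("unknown descriptor: ", descriptor), class = "gmx_reference_error")
  }
  v <- setNames(rep(NA_real_, nrow(m$genes)), m$genes$accession)
  hit <- m$cells[m$cells$descriptor == descriptor, ]
  v[hit$gene] <- hit$value
  v
}

# -- sorting and selection ---------------------------------------------------

#' Sort heat-matrix rows by one descriptor
#'
#' Reorders the gene rows by the cell value of one descriptor. Ties are always
#' broken by accession in ascending lexicographic order, so the output is
#' deterministic regardless of input order. Genes with no cell for the
#' descriptor are placed according to `absent_policy`.
#'
#' @param matrix A `heat_matrix`.
#' @param descriptor A declared descriptor id.
#' @param order `"asc"` or `"desc"`.
#' @param absent_policy `"last"` (default) or `"first"`.
#' @return A new `heat_matrix` with permuted gene order; the input is
#'   untouched.
#' @export
sort_rows <- function(matrix, descriptor, order = c("asc", "desc"),
                      absent_policy = c("last", "first")) {
  stopifnot(inherits(matrix, "heat_matrix"))
  order <- match.arg(order)
  absent_policy <- match.arg(absent_policy)
  v <- descriptor_column(matrix, descriptor)
  absent <- is.na(v)
  absent_key <- if (absent_policy == "last") absent else !absent
  vkey <- if (order == "asc") v else -v
  vkey[absent] <- 0  # neutral; absent_key already separates them
  idx <- base::order(absent_key, vkey, matrix$genes$accession, method = "radix")
  out <- matrix
  out$genes <- matrix$genes[idx, ]
  out
}

#' Select heat-matrix rows with a descriptor predicate
#'
#' Filters genes with a small infix predicate language over descriptor
#' values: comparisons (`=`, `!=`, `<`, `<=`, `>`, `>=`) between a descriptor
#' id and a number, combined with `AND`, `OR`, `NOT`, parentheses, the
#' constants `TRUE`/`FALSE`, and `ABSENT(desc)` which is true when the gene
#' has no cell for that descriptor. A comparison against an absent cell is
#' false (absence is not a number).
#'
#' @param matrix A `heat_matrix`.
#' @param predicate A predicate string, e.g. `"CF = 0 AND (S2 > 0 OR S3 > 0)"`.
#' @return A `heat_matrix` containing exactly the satisfying genes (original
#'   order preserved); the descriptor set is unchanged.
#' @export
select_rows <- function(matrix, predicate) {
  stopifnot(inherits(matrix, "heat_matrix"))
  ast <- parse_predicate(predicate)
  refs <- predicate_descriptors(ast)
  unknown <- setdiff(refs, matrix$descriptors$id)
  if (length(unknown) > 0) {
    abort(paste0("predicate references unknown descriptor(s): ",
                 paste(unknown, collapse = ", ")),
          class = "gmx_reference_error")
  }
  cols <- lapply(setNames(refs, refs), function(d) descriptor_column(matrix, d))
  keep <- vapply(seq_len(nrow(matrix$genes)), function(i) {
    eval_predicate(ast, lapply(cols, `[[`, i))
  }, logical(1))
  out <- matrix
  out$genes <- matrix$genes[keep, ]
  out$cells <- matrix$cells[matrix$cells$gene %in% out$genes$accession, ]
  out
}

# canonical equality on logical content (row order ignored, value-level cells)
matrix_equal <- function(a, b) {
  norm <- function(m) {
    list(
      genes = arrange(m$genes, .data$accession),
      descriptors = arrange(m$descriptors, .data$id),
      cells = arrange(select(m$cells, "gene", "descriptor", "value"),
                      .data$gene, .data$descriptor)
    )
  }
  identical(norm(a), norm(b))
}
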