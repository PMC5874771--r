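#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a heat matrix into its long cell table
#'
#' @param x A `heat_matrix`.
#' @param ... Unused.
#' @return Tibble of populated cells: `gene`, `descriptor`, `value`,
#'   `source`, `timestamp`.
#' @export
tidy.heat_matrix <- function(x, ...) as_tibble(x$cells)

#' @export
glance.heat_matrix <- function(x, ...) {
  tibble(n_genes = nrow(x$genes), n_descriptors = nrow(x$descriptors),
         n_tracks = nrow(x$tracks), n_cells = nrow(x$cells),
         fill_fraction = if (nrow(x$genes) * nrow(x$descriptors) == 0) NA_real_
                         else nrow(x$cells) / (nrow(x$genes) * nrow(x$descriptors)))
}

#' @export
tidy.triage_result <- function(x, ...) as_tibble(x$decisions)

#' @export
glance.triage_result <- function(x, ...) {
  counts <- x$decisions |> count(.data$category, name = "n")
  wide <- setNames(as.list(counts$n), tolower(counts$category))
  as_tibble(c(list(n_records = nrow(x$decisions),
                   n_biomaterials = length(unique(x$decisions$biomaterial))),
              wide))
}

#' @export
tidy.coverage_report <- function(x, ...) as_tibble(x$per_source)

#' @export
glance.coverage_report <- function(x, ...) {
  tibble(n_genes = x$n_genes, n_sources = nrow(x$per_source),
         union_fraction = x$union_fraction, missing_fraction = x$missing_fraction)
}

#' @export
tidy.diff_report <- function(x, ...) as_tibble(x$changed_cells)

#' @export
glance.diff_report <- function(x, ...) {
  tibble(added_genes = length(x$added_genes),
         removed_genes = length(x$removed_genes),
         added_descriptors = length(x$added_descriptors),
         removed_descriptors = length(x$removed_descriptors),
         changed_cells = nrow(x$changed_cells),
         empty = diff_is_empty(x))
}

GMX_COLOR_VALUES <- c(black = "#000000", red = "#d62728", orange = "#ff7f0e",
                      yellow = "#e6c300", green = "#2ca02c")

#' Plot a heat matrix as a coloured tile grid
#'
#' Renders the quantized colour grid of [colorize_matrix()]: black means no
#' data (or a stored zero), the red-to-green ramp tracks the amount of
#' evidence relative to each descriptor column's maximum.
#'
#' @param object A `heat_matrix`.
#' @param schemes Optional scheme registry ([register_scheme()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.heat_matrix <- function(object, schemes = NULL, ...) {
  grid <- colorize_matrix(object, schemes)
  grid$gene <- factor(grid$gene, levels = rev(object$genes$accession))
  grid$descriptor <- factor(grid$descriptor, levels = object$descriptors$id)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$descriptor, y = .data$gene,
                                     fill = .data$color)) +
    ggplot2::geom_tile(color = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = GMX_COLOR_VALUES, guide = "none") +
    ggplot2::labs(x = "descriptor", y = "gene") +
    ggplot2::theme_minimal()
}

#' Plot triage category counts per biomaterial
#'
#' @param object A `triage_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triage_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$biomaterial, y = .data$n,
                               fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "biomaterial", y = "genes", fill = "category") +
    ggplot2::theme_minimal()
}

#' Plot per-source and union coverage
#'
#' @param object A `coverage_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_report <- function(object, ...) {
  df <- bind_rows(
    object$per_source[c("source", "fraction")],
    tibble(source = "union", fraction = object$union_fraction)
  )
  df$source <- factor(df$source, levels = df$source)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2ca02c") +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "chromosome coverage") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
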