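# Colour quantization of descriptor values.
#
# The automatic scheme bins the fraction value/column-max into five half-open
# intervals (0,0.2], (0.2,0.4], (0.4,0.6], (0.6,0.8], (0.8,1.0] — open at the
# bottom so 0 is excluded, closed at the top so the column maximum lands in
# the top bin. Absence of data and a stored 0 both render black; everything
# else ramps red (little data) to green (sufficient data).

AUTO_BOUNDARIES <- c(1, 2, 3, 4, 5) / 5
AUTO_COLORS <- c("red", "red", "orange", "yellow", "green")

#' Define a colour scheme for a descriptor
#'
#' Auto mode uses the fixed 20% thresholds of the per-column maximum; custom
#' mode lets a descriptor owner supply raw-value bin boundaries.
#'
#' @param id Scheme identifier.
#' @param mode `"auto"` or `"custom"`.
#' @param boundaries For custom mode, strictly increasing upper bin bounds on
#'   the raw value scale; the final bound may be `Inf`. Ignored in auto mode.
#' @param colors One colour label per bin, low to high. Defaults to the
#'   red-to-green ramp (auto) or a ramp cut to the number of bins (custom).
#' @param absent_color Colour for absent data and stored zeros (default
#'   `"black"`).
#' @param owner Free-text owner of the scheme.
#' @return An object of class `color_scheme`.
#' @export
color_scheme <- function(id = "auto", mode = c("auto", "custom"),
                         boundaries = NULL, colors = NULL,
                         absent_color = "black", owner = NA_character_) {
  mode <- match.arg(mode)
  if (mode == "auto") {
    boundaries <- AUTO_BOUNDARIES
    colors <- colors %||% AUTO_COLORS
  } else {
    boundaries <- as.double(boundaries)
    if (length(boundaries) < 1 || anyNA(boundaries)) {
      abort("custom scheme needs at least one numeric boundary",
            class = "gmx_validation_error")
    }
    if (any(diff(boundaries) <= 0)) {
      abort("scheme boundaries must be strictly increasing",
            class = "gmx_validation_error")
    }
    if (is.null(colors)) {
      ramp <- c("red", "orange", "yellow", "green")
      colors <- ramp[round(seq(1, 4, length.out = length(boundaries)))]
    }
    if (length(colors) != length(boundaries)) {
      abort("need one colour per bin", class = "gmx_validation_error")
    }
  }
  structure(list(id = id, mode = mode, boundaries = boundaries,
                 colors = as.character(colors),
                 absent_color = as.character(absent_color),
                 owner = as.character(owner)),
            class = "color_scheme")
}

bin_lookup <- function(frac_or_value, boundaries) {
  # half-open (lo, hi]: number of boundaries strictly below the value
  findInterval(frac_or_value, boundaries, left.open = TRUE)
}

#' Quantize descriptor values into colour bins
#'
#' Vectorized over `value`. Absent (`NA`) and 0 map to bin `NA` with the
#' absent colour; positive values land in exactly one bin.
#'
#' @param value Non-negative numeric vector (`NA` = absent).
#' @param max_value Positive column maximum used by auto mode; present values
#'   must not exceed it.
#' @param scheme A [color_scheme()]; default auto.
#' @return A tibble with columns `value`, `bin` (integer, `NA` for absent/0)
#'   and `color`.
#' @examples
#' quantize(c(NA, 0, 37, 100), max_value = 100)
#' @export
quantize <- function(value, max_value, scheme = color_scheme()) {
  stopifnot(inherits(scheme, "color_scheme"))
  value <- as.double(value)
  if (!is.numeric(max_value) || length(max_value) != 1 || is.na(max_value) ||
      max_value <= 0) {
    abort("max_value must be a positive number", class = "gmx_range_error")
  }
  if (any(value < 0, na.rm = TRUE)) {
    abort("values must be non-negative", class = "gmx_range_error")
  }
  if (any(value > max_value, na.rm = TRUE)) {
    abort("value exceeds max_value", class = "gmx_range_error")
  }
  x <- if (scheme$mode == "auto") value / max_value else value
  raw_bin <- bin_lookup(x, scheme$boundaries)
  # top boundary is closed: anything at the maximum stays in the last bin
  raw_bin <- pmin(raw_bin, length(scheme$boundaries) - 1L)
  absent <- is.na(value) | value == 0
  bin <- ifelse(absent, NA_integer_, as.integer(raw_bin))
  color <- ifelse(absent, scheme$absent_color, scheme$colors[raw_bin + 1L])
  tibble(value = value, bin = bin, color = color)
}

#' Create or extend a descriptor-to-scheme registry
#'
#' The registry records which colour scheme each descriptor uses; a
#' descriptor without an entry falls back to the automatic 20% scheme.
#' Re-registering a descriptor replaces its scheme.
#'
#' @param registry An existing registry (named list) or `NULL`.
#' @param descriptor Descriptor id.
#' @param scheme A [color_scheme()].
#' @return The updated registry (named list of `color_scheme`).
#' @export
register_scheme <- function(registry = NULL, descriptor, scheme) {
  stopifnot(inherits(scheme, "color_scheme"))
  registry <- registry %||% list()
  registry[[descriptor]] <- scheme
  registry
}

#' Colour an entire heat matrix
#'
#' Produces one quantized cell per (gene, descriptor) pair. For auto-mode
#' descriptors the normalizing maximum is the per-descriptor column maximum
#' over present values (descriptors carry incommensurate units, so a global
#' maximum would be meaningless). An all-absent column simply renders black.
#'
#' @param matrix A `heat_matrix`.
#' @param schemes Optional registry from [register_scheme()].
#' @return A tibble with one row per (gene, descriptor): `gene`,
#'   `descriptor`, `value`, `bin`, `color`.
#' @export
colorize_matrix <- function(matrix, schemes = NULL) {
  stopifnot(inherits(matrix, "heat_matrix"))
  genes <- matrix$genes$accession
  out <- vector("list", nrow(matrix$descriptors))
  for (j in seq_len(nrow(matrix$descriptors))) {
    d <- matrix$descriptors$id[j]
    scheme <- schemes[[d]] %||% color_scheme()
    v <- descriptor_column(matrix, d)
    mx <- suppressWarnings(max(v, na.rm = TRUE))
    if (!is.finite(mx) || mx <= 0) {
      # no positive data in the column: everything is absent/zero -> black
      q <- tibble(value = unname(v), bin = NA_integer_, color = scheme$absent_color)
    } else {
      q <- quantize(unname(v), mx, scheme)
    }
    out[[j]] <- tibble(gene = genes, descriptor = d, value = q$value,
                       bin = q$bin, color = q$color)
  }
  grid <- bind_rows(out)
  if (nrow(grid) == 0) {
    grid <- tibble(gene = character(), descriptor = character(),
                   value = double(), bin = integer(), color = character())
  }
  # order rows by matrix gene order then descriptor order
  grid$gene <- factor(grid$gene, levels = genes)
  grid$descriptor <- factor(grid$descriptor, levels = matrix$descriptors$id)
  grid <- arrange(grid, .data$gene, .data$descriptor)
  grid$gene <- as.character(grid$gene)
  grid$descriptor <- as.character(grid$descriptor)
  grid
}
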