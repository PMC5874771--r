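# Splice-aware missing-protein filtering, guilt-by-association ranking,
# chromosome coverage accounting, and SRM peptide susceptibility ranking.

SPLICE_FORMS <- paste0("S", 2:7)

#' Find genes missing because of splicing
#'
#' A gene is "missing because of splicing" in a biomaterial when its
#' canonical form shows no expression (`cf == 0`) while at least one splice
#' form S2..S7 is expressed. Genes with all forms silent are dark, not
#' splice-only, and are not returned.
#'
#' @param profiles Tibble with columns `gene`, `biomaterial`, `cf` and splice
#'   levels `s2`..`s7` (any subset; absent columns count as 0).
#' @return Tibble of the qualifying profiles: `gene`, `biomaterial`,
#'   `splice_forms` (list column of expressed form labels, e.g. `"S3"`).
#' @export
find_missing_spliced <- function(profiles) {
  p <- as_tibble(profiles)
  names(p) <- tolower(names(p))
  if (!all(c("gene", "cf") %in% names(p))) {
    abort("splice profiles need columns gene, cf", class = "gmx_format_error")
  }
  if (!"biomaterial" %in% names(p)) p$biomaterial <- "unspecified"
  scols <- intersect(tolower(SPLICE_FORMS), names(p))
  for (nm in scols) p[[nm]] <- as.double(p[[nm]])
  lev <- if (length(scols) > 0) as.matrix(p[scols]) else
    matrix(0, nrow(p), 0)
  lev[is.na(lev)] <- 0
  p$cf <- as.double(p$cf)
  p$cf[is.na(p$cf)] <- 0
  if (any(lev < 0) || any(p$cf < 0)) {
    abort("expression levels must be >= 0", class = "gmx_validation_error")
  }
  hit <- p$cf == 0 & rowSums(lev > 0) > 0
  out <- p[hit, c("gene", "biomaterial")]
  out$splice_forms <- lapply(which(hit), function(i) toupper(scols)[lev[i, ] > 0])
  as_tibble(out)
}

# auto-quantizer bin index used as the guilt-by-association unit: 0 for
# absent/zero, otherwise the 5-level bin of value/column-max (0-based).
gba_bin <- function(values) {
  v <- as.double(values)
  v[is.na(v)] <- 0
  if (any(v < 0)) abort("association counts must be >= 0", class = "gmx_validation_error")
  mx <- max(v)
  if (mx <= 0) return(rep(0L, length(v)))
  q <- quantize(ifelse(v == 0, NA, v), mx)
  ifelse(is.na(q$bin), 0L, q$bin)
}

STRING_BONUS <- c(S9 = 3, S7 = 2, S4 = 1, none = 0)

normalize_association <- function(rows) {
  a <- as_tibble(rows)
  names(a) <- tolower(names(a))
  if (!"gene" %in% names(a)) {
    abort("association rows need a gene column", class = "gmx_format_error")
  }
  for (nm in c("ab", "pa", "sl", "ns", "biogrid_count", "intact_count")) {
    if (!nm %in% names(a)) a[[nm]] <- 0
    a[[nm]] <- as.double(a[[nm]])
    a[[nm]][is.na(a[[nm]])] <- 0
    if (any(a[[nm]] < 0)) abort(paste0(nm, " must be >= 0"), class = "gmx_validation_error")
  }
  if (!"string_bin" %in% names(a)) a$string_bin <- "none"
  a$string_bin <- as.character(a$string_bin)
  a$string_bin[is.na(a$string_bin)] <- "none"
  bad <- !a$string_bin %in% names(STRING_BONUS)
  if (any(bad)) {
    abort(paste0("string_bin must be one of S9, S7, S4, none; got: ",
                 paste(unique(a$string_bin[bad]), collapse = ", ")),
          class = "gmx_validation_error")
  }
  a
}

#' Guilt-by-association score
#'
#' Additive evidence score over the functional-annotation descriptors:
#' antibody availability (AB), tissues with MS detection (PA), subcellular
#' localization evidence (SL) and interaction counts (BioGRID + IntAct),
#' each reduced to its 5-level auto-quantizer bin (column-max normalized
#' within the batch, absent/0 mapping to 0), plus a STRING-confidence bonus
#' of 3/2/1 for the S9/S7/S4 score bins. Higher means better supported.
#'
#' @param rows Association tibble: `gene`, `ab`, `pa`, `sl`, `ns`,
#'   `biogrid_count`, `intact_count`, `string_bin` (`S9`, `S7`, `S4` or
#'   `none`). Missing numeric columns count as 0.
#' @param weights Named weights `w_ab`, `w_pa`, `w_sl`, `w_int`, `w_str`,
#'   default all 1.
#' @return The input tibble with a `guilt_score` column appended.
#' @export
guilt_score <- function(rows, weights = c(w_ab = 1, w_pa = 1, w_sl = 1,
                                          w_int = 1, w_str = 1)) {
  a <- normalize_association(rows)
  if (nrow(a) == 0) {
    abort("empty association batch: nothing to normalize against",
          class = "gmx_validation_error")
  }
  w <- function(nm) if (nm %in% names(weights)) unname(weights[[nm]]) else 1
  a$guilt_score <-
    w("w_ab") * gba_bin(a$ab) +
    w("w_pa") * gba_bin(a$pa) +
    w("w_sl") * gba_bin(a$sl) +
    w("w_int") * (gba_bin(a$biogrid_count) + gba_bin(a$intact_count)) +
    w("w_str") * unname(STRING_BONUS[a$string_bin])
  a
}

#' Select functional-annotation targets
#'
#' Two modes of the guilt-by-association shortlist. `novel` keeps proteins
#' detected in the project's own experiments but missing from the worldwide
#' MS databases (the pattern that surfaced C18orf21/TTC39C) and ranks them by
#' guilt score; `hub` ranks the whole batch purely by guilt score (the
#' interaction-hub pattern). Scores are normalized over the full input batch
#' before any filtering; ties break by accession.
#'
#' @param rows Association tibble as in [guilt_score()], plus logical columns
#'   `detected_in_house` and `in_global_ms_dbs` (required for `novel` mode).
#' @param mode `"novel"` or `"hub"`.
#' @param weights Passed to [guilt_score()].
#' @return Ranked tibble (best first) with `guilt_score` and `rank` columns.
#' @export
select_annotation_targets <- function(rows, mode = c("novel", "hub"),
                                      weights = c(w_ab = 1, w_pa = 1, w_sl = 1,
                                                  w_int = 1, w_str = 1)) {
  mode <- match.arg(mode)
  a <- as_tibble(rows)
  names(a) <- tolower(names(a))
  if (nrow(a) == 0) {
    return(tibble(gene = character(), guilt_score = double(), rank = integer()))
  }
  scored <- guilt_score(a, weights)
  if (mode == "novel") {
    for (nm in c("detected_in_house", "in_global_ms_dbs")) {
      if (!nm %in% names(scored)) {
        abort(paste0("novel mode needs column ", nm), class = "gmx_format_error")
      }
    }
    scored <- filter(scored, as.logical(.data$detected_in_house) &
                       !as.logical(.data$in_global_ms_dbs))
  }
  scored <- arrange(scored, dplyr::desc(.data$guilt_score), .data$gene)
  scored$rank <- seq_len(nrow(scored))
  scored
}

#' Chromosome coverage accounting
#'
#' Per-source detection fractions, their union, and the missing-protein
#' remainder over a declared gene universe.
#'
#' @param genes Either the universe size (a single positive integer) or the
#'   vector of universe accessions (detected accessions are then checked for
#'   membership).
#' @param detections Named list: source label -> character vector of detected
#'   accessions.
#' @return A `coverage_report`: list with `n_genes`, `per_source` (tibble:
#'   `source`, `n_detected`, `fraction`), `union_fraction`,
#'   `missing_fraction`.
#' @export
coverage_stats <- function(genes, detections) {
  if (is.numeric(genes) && length(genes) == 1) {
    n <- as.integer(genes)
    universe <- NULL
  } else {
    universe <- as.character(genes)
    if (anyDuplicated(universe)) {
      abort("gene universe contains duplicates", class = "gmx_validation_error")
    }
    n <- length(universe)
  }
  if (is.na(n) || n <= 0) abort("gene universe must be non-empty",
                                class = "gmx_validation_error")
  if (!is.list(detections)) abort("detections must be a named list",
                                  class = "gmx_format_error")
  sets <- lapply(detections, function(s) unique(as.character(s)))
  if (!is.null(universe)) {
    for (nm in names(sets)) {
      stray <- setdiff(sets[[nm]], universe)
      if (length(stray) > 0) {
        abort(paste0("source ", nm, " detects undeclared accession(s): ",
                     paste(stray, collapse = ", ")),
              class = "gmx_reference_error")
      }
    }
  }
  per_source <- tibble(
    source = names(sets) %||% character(),
    n_detected = vapply(sets, length, integer(1), USE.NAMES = FALSE),
    fraction = vapply(sets, length, integer(1), USE.NAMES = FALSE) / n
  )
  union_n <- length(unique(unlist(sets)))
  structure(list(n_genes = n, per_source = per_source,
                 union_fraction = union_n / n,
                 missing_fraction = 1 - union_n / n),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %d genes; union %.1f%%, missing %.1f%%\n",
              x$n_genes, 100 * x$union_fraction, 100 * x$missing_fraction))
  print(x$per_source)
  invisible(x)
}

#' Rank SRM candidate peptides by susceptibility
#'
#' Peptides overlapping known single amino-acid polymorphisms (SAP) or
#' post-translational modification sites are fragile SRM targets: the
#' measured transition may not represent the proteoform actually present.
#' Susceptibility is the weighted site count; the least susceptible peptides
#' rank first. Ties prefer the longer peptide, then lexicographic sequence.
#'
#' @param peptides Tibble: `peptide` (one-letter amino-acid sequence),
#'   `parent_gene`, `sap_sites`, `ptm_sites` (non-negative integers).
#' @param weights Named vector `c(w_sap =, w_ptm =)`, default both 1.
#' @return The input tibble with `susceptibility` and `rank`, ordered best
#'   (least susceptible) first.
#' @export
rank_peptides <- function(peptides, weights = c(w_sap = 1, w_ptm = 1)) {
  p <- as_tibble(peptides)
  if (nrow(p) == 0) {
    return(tibble(peptide = character(), parent_gene = character(),
                  sap_sites = integer(), ptm_sites = integer(),
                  susceptibility = double(), rank = integer()))
  }
  need <- c("peptide", "sap_sites", "ptm_sites")
  if (!all(need %in% names(p))) {
    abort(paste0("peptide table needs columns: ", paste(need, collapse = ", ")),
          class = "gmx_format_error")
  }
  p$peptide <- as.character(p$peptide)
  p$sap_sites <- as.double(p$sap_sites)
  p$ptm_sites <- as.double(p$ptm_sites)
  if (anyNA(p$sap_sites) || anyNA(p$ptm_sites)) {
    abort("site counts must be numeric", class = "gmx_validation_error")
  }
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWY]", p$peptide))) {
    abort("peptide sequences must use the 20 standard one-letter codes",
          class = "gmx_validation_error")
  }
  if (any(p$sap_sites < 0) || any(p$ptm_sites < 0)) {
    abort("site counts must be >= 0", class = "gmx_validation_error")
  }
  w_sap <- if ("w_sap" %in% names(weights)) weights[["w_sap"]] else 1
  w_ptm <- if ("w_ptm" %in% names(weights)) weights[["w_ptm"]] else 1
  p$susceptibility <- w_sap * p$sap_sites + w_ptm * p$ptm_sites
  p <- p[order(p$susceptibility, -nchar(p$peptide), p$peptide, method = "radix"), ]
  p$rank <- seq_len(nrow(p))
  p
}
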