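# Sort-and-select triage of chromosome genes.
#
# Each (gene, biomaterial) evidence record is classified by the first
# matching rule of a fixed, ordered rule table, and the non-detected
# categories are translated into concrete wet-lab recommendations (re-post
# the peptide design, adjust the SRM method, synthesize a new SIS standard,
# revise sample prep for membrane proteins, try another protease, target a
# splice form, or run a proteoform search).

TRIAGE_CATEGORIES <- c("PROTEIN_DETECTED", "SPLICE_ONLY", "PROTEOFORM_CANDIDATE",
                       "MISSING_WITH_EXTERNAL_EVIDENCE", "DARK")

# gene-level rollup preference, best first
CATEGORY_PRIORITY <- c("PROTEIN_DETECTED", "SPLICE_ONLY",
                       "MISSING_WITH_EXTERNAL_EVIDENCE",
                       "PROTEOFORM_CANDIDATE", "DARK")

RECOMMENDATION_CODES <- c("REPOST_PEPTIDE_DESIGN", "ADJUST_SRM_METHOD",
                          "SYNTHESIZE_NEW_SIS", "REVISE_SAMPLE_PREP",
                          "ALTERNATIVE_PROTEASE", "TARGET_SPLICE_FORM",
                          "PROTEOFORM_SEARCH")

EVIDENCE_COLUMNS <- c("gene", "biomaterial", "srm_detected", "shotgun_detected",
                      "expression", "db_transcript_evidence", "pe_level",
                      "pride_count", "cf_expression", "has_sis_peptide",
                      "membrane_bound", "tryptic_coverage_ok")

#' Triage thresholds
#'
#' @param expression_threshold Transcript-abundance cutoff (RPKM/FPKM) above
#'   which (strictly) a gene counts as expressed; default 1.
#' @param pride_min Minimum number of public proteomics-repository
#'   experiments treated as significant external evidence; default 3.
#' @param pe_confident_max Highest protein-existence level counted as
#'   protein-level evidence; default 1 (PE1 only).
#' @return A `triage_config` list.
#' @export
triage_config <- function(expression_threshold = 1.0, pride_min = 3L,
                          pe_confident_max = 1L) {
  if (expression_threshold < 0) abort("expression_threshold must be >= 0",
                                      class = "gmx_validation_error")
  if (pride_min < 1) abort("pride_min must be >= 1", class = "gmx_validation_error")
  structure(list(expression_threshold = as.double(expression_threshold),
                 pride_min = as.integer(pride_min),
                 pe_confident_max = as.integer(pe_confident_max)),
            class = "triage_config")
}

# normalize an evidence tibble; splice columns s2..s7 (any subset) allowed
normalize_evidence <- function(records) {
  ev <- as_tibble(records)
  names(ev) <- tolower(names(ev))
  missing <- setdiff(c("gene", "srm_detected"), names(ev))
  if (length(missing) > 0) {
    abort(paste0("evidence records need column(s): ", paste(missing, collapse = ", ")),
          class = "gmx_format_error")
  }
  defaults <- list(biomaterial = "unspecified", shotgun_detected = FALSE,
                   expression = 0, db_transcript_evidence = FALSE,
                   pe_level = 5L, pride_count = 0L, cf_expression = 0,
                   has_sis_peptide = FALSE, membrane_bound = FALSE,
                   tryptic_coverage_ok = TRUE)
  for (nm in names(defaults)) {
    if (!nm %in% names(ev)) ev[[nm]] <- defaults[[nm]]
  }
  for (nm in c("srm_detected", "shotgun_detected", "db_transcript_evidence",
               "has_sis_peptide", "membrane_bound", "tryptic_coverage_ok")) {
    ev[[nm]] <- as.logical(ev[[nm]])
  }
  for (nm in splice_columns(ev)) ev[[nm]] <- as.double(ev[[nm]])
  ev$pe_level <- as.integer(ev$pe_level)
  ev$pride_count <- as.integer(ev$pride_count)
  ev$expression <- as.double(ev$expression)
  ev$cf_expression <- as.double(ev$cf_expression)
  if (any(is.na(ev$pe_level)) || any(ev$pe_level < 1 | ev$pe_level > 5)) {
    abort("pe_level must be an integer in 1..5", class = "gmx_validation_error")
  }
  if (any(ev$pride_count < 0) || any(ev$expression < 0) || any(ev$cf_expression < 0)) {
    abort("counts and expression levels must be >= 0", class = "gmx_validation_error")
  }
  ev
}

splice_columns <- function(ev) {
  grep("^s[2-7]$", names(ev), value = TRUE)
}

any_splice_positive <- function(ev) {
  scols <- splice_columns(ev)
  if (length(scols) == 0) return(rep(FALSE, nrow(ev)))
  m <- as.matrix(ev[scols])
  m[is.na(m)] <- 0
  if (any(m < 0)) abort("splice levels must be >= 0", class = "gmx_validation_error")
  rowSums(m > 0) > 0
}

#' Classify evidence records into triage categories
#'
#' Applies the ordered rule table to each record; the first matching rule
#' wins:
#' 1. SRM signal observed: `PROTEIN_DETECTED`.
#' 2. No SRM, canonical form silent but some splice form expressed:
#'    `SPLICE_ONLY`.
#' 3. No SRM, no transcript in the public databases, weak protein-existence
#'    evidence, yet proprietary expression above threshold:
#'    `PROTEOFORM_CANDIDATE`.
#' 4. No SRM but confident protein existence, enough public repository
#'    experiments, or a shotgun hit: `MISSING_WITH_EXTERNAL_EVIDENCE`.
#' 5. Otherwise `DARK`.
#'
#' @param records Evidence tibble, one row per gene x biomaterial, with
#'   columns `gene`, `biomaterial`, `srm_detected`, `shotgun_detected`,
#'   `expression`, `db_transcript_evidence`, `pe_level`, `pride_count`,
#'   `cf_expression`, splice levels `s2`..`s7`, `has_sis_peptide`,
#'   `membrane_bound`, `tryptic_coverage_ok` (absent columns take neutral
#'   defaults).
#' @param config A [triage_config()].
#' @return The input tibble with columns `category` and `rationale` (the
#'   fired rule id) appended.
#' @export
classify_gene <- function(records, config = triage_config()) {
  stopifnot(inherits(config, "triage_config"))
  ev <- normalize_evidence(records)
  splice_pos <- any_splice_positive(ev)
  r1 <- ev$srm_detected
  r2 <- !r1 & ev$cf_expression == 0 & splice_pos
  r3 <- !r1 & !r2 & !ev$db_transcript_evidence &
    ev$pe_level > config$pe_confident_max &
    ev$expression > config$expression_threshold
  r4 <- !r1 & !r2 & !r3 &
    (ev$pe_level <= config$pe_confident_max |
       ev$pride_count >= config$pride_min | ev$shotgun_detected)
  category <- rep("DARK", nrow(ev))
  category[r4] <- "MISSING_WITH_EXTERNAL_EVIDENCE"
  category[r3] <- "PROTEOFORM_CANDIDATE"
  category[r2] <- "SPLICE_ONLY"
  category[r1] <- "PROTEIN_DETECTED"
  rationale <- rep("rule5_dark_fallthrough", nrow(ev))
  rationale[r4] <- "rule4_external_evidence"
  rationale[r3] <- "rule3_proteoform_candidate"
  rationale[r2] <- "rule2_splice_only"
  rationale[r1] <- "rule1_srm_detected"
  ev$category <- category
  ev$rationale <- rationale
  ev
}

#' Recommend follow-up actions for a classified record
#'
#' @param classified Output of [classify_gene()] (category is re-derived from
#'   the evidence and must agree with the stored one).
#' @param config The [triage_config()] used for classification.
#' @return The input with a `recommendations` list column of action codes.
#' @export
recommend <- function(classified, config = triage_config()) {
  ev <- as_tibble(classified)
  if (!"category" %in% names(ev)) {
    abort("recommend() expects classify_gene() output", class = "gmx_format_error")
  }
  check <- classify_gene(ev[setdiff(names(ev), c("category", "rationale"))], config)
  if (!identical(check$category, ev$category)) {
    bad <- which(check$category != ev$category)[1]
    abort(sprintf("category '%s' inconsistent with evidence for gene %s (expected %s)",
                  ev$category[bad], ev$gene[bad], check$category[bad]),
          class = "gmx_consistency_error")
  }
  recs <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    recs[[i]] <- switch(ev$category[i],
      PROTEIN_DETECTED = character(),
      DARK = character(),
      SPLICE_ONLY = c("TARGET_SPLICE_FORM", "SYNTHESIZE_NEW_SIS"),
      PROTEOFORM_CANDIDATE = "PROTEOFORM_SEARCH",
      MISSING_WITH_EXTERNAL_EVIDENCE = c(
        "REPOST_PEPTIDE_DESIGN",
        if (ev$has_sis_peptide[i]) "ADJUST_SRM_METHOD" else "SYNTHESIZE_NEW_SIS",
        if (ev$membrane_bound[i]) "REVISE_SAMPLE_PREP",
        if (!ev$tryptic_coverage_ok[i]) "ALTERNATIVE_PROTEASE"
      )
    )
  }
  ev$recommendations <- recs
  ev
}

#' Triage a batch of evidence records
#'
#' Classifies every record, attaches recommendations, and tabulates category
#' counts per biomaterial.
#'
#' @inheritParams classify_gene
#' @return A `triage_result`: list with `decisions` (tibble: gene,
#'   biomaterial, category, recommendations, rationale) and `summary`
#'   (tibble: biomaterial, category, n).
#' @export
batch_triage <- function(records, config = triage_config()) {
  ev <- normalize_evidence(records)
  key <- paste(ev$gene, ev$biomaterial, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    abort(paste0("duplicate (gene, biomaterial) record(s): ",
                 paste(gsub("\r", "/", dup), collapse = ", ")),
          class = "gmx_duplication_error")
  }
  dec <- recommend(classify_gene(ev, config), config)
  decisions <- dec[c("gene", "biomaterial", "category", "recommendations", "rationale")]
  summary <- decisions |>
    count(.data$biomaterial, .data$category, name = "n") |>
    arrange(.data$biomaterial, .data$category)
  structure(list(decisions = as_tibble(decisions), summary = summary,
                 config = config),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result> %d decisions across %d biomaterials\n",
              nrow(x$decisions), length(unique(x$decisions$biomaterial))))
  print(x$summary)
  invisible(x)
}

#' Roll triage decisions up to the gene level
#'
#' A gene keeps the best category it achieved across biomaterials, in the
#' order detected > splice-only > missing-with-evidence > proteoform
#' candidate > dark.
#'
#' @param result A `triage_result` (or its decisions tibble).
#' @return A tibble with one row per gene: `gene`, `category`.
#' @export
triage_rollup <- function(result) {
  decisions <- if (inherits(result, "triage_result")) result$decisions else as_tibble(result)
  decisions |>
    mutate(.rank = match(.data$category, CATEGORY_PRIORITY)) |>
    group_by(.data$gene) |>
    summarise(category = CATEGORY_PRIORITY[min(.data$.rank)], .groups = "drop")
}
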