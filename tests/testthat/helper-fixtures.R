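# Shared fixture builders and independent oracles. The oracles deliberately
# use record-by-record base-R scans, never the package's vectorized paths.

random_matrix <- function(n_genes, n_desc, fill = 0.6, max_value = 100,
                          desc_ids = sprintf("D%02d", seq_len(n_desc))) {
  genes <- tibble::tibble(accession = sprintf("G%03d", seq_len(n_genes)))
  grid <- expand.grid(gene = genes$accession, descriptor = desc_ids,
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < fill
  values <- tibble::tibble(
    gene = grid$gene[keep], descriptor = grid$descriptor[keep],
    value = round(stats::runif(sum(keep), 0, max_value), 3),
    source = "fixture", timestamp = "2020-01-01"
  )
  heat_matrix(genes, data.frame(id = desc_ids), values = values)
}

# randomly modify/delete/add cells of a matrix (n_changes distinct slots)
perturb_matrix <- function(m, n_changes) {
  cells <- m$cells
  all_pairs <- expand.grid(gene = m$genes$accession,
                           descriptor = m$descriptors$id,
                           stringsAsFactors = FALSE)
  picks <- sample(nrow(all_pairs), n_changes)
  for (i in picks) {
    g <- all_pairs$gene[i]; d <- all_pairs$descriptor[i]
    at <- which(cells$gene == g & cells$descriptor == d)
    if (length(at) == 1) {
      if (stats::runif(1) < 0.5) {
        cells$value[at] <- cells$value[at] + 1  # modify
      } else {
        cells <- cells[-at, ]                    # delete
      }
    } else {
      cells <- dplyr::bind_rows(cells, tibble::tibble(
        gene = g, descriptor = d, value = round(stats::runif(1, 1, 9), 2),
        source = "fixture", timestamp = "2020-01-01"))
    }
  }
  heat_matrix(m$genes, m$descriptors, m$tracks, cells)
}

# linear-scan binner over explicit half-open (lo, hi] intervals
oracle_bin <- function(value, max_value, boundaries = NULL) {
  if (is.na(value) || value == 0) return(NA_integer_)
  x <- if (is.null(boundaries)) value / max_value else value
  bounds <- if (is.null(boundaries)) c(0.2, 0.4, 0.6, 0.8, 1.0) else boundaries
  lo <- 0
  for (b in seq_along(bounds)) {
    if (x > lo && x <= bounds[b]) return(b - 1L)
    lo <- bounds[b]
  }
  length(bounds) - 1L  # top bin covers the maximum
}

# scalar rule-table oracle for triage classification
oracle_classify <- function(r, expression_threshold = 1, pride_min = 3,
                            pe_confident_max = 1) {
  splice_any <- any(unlist(r[grep("^s[2-7]$", names(r))]) > 0)
  if (isTRUE(r$srm_detected)) return("PROTEIN_DETECTED")
  if (r$cf_expression == 0 && splice_any) return("SPLICE_ONLY")
  if (!r$db_transcript_evidence && r$pe_level > pe_confident_max &&
      r$expression > expression_threshold) return("PROTEOFORM_CANDIDATE")
  if (r$pe_level <= pe_confident_max || r$pride_count >= pride_min ||
      isTRUE(r$shotgun_detected)) return("MISSING_WITH_EXTERNAL_EVIDENCE")
  "DARK"
}

oracle_recommend <- function(r, category) {
  switch(category,
    PROTEIN_DETECTED = character(),
    DARK = character(),
    SPLICE_ONLY = c("TARGET_SPLICE_FORM", "SYNTHESIZE_NEW_SIS"),
    PROTEOFORM_CANDIDATE = "PROTEOFORM_SEARCH",
    MISSING_WITH_EXTERNAL_EVIDENCE = c(
      "REPOST_PEPTIDE_DESIGN",
      if (isTRUE(r$has_sis_peptide)) "ADJUST_SRM_METHOD" else "SYNTHESIZE_NEW_SIS",
      if (isTRUE(r$membrane_bound)) "REVISE_SAMPLE_PREP",
      if (!isTRUE(r$tryptic_coverage_ok)) "ALTERNATIVE_PROTEASE"
    )
  )
}

random_evidence <- function(n) {
  tibble::tibble(
    gene = sprintf("G%04d", seq_len(n)),
    biomaterial = sample(c("plasma", "HepG2", "liver"), n, replace = TRUE),
    srm_detected = stats::runif(n) < 0.3,
    shotgun_detected = stats::runif(n) < 0.3,
    expression = round(stats::rexp(n, 1 / 2), 3),
    db_transcript_evidence = stats::runif(n) < 0.5,
    pe_level = sample.int(5, n, replace = TRUE),
    pride_count = stats::rpois(n, 2),
    cf_expression = ifelse(stats::runif(n) < 0.4, 0, round(stats::rexp(n), 3)),
    s2 = ifelse(stats::runif(n) < 0.3, round(stats::rexp(n), 3), 0),
    s5 = ifelse(stats::runif(n) < 0.3, round(stats::rexp(n), 3), 0),
    has_sis_peptide = stats::runif(n) < 0.5,
    membrane_bound = stats::runif(n) < 0.25,
    tryptic_coverage_ok = stats::runif(n) < 0.8
  )
}

# spreadsheet-style guilt-by-association oracle: per-column max, explicit
# bin scan, additive sum
oracle_guilt <- function(rows, weights = c(w_ab = 1, w_pa = 1, w_sl = 1,
                                           w_int = 1, w_str = 1)) {
  cols <- c("ab", "pa", "sl", "biogrid_count", "intact_count")
  bins <- sapply(cols, function(nm) {
    v <- rows[[nm]]
    mx <- max(v)
    sapply(v, function(x) {
      if (x == 0 || mx == 0) 0L else oracle_bin(x, mx)
    })
  })
  if (nrow(rows) == 1) bins <- matrix(bins, nrow = 1, dimnames = list(NULL, cols))
  bonus <- c(S9 = 3, S7 = 2, S4 = 1, none = 0)[rows$string_bin]
  weights[["w_ab"]] * bins[, "ab"] + weights[["w_pa"]] * bins[, "pa"] +
    weights[["w_sl"]] * bins[, "sl"] +
    weights[["w_int"]] * (bins[, "biogrid_count"] + bins[, "intact_count"]) +
    weights[["w_str"]] * unname(bonus)
}

random_association <- function(n) {
  tibble::tibble(
    gene = sprintf("G%03d", sample.int(999, n)),
    ab = stats::rpois(n, 2), pa = stats::rpois(n, 4), sl = stats::rpois(n, 1),
    ns = stats::rpois(n, 2),
    biogrid_count = stats::rpois(n, 3), intact_count = stats::rpois(n, 3),
    string_bin = sample(c("S9", "S7", "S4", "none"), n, replace = TRUE),
    detected_in_house = stats::runif(n) < 0.5,
    in_global_ms_dbs = stats::runif(n) < 0.5
  )
}

# run the installed CLI; returns list(status, stdout, stderr)
run_gmx <- function(args) {
  script <- system.file("cli", "gmx.R", package = "genemx")
  stopifnot(nzchar(script))
  out <- tempfile(); err <- tempfile()
  status <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(script, args),
    stdout = out, stderr = err,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = status,
       stdout = readLines(out, warn = FALSE),
       stderr = readLines(err, warn = FALSE))
}
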