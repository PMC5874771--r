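base_record <- function(...) {
  r <- tibble::tibble(
    gene = "G1", biomaterial = "plasma", srm_detected = FALSE,
    shotgun_detected = FALSE, expression = 0, db_transcript_evidence = FALSE,
    pe_level = 5L, pride_count = 0L, cf_expression = 0, s2 = 0, s3 = 0,
    has_sis_peptide = FALSE, membrane_bound = FALSE, tryptic_coverage_ok = TRUE
  )
  mods <- list(...)
  for (nm in names(mods)) r[[nm]] <- mods[[nm]]
  r
}

test_that("the rule table assigns the documented categories in order", {
  # SRM signal dominates everything
  expect_equal(classify_gene(base_record(srm_detected = TRUE, pride_count = 99,
                                         cf_expression = 0, s3 = 5))$category,
               "PROTEIN_DETECTED")
  # canonical form silent, splice form expressed
  expect_equal(classify_gene(base_record(cf_expression = 0, s3 = 5))$category,
               "SPLICE_ONLY")
  # transcript and protein both missing from databases, proprietary RPKM > 1
  expect_equal(classify_gene(base_record(db_transcript_evidence = FALSE,
                                         pe_level = 4L, expression = 2.5))$category,
               "PROTEOFORM_CANDIDATE")
  # strong external evidence but no SRM signal
  expect_equal(classify_gene(base_record(pe_level = 1L, expression = 8,
                                         pride_count = 12L,
                                         db_transcript_evidence = TRUE))$category,
               "MISSING_WITH_EXTERNAL_EVIDENCE")
  # nothing at all
  expect_equal(classify_gene(base_record())$category, "DARK")
})

test_that("expression threshold is strictly greater-than 1 RPKM", {
  at_threshold <- base_record(pe_level = 4L, expression = 1)
  above <- base_record(pe_level = 4L, expression = 1.0001)
  expect_equal(classify_gene(at_threshold)$category, "DARK")
  expect_equal(classify_gene(above)$category, "PROTEOFORM_CANDIDATE")
  # configurable
  cfg <- triage_config(expression_threshold = 5)
  expect_equal(classify_gene(above, cfg)$category, "DARK")
})

test_that("recommendations follow the category and the evidence flags", {
  r <- base_record(pe_level = 1L, has_sis_peptide = TRUE, membrane_bound = TRUE)
  out <- recommend(classify_gene(r))
  expect_setequal(out$recommendations[[1]],
                  c("REPOST_PEPTIDE_DESIGN", "ADJUST_SRM_METHOD",
                    "REVISE_SAMPLE_PREP"))
  r2 <- base_record(pe_level = 1L, has_sis_peptide = FALSE,
                    tryptic_coverage_ok = FALSE)
  expect_setequal(recommend(classify_gene(r2))$recommendations[[1]],
                  c("REPOST_PEPTIDE_DESIGN", "SYNTHESIZE_NEW_SIS",
                    "ALTERNATIVE_PROTEASE"))
  expect_setequal(recommend(classify_gene(base_record(s2 = 3)))$recommendations[[1]],
                  c("TARGET_SPLICE_FORM", "SYNTHESIZE_NEW_SIS"))
  expect_length(recommend(classify_gene(base_record(srm_detected = TRUE)))$
                  recommendations[[1]], 0)
  # tampered category is a consistency error
  bad <- classify_gene(base_record())
  bad$category <- "PROTEIN_DETECTED"
  expect_error(recommend(bad), class = "gmx_consistency_error")
})

test_that("batch triage counts sum and duplicates are rejected", {
  set.seed(9)
  ev <- random_evidence(10)
  ev$srm_detected <- rep(c(TRUE, FALSE), c(4, 6))
  ev$gene <- sprintf("G%02d", 1:10)
  res <- batch_triage(ev)
  expect_equal(nrow(res$decisions), 10)
  expect_equal(sum(res$summary$n), 10)
  expect_equal(sum(res$summary$n[res$summary$category == "PROTEIN_DETECTED"]), 4)

  empty <- batch_triage(random_evidence(0))
  expect_equal(nrow(empty$decisions), 0)
  expect_equal(sum(empty$summary$n), 0)

  dup <- ev[c(1, 1), ]
  expect_error(batch_triage(dup), class = "gmx_duplication_error")
})

test_that("batch decisions match the record-by-record rule-table oracle", {
  set.seed(77)
  ev <- random_evidence(200)
  ev$gene <- sprintf("G%04d", 1:200)
  res <- batch_triage(ev)
  for (i in seq_len(nrow(ev))) {
    r <- as.list(ev[i, ])
    expect_equal(res$decisions$category[i], oracle_classify(r), info = paste("row", i))
    expect_setequal(res$decisions$recommendations[[i]],
                    oracle_recommend(r, res$decisions$category[i]))
  }
  counts <- table(vapply(seq_len(nrow(ev)), function(i) oracle_classify(as.list(ev[i, ])),
                         character(1)))
  got <- res$decisions |> dplyr::count(category)
  expect_equal(setNames(got$n, got$category), c(counts)[got$category])
})

test_that("rationale identifies the fired rule and is replayable", {
  out <- classify_gene(base_record(s4 = 2))
  expect_equal(out$rationale, "rule2_splice_only")
  expect_true(all(nzchar(classify_gene(random_evidence(20))$rationale)))
})

test_that("gene-level rollup keeps the best category across biomaterials", {
  dec <- tibble::tibble(
    gene = c("A", "A", "B", "B", "C"),
    biomaterial = c("plasma", "liver", "plasma", "liver", "plasma"),
    category = c("DARK", "PROTEIN_DETECTED", "MISSING_WITH_EXTERNAL_EVIDENCE",
                 "PROTEOFORM_CANDIDATE", "DARK")
  )
  roll <- triage_rollup(dec)
  expect_equal(roll$category[roll$gene == "A"], "PROTEIN_DETECTED")
  expect_equal(roll$category[roll$gene == "B"], "MISSING_WITH_EXTERNAL_EVIDENCE")
  expect_equal(roll$category[roll$gene == "C"], "DARK")
})
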