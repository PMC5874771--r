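test_that("splice filter returns exactly cf = 0 with some splice expression", {
  set.seed(13)
  # 20 profiles: 3 liver hits, 2 HepG2 hits, the rest not splice-only
  hits <- tibble::tibble(
    gene = c("L1", "L2", "L3", "H1", "H2"),
    biomaterial = c("liver", "liver", "liver", "HepG2", "HepG2"),
    cf = 0, s2 = c(1, 0, 2, 3, 0), s3 = c(0, 4, 1, 0, 5), s4 = 0, s5 = 0,
    s6 = 0, s7 = 0
  )
  rest <- tibble::tibble(
    gene = sprintf("N%02d", 1:15),
    biomaterial = rep(c("liver", "HepG2", "plasma"), 5),
    cf = c(rep(2, 10), rep(0, 5)),           # last 5 are dark: all levels zero
    s2 = c(stats::rpois(10, 1), rep(0, 5)),
    s3 = 0, s4 = 0, s5 = 0, s6 = 0, s7 = 0
  )
  out <- find_missing_spliced(dplyr::bind_rows(hits, rest))
  expect_equal(sum(out$biomaterial == "liver"), 3)
  expect_equal(sum(out$biomaterial == "HepG2"), 2)
  expect_setequal(out$gene, hits$gene)
  expect_equal(out$splice_forms[[which(out$gene == "L2")]], "S3")

  all_cf <- tibble::tibble(gene = "x", biomaterial = "liver", cf = 1, s2 = 9)
  expect_equal(nrow(find_missing_spliced(all_cf)), 0)
  dark <- tibble::tibble(gene = "x", biomaterial = "liver", cf = 0, s2 = 0)
  expect_equal(nrow(find_missing_spliced(dark)), 0)
})

test_that("splice filter agrees with the matrix predicate representation", {
  set.seed(29)
  for (rep_i in 1:20) {
    n <- sample(5:12, 1)
    prof <- tibble::tibble(
      gene = sprintf("g%02d", 1:n), biomaterial = "liver",
      cf = ifelse(stats::runif(n) < 0.5, 0, round(stats::rexp(n), 2))
    )
    for (s in paste0("s", 2:7)) {
      prof[[s]] <- ifelse(stats::runif(n) < 0.4, round(stats::rexp(n), 2), 0)
    }
    m <- heat_matrix(
      data.frame(accession = prof$gene),
      data.frame(id = c("CF", paste0("S", 2:7))),
      values = tidyr::pivot_longer(prof[-2], -gene, names_to = "descriptor",
                                   values_to = "value") |>
        dplyr::mutate(descriptor = toupper(descriptor))
    )
    via_predicate <- select_rows(
      m, "CF = 0 AND (S2 > 0 OR S3 > 0 OR S4 > 0 OR S5 > 0 OR S6 > 0 OR S7 > 0)"
    )$genes$accession
    via_filter <- find_missing_spliced(prof)$gene
    expect_setequal(via_filter, via_predicate)
  }
})

test_that("guilt score is additive, zero for empty rows, and favors S9", {
  zero <- tibble::tibble(gene = "z", ab = 0, pa = 0, sl = 0, ns = 0,
                         biogrid_count = 0, intact_count = 0, string_bin = "none")
  expect_equal(guilt_score(zero)$guilt_score, 0)

  pair <- tibble::tibble(
    gene = c("hi", "lo"), ab = 4, pa = 4, sl = 1, ns = 1,
    biogrid_count = 5, intact_count = 5, string_bin = c("S9", "S4")
  )
  scored <- guilt_score(pair)
  expect_gt(scored$guilt_score[1], scored$guilt_score[2])
  expect_equal(scored$guilt_score[1] - scored$guilt_score[2], 2)  # 3 - 1
  ranked <- select_annotation_targets(pair, "hub")
  expect_equal(ranked$gene[1], "hi")

  expect_error(guilt_score(zero[0, ]), class = "gmx_validation_error")
})

test_that("guilt scores equal the spreadsheet-style oracle on random batches", {
  set.seed(37)
  for (rep_i in 1:10) {
    rows <- random_association(10)
    rows$gene <- sprintf("G%03d", 1:10)
    expect_equal(guilt_score(rows)$guilt_score, unname(oracle_guilt(rows)))
  }
})

test_that("guilt score is monotone in every count at fixed normalization", {
  base <- tibble::tibble(gene = c("a", "b", "cap"), ab = c(2, 2, 100),
                         pa = c(3, 3, 100), sl = c(1, 1, 100), ns = 0,
                         biogrid_count = c(4, 4, 100),
                         intact_count = c(4, 4, 100), string_bin = "none")
  for (col in c("ab", "pa", "sl", "biogrid_count", "intact_count")) {
    bumped <- base
    bumped[[col]][2] <- bumped[[col]][2] + 30
    s <- guilt_score(bumped)$guilt_score
    expect_gte(s[2], s[1])
  }
})

test_that("annotation target modes filter and rank as documented", {
  set.seed(41)
  rows <- random_association(16)
  rows$gene <- sprintf("G%03d", 1:16)
  rows$detected_in_house <- c(TRUE, TRUE, rep(FALSE, 14))
  rows$in_global_ms_dbs <- c(FALSE, FALSE, rep(TRUE, 14))
  novel <- select_annotation_targets(rows, "novel")
  expect_setequal(novel$gene, c("G001", "G002"))

  hub <- select_annotation_targets(rows, "hub")
  scores <- guilt_score(rows)
  oracle_order <- scores$gene[order(-scores$guilt_score, scores$gene,
                                    method = "radix")]
  expect_equal(hub$gene, oracle_order)
  expect_equal(hub$rank, 1:16)

  expect_equal(nrow(select_annotation_targets(rows[0, ], "hub")), 0)
  expect_error(select_annotation_targets(rows, "nope"))
})

test_that("coverage fractions follow set algebra", {
  rep4 <- coverage_stats(4, list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_equal(rep4$per_source$fraction, c(0.5, 0.5))
  expect_equal(rep4$union_fraction, 0.75)
  expect_equal(rep4$missing_fraction, 0.25)

  full <- coverage_stats(c("a", "b"), list(S = c("a", "b")))
  expect_equal(full$union_fraction, 1)
  expect_equal(full$missing_fraction, 0)

  expect_error(coverage_stats(c("a"), list(S = "zz")), class = "gmx_reference_error")
  expect_error(coverage_stats(0, list()), class = "gmx_validation_error")
})

test_that("peptide ranking prefers unmodified, unpolymorphic peptides", {
  p <- tibble::tibble(
    peptide = c("AAAAAAAAK", "CCCCCCCCK", "DDDDDDDDK"),
    parent_gene = "G1",
    sap_sites = c(0, 1, 0), ptm_sites = c(0, 0, 2)
  )
  out <- rank_peptides(p)
  expect_equal(out$peptide, c("AAAAAAAAK", "CCCCCCCCK", "DDDDDDDDK"))
  expect_equal(out$susceptibility, c(0, 1, 2))

  ties <- tibble::tibble(peptide = c("AK", "CCK", "AAK"), parent_gene = "G",
                         sap_sites = 0, ptm_sites = 0)
  # all-zero susceptibility: longer first, then lexicographic
  expect_equal(rank_peptides(ties)$peptide, c("AAK", "CCK", "AK"))

  expect_equal(nrow(rank_peptides(p[0, ])), 0)
  expect_error(rank_peptides(tibble::tibble(peptide = "AXZ1", parent_gene = "G",
                                            sap_sites = 0, ptm_sites = 0)),
               class = "gmx_validation_error")
})

test_that("peptide ranking matches a brute-force sort and conserves the input", {
  set.seed(53)
  p <- tibble::tibble(
    peptide = replicate(50, paste(sample(c("A", "G", "K", "R", "S"),
                                         sample(6:15, 1), replace = TRUE),
                                  collapse = "")),
    parent_gene = sprintf("G%02d", sample.int(99, 50)),
    sap_sites = stats::rpois(50, 1), ptm_sites = stats::rpois(50, 1)
  )
  w <- c(w_sap = 2, w_ptm = 0.5)
  out <- rank_peptides(p, w)
  score <- 2 * p$sap_sites + 0.5 * p$ptm_sites
  oracle <- p$peptide[order(score, -nchar(p$peptide), p$peptide, method = "radix")]
  expect_equal(out$peptide, oracle)
  expect_setequal(out$peptide, p$peptide)           # permutation
  expect_equal(sum(out$susceptibility), sum(score)) # conserved
})
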