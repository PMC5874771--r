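test_that("simulation is bit-exact reproducible from the seed", {
  cfg <- sim_config(n_genes = 60, seed = 99)
  a <- simulate_chromosome(cfg)
  b <- simulate_chromosome(cfg)
  for (tab in c("genes", "evidence", "splice_profiles", "values",
                "association", "peptides", "truth")) {
    expect_identical(a[[tab]], b[[tab]], info = tab)
  }
  c_ <- simulate_chromosome(sim_config(n_genes = 60, seed = 100))
  expect_false(identical(a$evidence, c_$evidence))
})

test_that("degenerate detection probability yields no detected proteins", {
  cfg <- sim_config(n_genes = 40, detect_prob = c(plasma = 0, HepG2 = 0, liver = 0),
                    shotgun_given_missing = 0, seed = 3)
  sim <- simulate_chromosome(cfg)
  res <- batch_triage(sim$evidence)
  expect_equal(sum(res$decisions$category == "PROTEIN_DETECTED"), 0)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_genes = 0), class = "gmx_validation_error")
  expect_error(sim_config(public_detect_prob = 1.5), class = "gmx_validation_error")
  expect_error(sim_config(pe_distribution = c(0.5, 0.5, 0.1, 0, 0)),
               class = "gmx_validation_error")
  expect_error(sim_config(splice_only_prob = 0.7, proteoform_prob = 0.6),
               class = "gmx_validation_error")
})

test_that("the chromosome-18-like preset solves the public layer for 63% union", {
  cfg <- chr18_preset()
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_genes, 275)
  expect_equal(unname(cfg$detect_prob), c(0.32, 0.24, 0.13))
  # expected union under independence equals the calibration target
  p_missing <- prod(1 - unlist(cfg$detect_prob)) * (1 - cfg$public_detect_prob)
  expect_equal(1 - p_missing, 0.63, tolerance = 1e-12)
  expect_equal(cfg$public_detect_prob, 0.177076, tolerance = 1e-4)
})

test_that("generated tables are mutually consistent", {
  sim <- simulate_chromosome(sim_config(n_genes = 120, seed = 17))

  # classification is total over generated evidence
  res <- batch_triage(sim$evidence)
  expect_equal(nrow(res$decisions), nrow(sim$evidence))

  # labelled splice-only genes are exactly the recoverable set
  truth_splice <- sim$truth$gene[sim$truth$label == "splice_only"]
  found <- unique(find_missing_spliced(sim$splice_profiles)$gene)
  expect_setequal(found, truth_splice)

  # labelled proteoform candidates classify as such in every biomaterial
  truth_pf <- sim$truth$gene[sim$truth$label == "proteoform"]
  pf_rows <- res$decisions[res$decisions$gene %in% truth_pf, ]
  expect_true(all(pf_rows$category == "PROTEOFORM_CANDIDATE"))

  # the descriptor value table agrees with the first biomaterial's profile
  first_bm <- sim$config$biomaterials[1]
  prof1 <- sim$splice_profiles[sim$splice_profiles$biomaterial == first_bm, ]
  cf_vals <- sim$values[sim$values$descriptor == "CF", ]
  expect_equal(cf_vals$value[match(prof1$gene, cf_vals$gene)], prof1$cf)
  pe_vals <- sim$values[sim$values$descriptor == "PE", ]
  expect_equal(pe_vals$value[match(sim$truth$gene, pe_vals$gene)],
               as.double(sim$truth$pe_level))

  # values build a valid matrix
  m <- heat_matrix(sim$genes, sim$descriptors, values = sim$values)
  expect_equal(nrow(m$cells), nrow(sim$values))
})

test_that("adding downstream tables does not perturb earlier streams", {
  # the gene list must be identical whatever happens to later tables; check by
  # comparing against a run with different peptide settings (last stream)
  a <- simulate_chromosome(sim_config(n_genes = 50, seed = 5, peptides_per_gene = 1))
  b <- simulate_chromosome(sim_config(n_genes = 50, seed = 5, peptides_per_gene = 3))
  expect_identical(a$genes, b$genes)
  expect_identical(a$evidence, b$evidence)
  expect_identical(a$association, b$association)
})
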