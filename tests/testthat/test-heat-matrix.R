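test_that("build counts populated cells and rejects bad references", {
  m <- heat_matrix(
    data.frame(accession = c("G1", "G2")),
    data.frame(id = c("PE", "CF")),
    values = data.frame(gene = c("G1", "G1", "G2"),
                        descriptor = c("PE", "CF", "PE"), value = c(1, 2, 3))
  )
  expect_equal(nrow(m$cells), 3)
  expect_equal(dim(m), c(2, 2))

  empty <- heat_matrix(data.frame(accession = "G1"), data.frame(id = "PE"))
  expect_equal(nrow(empty$cells), 0)

  expect_error(
    heat_matrix(data.frame(accession = "G1"), data.frame(id = "PE"),
                values = data.frame(gene = "X", descriptor = "PE", value = 1)),
    class = "gmx_reference_error", regexp = "X"
  )
  expect_error(
    heat_matrix(data.frame(accession = "G1"), data.frame(id = c("PE", "CF")),
                values = data.frame(gene = "X", descriptor = "ZZ", value = 1)),
    class = "gmx_reference_error"
  )
  expect_error(
    heat_matrix(data.frame(accession = "G1"), data.frame(id = "PE"),
                values = data.frame(gene = c("G1", "G1"),
                                    descriptor = c("PE", "PE"), value = 1:2)),
    class = "gmx_duplication_error"
  )
})

test_that("gene and descriptor invariants are enforced", {
  expect_error(gene_table(data.frame(accession = c("A", "A"))),
               class = "gmx_duplication_error")
  expect_error(gene_table(data.frame(accession = "A", start = 10, end = 5)),
               class = "gmx_validation_error")
  expect_error(descriptor_table(data.frame(id = "PE", value_kind = "volume")),
               class = "gmx_validation_error")
  expect_error(
    track_table(data.frame(id = "t", descriptor_ids = "PE,XX"),
                descriptor_table(data.frame(id = "PE"))),
    class = "gmx_reference_error"
  )
})

test_that("sort_rows orders by value with accession tie-break and absent policy", {
  m <- heat_matrix(
    data.frame(accession = c("g1", "g2", "g3")),
    data.frame(id = "D"),
    values = data.frame(gene = c("g1", "g2"), descriptor = "D", value = c(5, 9))
  )
  expect_equal(sort_rows(m, "D", "desc", "last")$genes$accession,
               c("g2", "g1", "g3"))
  expect_equal(sort_rows(m, "D", "asc", "first")$genes$accession,
               c("g3", "g1", "g2"))

  ties <- heat_matrix(
    data.frame(accession = c("b", "c", "a")),
    data.frame(id = "D"),
    values = data.frame(gene = c("b", "c", "a"), descriptor = "D", value = 7)
  )
  expect_equal(sort_rows(ties, "D")$genes$accession, c("a", "b", "c"))
  expect_error(sort_rows(m, "nope"), class = "gmx_reference_error")
})

test_that("sort_rows matches a brute-force stable sort on random matrices", {
  set.seed(101)
  for (rep in 1:5) {
    m <- random_matrix(50, 3, fill = 0.7)
    d <- m$descriptors$id[1]
    v <- rep(NA_real_, 50)
    names(v) <- m$genes$accession
    hit <- m$cells[m$cells$descriptor == d, ]
    v[hit$gene] <- hit$value
    for (ord in c("asc", "desc")) {
      present <- names(v)[!is.na(v)]
      pv <- v[present]
      sorted_present <- present[order(if (ord == "asc") pv else -pv, present,
                                      method = "radix")]
      absent <- sort(names(v)[is.na(v)])
      expect_equal(sort_rows(m, d, ord, "last")$genes$accession,
                   c(sorted_present, absent))
      expect_equal(sort_rows(m, d, ord, "first")$genes$accession,
                   c(absent, sorted_present))
    }
  }
})

test_that("sort and select are value-semantic permutations", {
  set.seed(7)
  m <- random_matrix(20, 4)
  before <- tidy(m)
  s <- sort_rows(m, m$descriptors$id[2], "desc")
  expect_setequal(s$genes$accession, m$genes$accession)
  expect_identical(tidy(m), before)  # input untouched
  sub <- select_rows(m, sprintf("%s > 50", m$descriptors$id[1]))
  expect_identical(tidy(m), before)
  expect_identical(sub$descriptors, m$descriptors)
})

test_that("select_rows filters exactly the satisfying genes", {
  m <- heat_matrix(
    data.frame(accession = sprintf("g%d", 1:5)),
    data.frame(id = c("CF", "S3")),
    values = data.frame(
      gene = c("g1", "g1", "g2", "g2", "g3", "g3", "g4", "g5"),
      descriptor = c("CF", "S3", "CF", "S3", "CF", "S3", "CF", "S3"),
      value = c(0, 2, 0, 1, 3, 1, 0, 4)
    )
  )
  # brute force: g1 (0, 2) yes; g2 (0, 1) yes; g3 (3, 1) no; g4 (0, absent) no;
  # g5 (absent, 4) no because CF is absent, not 0
  expect_equal(select_rows(m, "CF = 0 AND S3 > 0")$genes$accession, c("g1", "g2"))
  expect_equal(select_rows(m, "TRUE")$genes$accession, m$genes$accession)
  expect_equal(nrow(select_rows(m, "ABSENT(CF)")$genes), 1)  # g5 only
  full <- heat_matrix(
    data.frame(accession = c("a", "b")), data.frame(id = "PE"),
    values = data.frame(gene = c("a", "b"), descriptor = "PE", value = c(1, 2))
  )
  expect_equal(nrow(select_rows(full, "ABSENT(PE)")$genes), 0)
  expect_error(select_rows(m, "ZZ > 1"), class = "gmx_reference_error")
})

test_that("canonical round trip: always-true select then double sort is stable", {
  set.seed(42)
  m <- random_matrix(30, 3)
  d <- m$descriptors$id[1]
  canon <- sort_rows(sort_rows(select_rows(m, "TRUE"), d, "asc"), d, "asc")
  expect_equal(canon$genes$accession,
               sort_rows(m, d, "asc")$genes$accession)
  expect_setequal(canon$genes$accession, m$genes$accession)
})
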