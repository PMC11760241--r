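test_that("omics CSVs parse with IDs and values preserved", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,g1,g2", "s1,1.5,2", "s2,-0.5,NA", "s3,0,3.25"), f)
  m <- read_omics_csv(f, "gene_expression")
  expect_s3_class(m, "omics_matrix")
  expect_equal(m$sample_ids, c("s1", "s2", "s3"))
  expect_equal(m$feature_ids, c("g1", "g2"))
  expect_equal(m$values["s2", "g2"], NA_real_)
  expect_equal(m$values["s3", "g2"], 3.25)
})

test_that("write/read round trip reproduces IDs and values exactly", {
  for (m in list(tiny_expression(), tiny_snp(), tiny_cnv())) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_omics_csv(m, f)
    back <- read_omics_csv(f, m$omics_type)
    expect_identical(back$sample_ids, m$sample_ids)
    expect_identical(back$feature_ids, m$feature_ids)
    expect_equal(unname(back$values), unname(m$values))
  }
  # round trip preserves missing expression entries
  me <- tiny_expression()
  me$values[2, 3] <- NA
  f <- withr::local_tempfile(fileext = ".csv")
  write_omics_csv(me, f)
  expect_equal(read_omics_csv(f, "gene_expression")$values[2, 3], NA_real_)
})

test_that("validation errors name the offending cell or ID", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,g1", "s1,1", "s1,2"), f)
  expect_error(read_omics_csv(f, "gene_expression"), "duplicate sample.*s1")

  writeLines(c("id,g1,g2", "s1,1,abc", "s2,2,3"), f)
  expect_error(read_omics_csv(f, "gene_expression"), "abc.*s1.*g2")

  writeLines(c("id,m1", "s1,N"), f)
  expect_error(read_omics_csv(f, "snp"), "A, T, C, G, missing")

  writeLines(c("id,c1", "s1,7"), f)
  expect_error(read_omics_csv(f, "cnv"), "unknown CNV state")

  expect_error(read_omics_csv("no/such/file.csv", "snp"), "not found")
})

test_that("snp and cnv token vocabularies are normalised on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,m1,m2", "s1,a,-", "s2,G,missing"), f)
  m <- read_omics_csv(f, "snp")
  expect_equal(as.vector(m$values), c("A", "G", "missing", "missing"))

  writeLines(c("id,c1,c2", "s1,-2,diploid normal copy", "s2,2,1"), f)
  m <- read_omics_csv(f, "cnv")
  expect_equal(as.vector(m$values),
               c("homozygous_deletion", "high_level_amplification",
                 "diploid_normal", "low_level_amplification"))
})

test_that("transposed CSVs load with the flag", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("feature,s1,s2,s3", "g1,1,2,3", "g2,4,5,6"), f)
  m <- read_omics_csv(f, "gene_expression", transpose = TRUE)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m$values["s2", "g2"], 5)
})

test_that("label tables validate task and completeness", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,label", "s1,LTS", "s2,non-LTS", "s3,LTS", "s4,non-LTS"), f)
  lt <- read_labels(f, "categorical")
  expect_equal(length(unique(lt$values)), 2)
  expect_equal(lt$sample_ids, paste0("s", 1:4))

  writeLines(c("id,label", "s1,1.5", "s2,abc"), f)
  expect_error(read_labels(f, "quantitative"), "abc.*s2")

  writeLines(c("id,label", "s1,same", "s2,same"), f)
  expect_error(read_labels(f, "categorical"), ">= 2 distinct")

  writeLines(c("id,label", "s1,"), f)
  expect_error(read_labels(f, "categorical"), "missing label")

  writeLines("id,label", f)
  expect_error(read_labels(f, "categorical"), "no rows")
})

test_that("GMT collections parse line-per-set with dedup and errors", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3",
               "setB\tdesc\tg1\tg4\tg5\tg6\tg7"), f)
  gs <- read_gmt(f)
  expect_length(gs, 2)
  expect_length(gs$setA$genes, 3)
  expect_length(gs$setB$genes, 5)

  writeLines(c("setA\tdesc\tg1\tg1\tg2"), f)
  expect_length(read_gmt(f)$setA$genes, 2)

  writeLines(c("setA\tdesc\tg1", "setA\tdesc\tg2"), f)
  expect_error(read_gmt(f), "duplicate gene-set name")

  writeLines(c("setA\tdesc"), f)
  expect_error(read_gmt(f), "line 1")
})

test_that("marker annotations enforce half-open coordinates and uniqueness", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("cg001\tchr1\t100\t200\tGENE1", f)
  ann <- read_marker_annotation(f)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$gene, "GENE1")

  writeLines("cg001\tchr1\t100\t100\tGENE1", f)
  expect_error(read_marker_annotation(f), "start >= end")

  writeLines(c("cg001\tchr1\t1\t2\tG1", "cg001\tchr1\t5\t9\tG2"), f)
  expect_error(read_marker_annotation(f), "duplicate marker")

  writeLines(character(), f)
  expect_equal(nrow(read_marker_annotation(f)), 0)
})
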