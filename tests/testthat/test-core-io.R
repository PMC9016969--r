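test_that("BED reading maps fields, validates, and round-trips byte-identically", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t110\tFOXA1",
               "chr2\t5\t30\tGATA3",
               "chr1\t200\t215\tFOXA1"), path)
  df <- read_bed(path)
  expect_equal(df$chrom, c("chr1", "chr2", "chr1"))
  expect_equal(df$start, c(100L, 5L, 200L))
  expect_equal(df$end, c(110L, 30L, 215L))
  expect_equal(df$name, c("FOXA1", "GATA3", "FOXA1"))

  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(df, out)
  expect_identical(readLines(out), readLines(path))

  tfbs <- read_bed(path, group_by_name = TRUE)
  expect_s3_class(tfbs, "tfbs_collection")
  expect_equal(sum(tfbs$sites$tf == "FOXA1"), 2)
})

test_that("malformed BED lines raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t110", "chr1\t110\t100"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\t100"), path)
  expect_error(read_bed(path), "line 1")
  writeLines(c("chr1\tx\t110"), path)
  expect_error(read_bed(path), "line 1")
})

test_that("chromosome dialects are normalized to the chr prefix", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("1\t10\t20\tTF", path)
  expect_equal(read_bed(path)$chrom, "chr1")
  expect_equal(normalize_chrom(c("chrX", "7")), c("chrX", "chr7"))
})

test_that("matrix TSV reading validates IDs, cells and beta range", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tS1\tS2\tS3",
               "cg1\t0.1\t0.5\t0.9",
               "cg2\t0.2\t\t0.8"), path)
  m <- read_matrix(path, type = "methylation")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m["cg1", "S2"], 0.5)
  expect_true(is.na(m["cg2", "S2"]))  # empty cell recorded as missing

  writeLines(c("probe_id\tS1", "cg1\t0.1", "cg1\t0.2"), path)
  expect_error(read_matrix(path), "duplicate row ID")
  writeLines(c("probe_id\tS1\tS2", "cg1\t0.1\toops"), path)
  expect_error(read_matrix(path), "row 'cg1', sample 'S2'")
  writeLines(c("probe_id\tS1", "cg1\t1.2"), path)
  expect_error(read_matrix(path, type = "methylation"), "\\[0, 1\\]")
})

test_that("matrices round-trip through TSV within formatting precision", {
  set.seed(42)
  m <- matrix(runif(60), 10, 6,
              dimnames = list(sprintf("cg%02d", 1:10), sprintf("S%d", 1:6)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path, id_name = "probe_id")
  m2 <- read_matrix(path, type = "methylation")
  expect_equal(m2, m, tolerance = 1e-12)
})

test_that("cohort alignment intersects and orders samples deterministically", {
  expr <- matrix(1:8, 2, 4,
                 dimnames = list(c("TF1", "TF2"), c("A", "B", "C", "D")))
  meth <- matrix(runif(8), 2, 4,
                 dimnames = list(c("cg1", "cg2"), c("E", "D", "C", "B")))
  b <- align_cohort(expr, meth)
  expect_equal(b$samples, c("B", "C", "D"))
  expect_equal(colnames(b$expression), colnames(b$methylation))

  # permuted columns give the identical bundle
  meth2 <- meth[, c(3, 1, 4, 2)]
  expr2 <- expr[, c("C", "A", "D", "B")]
  b2 <- align_cohort(expr2, meth2)
  expect_identical(b$expression, b2$expression)
  expect_identical(b$methylation, b2$methylation)

  meth3 <- meth
  colnames(meth3) <- c("W", "X", "Y", "Z")
  expect_error(align_cohort(expr, meth3), "no shared samples")

  # two shared samples violate the minimum-cohort invariant
  meth4 <- meth
  colnames(meth4) <- c("B", "C", "Y", "Z")
  expect_error(align_cohort(expr, meth4), "fewer than 3")
})

test_that("manifest reading converts 1-based Illumina positions", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\tchrom\tpos", "cg1\t1\t1000", "cg2\tchr2\t1"), path)
  man <- read_manifest(path)
  expect_equal(man$pos, c(999L, 0L))
  expect_equal(man$chrom, c("chr1", "chr2"))
  man0 <- read_manifest(path, one_based = FALSE)
  expect_equal(man0$pos, c(1000L, 1L))
  writeLines(c("probe_id\tchrom\tpos", "cg1\t1\t10", "cg1\t1\t20"), path)
  expect_error(read_manifest(path), "duplicate probe_id")
})

test_that("interval index queries match a brute-force scan over random points", {
  set.seed(7)
  sites <- data.frame(
    chrom = sample(c("chr1", "chr2"), 200, replace = TRUE),
    start = sample.int(50000, 200), name = sample(c("A", "B", "C"), 200, TRUE))
  sites$end <- sites$start + sample(5:40, 200, replace = TRUE)
  tfbs <- tfbs_collection(sites)
  manifest <- data.frame(
    probe_id = sprintf("p%04d", 1:1000),
    chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
    pos = sample.int(51000, 1000) - 1L)
  got <- map_cpgs_to_tfbs(manifest, tfbs, window = 0)
  want <- brute_force_proximity(manifest,
                                setNames(sites, c("chrom", "start", "tf", "end")),
                                window = 0)
  expect_equal(got[sort(names(got))], want[sort(names(want))])
})

test_that("high-missingness CpGs are dropped at the 20% rule", {
  m <- matrix(runif(50), 5, 10, dimnames = list(paste0("cg", 1:5), NULL))
  m[1, 1:3] <- NA  # 30% missing
  m[2, 1:2] <- NA  # 20% missing: kept
  kept <- drop_missing_cpgs(m)
  expect_equal(rownames(kept), paste0("cg", 2:5))
})
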