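test_that("CpG flank windows are built and clipped as stated", {
  man <- data.frame(probe_id = c("a", "b"), chrom = "chr1",
                    pos = c(1000L, 50L))
  w <- window_regions(c("a", "b"), man, flank = 200,
                      chrom_sizes = c(chr1 = 10000L))
  expect_equal(w$start, c(800L, 0L))
  expect_equal(w$end, c(1201L, 251L))
  expect_error(window_regions("zzz", man), "unknown probe")

  # random windows match naive construction and are 401 bp unless clipped
  set.seed(5)
  man2 <- data.frame(probe_id = sprintf("c%03d", 1:100), chrom = "chr1",
                     pos = sample.int(5000, 100))
  w2 <- window_regions(man2$probe_id, man2, flank = 200,
                       chrom_sizes = c(chr1 = 5200L))
  naive_start <- pmax(0, man2$pos - 200)
  naive_end <- pmin(5200, man2$pos + 201)
  expect_equal(w2$start, naive_start[match(w2$name, man2$probe_id)])
  expect_equal(w2$end, naive_end[match(w2$name, man2$probe_id)])
  unclipped <- w2$start > 0 & w2$end < 5200
  expect_true(all((w2$end - w2$start)[unclipped] == 401))
})

test_that("GC content counts ambiguous bases in the denominator only", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = "AAAAGCGCGCNNA"))
  regions <- data.frame(chrom = "chr1",
                        start = c(0L, 4L, 8L), end = c(4L, 8L, 13L))
  expect_equal(gc_content(regions, seqs), c(0, 1, 0.4))
  bad <- data.frame(chrom = "chr1", start = 10L, end = 20L)
  expect_error(gc_content(bad, seqs), "beyond")
  missing <- data.frame(chrom = "chr9", start = 0L, end = 2L)
  expect_error(gc_content(missing, seqs), "chr9")
})

test_that("two-set differential enrichment matches the hypergeometric tail", {
  # foreground: 10 regions, 8 overlapping; other: 20 regions, 2 overlapping
  fg <- data.frame(chrom = "chr1", start = seq(0, 9000, by = 1000))
  fg$end <- fg$start + 100L
  ot <- data.frame(chrom = "chr1", start = seq(20000, 39000, by = 1000))
  ot$end <- ot$start + 100L
  hit_starts <- c(fg$start[1:8], ot$start[1:2]) + 10L
  sites <- data.frame(chrom = "chr1", start = hit_starts,
                      end = hit_starts + 20L, name = "TFX")
  rows <- differential_tfbs_enrichment(fg, ot, tfbs_collection(sites))
  expect_equal(rows[, c("a", "b", "c", "d")],
               data.frame(a = 8L, b = 2L, c = 2L, d = 18L),
               ignore_attr = TRUE)
  want_p <- enumerate_hyper_tail(8, marked = 10, universe = 30, draws = 10)
  expect_equal(rows$p_one_sided, want_p, tolerance = 1e-12)
  expect_equal(rows$p_one_sided,
               fisher.test(matrix(c(8, 2, 2, 18), 2, byrow = TRUE),
                           alternative = "greater")$p.value,
               tolerance = 1e-10)
  expect_equal(rows$odds_ratio, (8 * 18) / (2 * 2))

  # swapping foreground and other swaps a<->c and b<->d exactly
  sw <- differential_tfbs_enrichment(ot, fg, tfbs_collection(sites))
  expect_equal(sw[, c("a", "b", "c", "d")], rows[, c("c", "d", "a", "b")],
               ignore_attr = TRUE)

  # a set hitting nothing: p = 1, Haldane-corrected odds ratio
  sites0 <- rbind(sites, data.frame(chrom = "chr1", start = 90000L,
                                    end = 90020L, name = "TFZ"))
  rows2 <- differential_tfbs_enrichment(fg, ot, tfbs_collection(sites0))
  z <- rows2[rows2$tf == "TFZ", ]
  expect_equal(z$p_one_sided, 1)
  expect_equal(z$odds_ratio, (0.5 * 20.5) / (10.5 * 0.5))

  expect_error(differential_tfbs_enrichment(fg, fg, tfbs_collection(sites)),
               "overlap")
})

test_that("hypergeometric tails agree with enumeration for universes up to 200", {
  set.seed(17)
  for (i in 1:40) {
    N <- sample(10:200, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hyper_tail(k, K, N, n), enumerate_hyper_tail(k, K, N, n),
                 tolerance = 1e-10)
    expect_equal(hyper_tail(k, K, N, n),
                 sum(dhyper(k:min(K, n), K, N - K, n)), tolerance = 1e-10)
  }
})

test_that("genomic context annotation applies strand-aware promoter precedence", {
  ann <- data.frame(
    gene_id = c("G1", "G2"), chrom = "chr1",
    start = c(5000L, 20000L), end = c(8000L, 23000L),
    strand = c("+", "-"), tss = c(5000L, 22999L))
  ann$exons <- list(cbind(start = c(5000L, 7500L), end = c(5600L, 8000L)),
                    cbind(start = c(20000L, 22400L), end = c(20600L, 23000L)))
  man <- data.frame(
    probe_id = c("up300", "minus_up", "exonic", "intronic", "far"),
    chrom = "chr1",
    pos = c(4700L,   # 300 bp upstream of + TSS: promoter
            23300L,  # 301 bp upstream of - TSS (pos strandwise): promoter
            5200L,   # inside first exon, past the promoter window
            6000L,   # between the two exons of G1
            60000L))
  got <- annotate_genomic_context(man$probe_id, man, ann)
  expect_equal(unname(got$category),
               c("promoter", "promoter", "exon", "intron", "intergenic"))
  expect_equal(as.integer(got$distribution),
               c(2L, 1L, 1L, 1L))

  # random CpGs match the brute-force classifier
  set.seed(23)
  man2 <- data.frame(probe_id = sprintf("c%03d", 1:300), chrom = "chr1",
                     pos = sample.int(70000, 300))
  got2 <- annotate_genomic_context(man2$probe_id, man2, ann)
  want <- brute_force_context(man2$pos, man2$chrom, ann)
  expect_equal(unname(got2$category), want)
})

test_that("list-overlap Fisher test matches closed forms", {
  one <- list_overlap_fisher("x", "x", universe_size = 10)
  expect_equal(one$p, 0.1, tolerance = 1e-12)  # 1 - 9/10
  expect_equal(one$overlap, 1)

  disjoint <- list_overlap_fisher(c("a", "b"), c("c", "d"), 100)
  expect_equal(disjoint$overlap, 0)
  expect_equal(disjoint$p, 1)

  # TF-list sized case: |A| = 13, |B| = 34, overlap 11, universe 231
  A <- c(paste0("S", 1:11), "a1", "a2")
  B <- c(paste0("S", 1:11), paste0("b", 1:23))
  got <- list_overlap_fisher(A, B, 231)
  expect_equal(got$overlap, 11)
  expect_equal(got$p, enumerate_hyper_tail(11, 34, 231, 13),
               tolerance = 1e-12)
  expect_equal(got$p,
               fisher.test(matrix(c(11, 2, 23, 195), 2, byrow = TRUE),
                           alternative = "greater")$p.value,
               tolerance = 1e-10)
})
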