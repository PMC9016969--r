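test_that("IQR filter uses strict type-7 quartiles", {
  m <- rbind(
    const = c(0.5, 0.5, 0.5, 0.5),              # IQR 0: dropped
    atcut = c(0.4, 0.4, 0.5, 0.5),              # IQR exactly 0.1: dropped
    below = c(0.40, 0.45, 0.50, 0.55),          # type-7 IQR 0.075: dropped
    wide  = c(0.1, 0.2, 0.8, 0.9)               # Q1 .175, Q3 .825: kept
  )
  colnames(m) <- paste0("S", 1:4)
  kept <- iqr_filter(m, 0.1)
  expect_equal(rownames(kept), "wide")
  # hand evaluation of the stated quantile rule
  q <- quantile(m["wide", ], c(.25, .75), type = 7)
  expect_equal(unname(q), c(0.175, 0.825))
  expect_warning(iqr_filter(m[1:2, , drop = FALSE], 0.1), "every CpG")
})

test_that("proximity window boundary is inclusive at exactly 200 bp", {
  tfbs <- tfbs_collection(data.frame(chrom = "chr1", start = 1100,
                                     end = 1110, name = "TF1"))
  man <- data.frame(probe_id = c("in200", "out201", "inside"),
                    chrom = "chr1", pos = c(900L, 899L, 1105L))
  got <- map_cpgs_to_tfbs(man, tfbs, window = 200)
  expect_equal(got$TF1, c("in200", "inside"))
  # right boundary: last covered base is 1109, so 1309 maps, 1310 does not
  man2 <- data.frame(probe_id = c("r_in", "r_out"), chrom = "chr1",
                     pos = c(1309L, 1310L))
  expect_equal(map_cpgs_to_tfbs(man2, tfbs, window = 200)$TF1, "r_in")
})

test_that("random proximity maps equal the all-pairs brute-force oracle", {
  set.seed(13)
  sites <- data.frame(chrom = "chr1", start = sample.int(100000, 200),
                      name = sample(paste0("TF", 1:5), 200, replace = TRUE))
  sites$end <- sites$start + sample(8:25, 200, replace = TRUE)
  tfbs <- tfbs_collection(sites)
  man <- data.frame(probe_id = sprintf("cg%03d", 1:500), chrom = "chr1",
                    pos = sample.int(101000, 500) - 1L)
  got <- map_cpgs_to_tfbs(man, tfbs, window = 200)
  want <- brute_force_proximity(man,
                                setNames(sites, c("chrom", "start", "tf", "end")),
                                window = 200)
  expect_equal(got[sort(names(got))], want[sort(names(want))])
})

make_bundle <- function(expr, meth) {
  n <- ncol(expr)
  colnames(expr) <- colnames(meth) <- paste0("S", seq_len(n))
  align_cohort(expr, meth)
}

test_that("Spearman screen handles perfect, degenerate and tied inputs", {
  expr <- rbind(TF1 = c(1, 2, 3, 4, 5))
  meth <- rbind(cg1 = c(0.9, 0.7, 0.5, 0.3, 0.1),
                cg2 = c(0.4, 0.4, 0.4, 0.4, 0.4))
  tab <- spearman_screen(make_bundle(expr, meth))
  expect_equal(tab$rho[tab$probe_id == "cg1"], -1)
  expect_true(is.na(tab$rho[tab$probe_id == "cg2"]))
  flagged <- bonferroni_flag(tab, alpha = 0.01, family_size = 2)
  expect_false(flagged$significant[flagged$probe_id == "cg2"])

  # average-rank computation with tie correction vs the base-R oracle
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(0.31, 0.27, 0.59, 0.28, 0.41, 0.10, 0.44, 0.35)
  tab2 <- spearman_screen(make_bundle(rbind(TF1 = x), rbind(cg1 = y)))
  expect_equal(tab2$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("screen rho and p agree with scalar spearman_test and base R across random cases", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    x <- sample(1:8, n, replace = TRUE) + runif(n) * (i %% 2)  # ties half the time
    y <- round(runif(n), 2)
    if (i %% 5 == 0) y[sample(n, 2)] <- NA
    got <- spearman_test(x, y)
    ok <- complete.cases(x, y)
    expect_equal(got$rho, cor(x[ok], y[ok], method = "spearman"),
                 tolerance = 1e-12)
    k <- spearman_screen_matrix(rbind(a = x), rbind(b = y))
    expect_equal(unname(k$rho[1, 1]), got$rho, tolerance = 1e-12)
    expect_equal(unname(k$p[1, 1]), got$p, tolerance = 1e-12)
    # t-approximation two-sided p recomputed from first principles
    r <- got$rho; m <- sum(ok)
    tt <- r * sqrt((m - 2) / (1 - r^2))
    expect_equal(got$p, 2 * pt(-abs(tt), m - 2), tolerance = 1e-12)
  }
})

test_that("Bonferroni flags match direct arithmetic and a recount", {
  tab <- data.frame(tf = "TF1", probe_id = c("a", "b"),
                    rho = c(0.9, 0.5), p_raw = c(1e-9, 2e-8))
  out <- bonferroni_flag(tab, alpha = 0.01, family_size = 1e6)
  expect_equal(out$significant, c(TRUE, FALSE))
  expect_error(bonferroni_flag(tab, family_size = 0), "positive")

  set.seed(3)
  big <- data.frame(tf = "TF1", probe_id = sprintf("c%04d", 1:2000),
                    rho = runif(2000, -1, 1), p_raw = 10^runif(2000, -9, 0))
  fam <- 5000
  out <- bonferroni_flag(big, alpha = 0.01, family_size = fam)
  expect_equal(sum(out$significant), sum(big$p_raw < 0.01 / fam))
})

test_that("proximal fraction counts significant proximal CpGs", {
  tab <- data.frame(
    tf = "TF1", probe_id = sprintf("cg%02d", 1:12),
    rho = rep(-0.5, 12), p_raw = rep(1e-10, 12),
    significant = c(rep(TRUE, 4), rep(FALSE, 8)))
  prox <- list(TF1 = sprintf("cg%02d", 1:10), TF2 = character(0))
  fr <- proximal_fraction(tab, prox)
  expect_equal(fr$fraction, 0.4)
  expect_equal(fr$n_proximal, 10)
  # zero significant
  tab$significant <- FALSE
  expect_equal(proximal_fraction(tab, prox)$fraction, 0)

  # recount oracle on a random fixture
  set.seed(8)
  tfs <- paste0("TF", 1:4)
  tab2 <- expand.grid(tf = tfs, probe_id = sprintf("cg%03d", 1:200),
                      stringsAsFactors = FALSE)
  tab2$rho <- runif(nrow(tab2), -1, 1)
  tab2$p_raw <- runif(nrow(tab2))
  tab2$significant <- tab2$p_raw < 0.1
  prox2 <- lapply(setNames(tfs, tfs), function(tf)
    sample(sprintf("cg%03d", 1:200), 50))
  fr2 <- proximal_fraction(tab2, prox2)
  for (tf in tfs) {
    sub <- tab2[tab2$tf == tf & tab2$probe_id %in% prox2[[tf]], ]
    expect_equal(fr2$fraction[fr2$tf == tf], mean(sub$significant))
  }
})

test_that("MWU enrichment gives the exact worked p of 1/35 and handles ties", {
  tab <- data.frame(
    tf = "TF1", probe_id = paste0("c", 1:7),
    rho = c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3, 0.4),
    p_raw = 0.5, significant = FALSE)
  prox <- list(TF1 = paste0("c", 1:3))
  res <- mwu_proximity_enrichment(tab, prox, "TF1")
  expect_equal(res$U, 12)
  expect_equal(res$p, 1 / 35, tolerance = 1e-12)

  # full ties never pass a 0.01 gate
  tied <- mwu_greater(rep(0.3, 10), rep(0.3, 40))
  expect_gt(tied$p, 0.4)

  # empty group => undefined p
  res2 <- mwu_proximity_enrichment(tab, list(TF1 = character(0)), "TF1")
  expect_true(is.na(res2$p))
})

test_that("exact MWU p equals exhaustive enumeration for all small no-tie inputs", {
  set.seed(21)
  for (i in 1:30) {
    n1 <- sample(1:8, 1)
    n2 <- sample(2:9, 1)
    v <- sample(seq(0.01, 0.99, by = 0.01), n1 + n2)  # distinct values
    x <- v[seq_len(n1)]
    y <- v[-seq_len(n1)]
    got <- mwu_greater(x, y)
    expect_equal(got$p, enumerate_mwu_p(x, y), tolerance = 1e-12,
                 info = sprintf("case %d (n1=%d, n2=%d)", i, n1, n2))
  }
})

test_that("candidate gates apply min_sig, pooled percentile and MWU thresholds", {
  # boundary: 4999 significant CpGs fails gate 1
  st <- data.frame(tf = c("A", "B"), cohort = "C1",
                   n_sig_total = c(4999L, 5000L), fraction = c(0.9, 0.9),
                   mwu_p = c(1e-10, 1e-10))
  out <- select_candidates(st)
  expect_equal(out$passed_min_sig, c(FALSE, TRUE))

  # derived type-7 quantile: fractions 0.01 * (1..40), 95th pct = 0.3805
  st2 <- data.frame(tf = paste0("T", 1:40), cohort = "C1",
                    n_sig_total = 10000L, fraction = 0.01 * (1:40),
                    mwu_p = 1e-9)
  out2 <- select_candidates(st2)
  expect_equal(out2$fraction_cutoff[1], 0.3805)
  expect_equal(sum(out2$passed_percentile), 2)  # exactly the top pairs

  # identical fractions all pass the >= comparison
  st3 <- st2
  st3$fraction <- 0.2
  expect_true(all(select_candidates(st3)$passed_percentile))
  expect_error(select_candidates(st2, percentile = 100), "strictly between")
})

test_that("MWU p is Bonferroni-corrected across tested pairs", {
  st <- data.frame(tf = paste0("T", 1:20), cohort = "C1",
                   n_sig_total = 10000L, fraction = 0.5,
                   mwu_p = c(0.0004, rep(0.001, 19)))
  out <- select_candidates(st, mwu_alpha = 0.01)
  # 0.0004 * 20 = 0.008 < 0.01 passes; 0.001 * 20 = 0.02 fails
  expect_equal(out$passed_mwu, c(TRUE, rep(FALSE, 19)))
})

test_that("emTF calls require recurrence across cohorts", {
  cand <- data.frame(tf = c("A", "A", "B"), cohort = c("C1", "C2", "C1"),
                     candidate = TRUE)
  tabs <- list(
    C1 = data.frame(tf = c("A", "A", "B"), probe_id = c("p1", "p2", "p3"),
                    rho = c(-0.5, 0.4, -0.3), significant = c(TRUE, TRUE, TRUE)),
    C2 = data.frame(tf = "A", probe_id = "p1", rho = -0.6, significant = TRUE))
  prox <- list(A = c("p1", "p2"), B = "p3")
  cs <- call_emtfs(cand, tabs, prox, min_cohorts = 2)
  expect_equal(cs$emtfs, "A")
  expect_equal(cs$emcpgs$A$C1$probe_id, c("p1", "p2"))

  single <- cand[cand$cohort == "C1", ]
  expect_warning(cs2 <- call_emtfs(single, tabs["C1"], prox, min_cohorts = 2),
                 "min_cohorts")
  expect_length(cs2$emtfs, 0)
})

test_that("sign partition reports proportions over all proximal CpGs", {
  emcpg <- data.frame(probe_id = c("a", "b", "c"), rho = c(-0.5, -0.4, 0.3))
  part <- partition_sign(emcpg, n_proximal = 10)
  expect_equal(part$prop_negative, 0.2)
  expect_equal(part$prop_positive, 0.1)
  allneg <- data.frame(probe_id = c("a", "b"), rho = c(-0.5, -0.1))
  expect_equal(partition_sign(allneg, 5)$prop_positive, 0)
})

test_that("raising alpha or window never shrinks result sets", {
  set.seed(31)
  tab <- data.frame(tf = "TF1", probe_id = sprintf("c%03d", 1:300),
                    rho = runif(300, -1, 1), p_raw = 10^runif(300, -8, 0))
  for (alphas in list(c(0.001, 0.01), c(0.01, 0.05))) {
    lo <- bonferroni_flag(tab, alpha = alphas[1], family_size = 300)
    hi <- bonferroni_flag(tab, alpha = alphas[2], family_size = 300)
    expect_true(all(!lo$significant | hi$significant))
  }
  sites <- data.frame(chrom = "chr1", start = sample.int(50000, 100),
                      name = sample(paste0("TF", 1:3), 100, TRUE))
  sites$end <- sites$start + 15L
  tfbs <- tfbs_collection(sites)
  man <- data.frame(probe_id = sprintf("cg%03d", 1:300), chrom = "chr1",
                    pos = sample.int(50000, 300))
  for (w in list(c(0, 100), c(100, 200), c(200, 500))) {
    small <- map_cpgs_to_tfbs(man, tfbs, window = w[1])
    large <- map_cpgs_to_tfbs(man, tfbs, window = w[2])
    for (tf in names(small)) {
      expect_true(all(small[[tf]] %in% large[[tf]]))
    }
  }
})

test_that("missing TF in the expression matrix is reported by name", {
  expr <- rbind(TF1 = 1:5)
  meth <- rbind(cg1 = runif(5))
  b <- make_bundle(expr, meth)
  expect_error(spearman_screen(b, tf_list = c("TF1", "TFX")), "TFX")
})
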