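# Shared fixture builders. Everything is generated in code at test time.

# small but fully structured simulation used by unit tests
small_sim_config <- function(seed = 11, ...) {
  args <- list(seed = seed, n_cohorts = 2, n_samples = 40, n_tfs = 6,
               n_cpgs = 400, sites_per_tf = 20, emcpgs_per_tf = 50,
               n_planted = 2, n_protectors = 2, n_protected = 40,
               n_purity_pos = 1, n_purity_neg = 1, n_true_links = 20,
               n_decoy_genes = 10, atac_n_peaks = 20, atac_n_samples = 25,
               chrom_length = 2e6)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# matching pipeline thresholds for the small synthetic universe
small_pipe_config <- function(cfg, ...) {
  synthetic_pipeline_config(cfg, atac_min_samples = 20, ...)
}

# brute-force CpG-to-TF proximity map (quadratic scan oracle)
brute_force_proximity <- function(manifest, sites, window) {
  out <- lapply(sort(unique(sites$tf)), function(tf) {
    s <- sites[sites$tf == tf, , drop = FALSE]
    hit <- vapply(seq_len(nrow(manifest)), function(i) {
      same <- s$chrom == manifest$chrom[i]
      if (!any(same)) return(FALSE)
      d <- pmax(0, pmax(s$start[same] - manifest$pos[i],
                        manifest$pos[i] - (s$end[same] - 1L)))
      any(d <= window)
    }, logical(1))
    sort(manifest$probe_id[hit])
  })
  names(out) <- sort(unique(sites$tf))
  out
}

# exhaustive Mann-Whitney enumeration oracle: one-sided P(U >= u_obs)
# over all assignments of ranks to the first group (no ties assumed)
enumerate_mwu_p <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(u_all >= u_obs)
}

# exhaustive hypergeometric tail: P(overlap >= k) by term summation
enumerate_hyper_tail <- function(k, marked, universe, draws) {
  ks <- k:min(marked, draws)
  sum(choose(marked, ks) * choose(universe - marked, draws - ks)) /
    choose(universe, draws)
}

# brute-force genomic context classifier
brute_force_context <- function(pos, chrom, annotation, up = 1000, dn = 100) {
  vapply(seq_along(pos), function(i) {
    same <- annotation[annotation$chrom == chrom[i], , drop = FALSE]
    for (j in seq_len(nrow(same))) {
      tss <- same$tss[j]
      win <- if (same$strand[j] == "+") c(tss - up, tss + dn)
             else c(tss - dn, tss + up)
      if (pos[i] >= win[1] && pos[i] <= win[2]) return("promoter")
    }
    for (j in seq_len(nrow(same))) {
      ex <- same$exons[[j]]
      if (!is.null(ex) &&
          any(pos[i] >= ex[, 1] & pos[i] < ex[, 2])) return("exon")
    }
    for (j in seq_len(nrow(same))) {
      if (pos[i] >= same$start[j] && pos[i] < same$end[j]) return("intron")
    }
    "intergenic"
  }, character(1))
}
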