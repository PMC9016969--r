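## Seeded multi-cohort simulator with planted structure and ground truth.
##
## The generator emulates the statistical structure the screen assumes:
## TF expression is log-normal; planted emCpGs respond to their TF's
## standardized log-expression through a logistic link (keeping beta in
## (0,1) without clipping); methylation-protected CpGs are constitutively
## hypomethylated i.i.d. Beta draws near protector-TF sites; null CpGs mix
## variable and near-constant baselines; target-gene expression decreases
## with linked-CpG methylation; ATAC counts decrease with methylation;
## tumour purity optionally loads on selected TFs' expression.

#' Simulation configuration
#'
#' Defaults encode the standard two-cohort recovery study: 150 samples per
#' cohort, 40 TFs with 200 binding sites each on a 20 Mb synthetic
#' chromosome, 30,000 CpGs of which 5 planted demethylating emTFs own
#' 1,000 emCpGs each, 4 protector TFs with 500 protected CpGs, and the
#' remainder null. `effect_slope = 0.6` with unit logit noise gives planted
#' pairs a latent correlation of 0.51, i.e. a median Spearman rho of about
#' 0.5 at n = 150.
#'
#' @param seed integer RNG seed; the whole fixture is a deterministic
#'   function of the config.
#' @param n_cohorts,n_samples,n_tfs,n_cpgs cohort/genome dimensions.
#' @param sites_per_tf,site_length,chrom,chrom_length genome layout.
#' @param window proximity window used for CpG placement (bp).
#' @param n_planted number of planted emTFs (the first TFs by name).
#' @param direction "demethylating" (negative planted correlations) or
#'   "methylating"; scalar or per-planted-TF vector.
#' @param effect_slope slope of the planted TF effect on the logit scale
#'   (0 disables all planted effects).
#' @param emcpgs_per_tf planted emCpGs per planted TF.
#' @param homotypic_cluster_factor,homotypic_fraction a fraction of each
#'   planted TF's loci carries this many co-located sites (homotypic
#'   clusters).
#' @param n_protectors,n_protected,protected_beta_params protector TFs
#'   (the last TFs by name), number of protected CpGs, and the Beta-law
#'   shape parameters of their constitutive hypomethylation.
#' @param noise_sd CpG-level logit noise standard deviation.
#' @param null_near_fraction fraction of null CpGs placed near binding
#'   sites (the rest are uniform on the chromosome).
#' @param purity_beta_params Beta law of per-sample tumour purity.
#' @param purity_loading,n_purity_pos,n_purity_neg strength and number of
#'   TFs with positive (cancer-cell) and negative (microenvironment)
#'   purity loadings on log-expression.
#' @param n_true_links number of emCpG-to-gene links planted;
#'   `reg_element_fraction` of them act through a regulatory element, the
#'   rest through the nearest TSS.
#' @param link_slope,link_noise_sd log-expression response of true target
#'   genes to their CpG's beta (defaults target |rho| of about 0.6).
#' @param n_decoy_genes unlinked genes with independent expression.
#' @param atac_n_peaks,atac_slope,atac_noise_sd,atac_n_samples ATAC peaks
#'   planted over emCpGs, log-count response to beta, and the number of
#'   cohort samples with ATAC data.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_cohorts = 2, n_samples = 150,
                       n_tfs = 40, n_cpgs = 30000, sites_per_tf = 200,
                       site_length = c(10L, 20L), chrom = "chrS",
                       chrom_length = 2e7, window = 200, n_planted = 5,
                       direction = "demethylating", effect_slope = 0.6,
                       emcpgs_per_tf = 1000,
                       homotypic_cluster_factor = 3,
                       homotypic_fraction = 0.3, n_protectors = 4,
                       n_protected = 500, protected_beta_params = c(1, 20),
                       noise_sd = 1, null_near_fraction = 0.5,
                       purity_beta_params = c(6, 3), purity_loading = 1,
                       n_purity_pos = 2, n_purity_neg = 2,
                       n_true_links = 200, reg_element_fraction = 0.6,
                       link_slope = 2, link_noise_sd = 0.55,
                       n_decoy_genes = 100, atac_n_peaks = 400,
                       atac_slope = 4, atac_noise_sd = 0.3,
                       atac_n_samples = 50) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_samples >= 3, cfg$n_tfs >= 1, cfg$n_cpgs >= 1,
            cfg$sites_per_tf >= 1, cfg$effect_slope >= 0,
            cfg$homotypic_cluster_factor >= 1,
            cfg$n_planted + cfg$n_protectors <= cfg$n_tfs)
  n_em <- cfg$n_planted * cfg$emcpgs_per_tf
  if (n_em + cfg$n_protected > cfg$n_cpgs) {
    stop("n_cpgs too small for the requested planted and protected CpGs",
         call. = FALSE)
  }
  if (cfg$chrom_length < 500 * (cfg$n_tfs * cfg$sites_per_tf + cfg$n_cpgs) / 100) {
    stop("chromosome too short for the requested site and CpG density",
         call. = FALSE)
  }
  cfg$tf_names <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  cfg$planted_emtfs <- cfg$tf_names[seq_len(cfg$n_planted)]
  cfg$protector_tfs <- if (cfg$n_protectors > 0)
    cfg$tf_names[(cfg$n_tfs - cfg$n_protectors + 1):cfg$n_tfs] else character(0)
  cfg$direction <- rep(cfg$direction, length.out = cfg$n_planted)
  stopifnot(all(cfg$direction %in% c("demethylating", "methylating")))
  # purity loads on the first planted TFs (+, cancer-cell context) and the
  # last planted TFs (-, microenvironment context)
  cfg$n_purity_pos <- min(cfg$n_purity_pos, cfg$n_planted)
  cfg$n_purity_neg <- min(cfg$n_purity_neg, cfg$n_planted - cfg$n_purity_pos)
  cfg$purity_loadings <- c(
    setNames(rep(cfg$purity_loading, cfg$n_purity_pos),
             cfg$planted_emtfs[seq_len(cfg$n_purity_pos)]),
    setNames(rep(-cfg$purity_loading, cfg$n_purity_neg),
             rev(cfg$planted_emtfs)[seq_len(cfg$n_purity_neg)])
  )
  structure(cfg, class = "sim_config")
}

## uniform CpG position with distance <= window from site [start, end)
place_near <- function(start, end, window, chrom_length) {
  lo <- pmax(0L, start - window)
  hi <- pmin(chrom_length - 1L, end - 1L + window)
  lo + floor(runif(length(start)) * (hi - lo + 1L))
}

#' Simulate the synthetic genome layout
#'
#' Places binding sites, CpGs (planted emCpGs within the proximity window
#' of their own TF's sites, protected CpGs near protector sites, null CpGs
#' near and far), genes with TSSs/exons, regulatory elements covering a
#' subset of emCpGs, and ATAC peaks over emCpGs. Deterministic in
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `manifest`, `tfbs` ([tfbs_collection()]),
#'   `annotation`, `regmap`, `atac_peaks`, and `truth` (planted emCpG
#'   table, protected probes, true links, planted emTFs/protectors).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cl <- config$chrom_length

  ## binding sites
  site_list <- lapply(config$tf_names, function(tf) {
    start <- sample.int(cl - 500L, config$sites_per_tf)
    len <- sample(seq(config$site_length[1], config$site_length[2]),
                  config$sites_per_tf, replace = TRUE)
    df <- data.frame(chrom = config$chrom, start = start,
                     end = start + len, name = tf,
                     stringsAsFactors = FALSE)
    if (tf %in% config$planted_emtfs && config$homotypic_cluster_factor > 1) {
      n_clust <- floor(config$homotypic_fraction * config$sites_per_tf)
      if (n_clust > 0) {
        idx <- seq_len(n_clust)
        extra <- df[rep(idx, config$homotypic_cluster_factor - 1), ]
        shift <- sample(-30:30, nrow(extra), replace = TRUE)
        extra$start <- pmax(0L, extra$start + shift)
        extra$end <- extra$start + (df$end[rep(idx, config$homotypic_cluster_factor - 1)] -
                                      df$start[rep(idx, config$homotypic_cluster_factor - 1)])
        df <- rbind(df, extra)
      }
    }
    df
  })
  sites <- do.call(rbind, site_list)
  rownames(sites) <- NULL
  tfbs <- tfbs_collection(sites)

  ## CpGs: planted emCpGs around their own TF's primary sites
  em_list <- lapply(seq_len(config$n_planted), function(i) {
    tf <- config$planted_emtfs[i]
    own <- site_list[[i]][seq_len(config$sites_per_tf), ]
    pick <- rep_len(seq_len(nrow(own)), config$emcpgs_per_tf)
    data.frame(tf = tf,
               pos = place_near(own$start[pick], own$end[pick],
                                config$window, cl),
               direction = config$direction[i], stringsAsFactors = FALSE)
  })
  em <- do.call(rbind, em_list)
  n_em <- if (is.null(em)) 0L else nrow(em)

  prot_pos <- integer(0)
  if (config$n_protected > 0 && length(config$protector_tfs)) {
    prot_sites <- do.call(rbind, site_list[match(config$protector_tfs,
                                                 config$tf_names)])
    pick <- rep_len(seq_len(nrow(prot_sites)), config$n_protected)
    prot_pos <- place_near(prot_sites$start[pick], prot_sites$end[pick],
                           config$window, cl)
  }

  n_null <- config$n_cpgs - n_em - length(prot_pos)
  n_near <- floor(config$null_near_fraction * n_null)
  pick <- sample.int(nrow(sites), n_near, replace = TRUE)
  null_near <- place_near(sites$start[pick], sites$end[pick],
                          config$window, cl)
  null_far <- sample.int(cl, n_null - n_near) - 1L

  pos <- c(if (n_em) em$pos, prot_pos, null_near, null_far)
  kind <- c(if (n_em) rep("emcpg", n_em),
            rep("protected", length(prot_pos)),
            rep("null", n_null))
  manifest <- data.frame(
    probe_id = sprintf("cg%06d", seq_along(pos)),
    chrom = config$chrom, pos = as.integer(pos),
    stringsAsFactors = FALSE)
  truth_emcpg <- if (n_em) {
    data.frame(probe_id = manifest$probe_id[seq_len(n_em)],
               tf = em$tf, direction = em$direction,
               stringsAsFactors = FALSE)
  } else {
    data.frame(probe_id = character(0), tf = character(0),
               direction = character(0))
  }
  protected_ids <- manifest$probe_id[seq_len(length(prot_pos)) + n_em]

  ## genes: true-link targets + decoys; 2 exons each so introns exist
  n_links <- min(config$n_true_links, n_em)
  link_probes <- if (n_links) truth_emcpg$probe_id[
    seq(1L, n_em, length.out = n_links)] else character(0)
  link_pos <- manifest$pos[match(link_probes, manifest$probe_id)]
  n_reg <- floor(config$reg_element_fraction * n_links)
  gene_ids <- sprintf("GENE%03d", seq_len(n_links))
  decoy_ids <- if (config$n_decoy_genes > 0)
    sprintf("DEC%03d", seq_len(config$n_decoy_genes)) else character(0)

  gene_tss <- integer(0)
  if (n_links) {
    # regulatory-element targets live far from their CpG; nearest-TSS
    # targets get a TSS placed a few hundred bp from the CpG
    tss_reg <- sample.int(cl - 20000L, n_reg)
    off <- sample(c(-1, 1), n_links - n_reg, replace = TRUE) *
      sample(300:800, n_links - n_reg, replace = TRUE)
    tss_near <- pmin(cl - 20000L, pmax(2000L, link_pos[(n_reg + 1):n_links] + off))
    gene_tss <- c(tss_reg, tss_near)
  }
  decoy_tss <- if (length(decoy_ids)) sample.int(cl - 20000L, length(decoy_ids))
               else integer(0)
  all_ids <- c(gene_ids, decoy_ids)
  all_tss <- as.integer(c(gene_tss, decoy_tss))
  strand <- sample(c("+", "-"), length(all_ids), replace = TRUE)
  gstart <- ifelse(strand == "+", all_tss, all_tss - 1999L)
  gend <- gstart + 2000L
  annotation <- data.frame(gene_id = all_ids, chrom = config$chrom,
                           start = as.integer(gstart), end = as.integer(gend),
                           strand = strand, tss = all_tss,
                           stringsAsFactors = FALSE)
  annotation$exons <- lapply(seq_along(all_ids), function(i) {
    cbind(start = c(gstart[i], gend[i] - 500L),
          end = c(gstart[i] + 500L, gend[i]))
  })

  regmap <- if (n_reg > 0) {
    data.frame(chrom = config$chrom,
               start = as.integer(pmax(0L, link_pos[seq_len(n_reg)] - 50L)),
               end = as.integer(link_pos[seq_len(n_reg)] + 51L),
               gene_id = gene_ids[seq_len(n_reg)], stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               gene_id = character(0))
  }
  links <- if (n_links) {
    data.frame(probe_id = link_probes, gene_id = gene_ids,
               source = c(rep("regulatory_map", n_reg),
                          rep("nearest_tss", n_links - n_reg)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(probe_id = character(0), gene_id = character(0),
               source = character(0))
  }

  ## ATAC peaks over a sample of emCpGs
  n_peaks <- min(config$atac_n_peaks, n_em)
  atac_peaks <- if (n_peaks > 0) {
    pk_probe <- truth_emcpg$probe_id[seq(1L, n_em, length.out = n_peaks)]
    pk_pos <- manifest$pos[match(pk_probe, manifest$probe_id)]
    data.frame(chrom = config$chrom,
               start = as.integer(pmax(0L, pk_pos - 100L)),
               end = as.integer(pk_pos + 101L),
               peak_id = sprintf("peak%04d", seq_len(n_peaks)),
               probe_id = pk_probe, stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               peak_id = character(0), probe_id = character(0))
  }

  list(manifest = manifest, tfbs = tfbs, annotation = annotation,
       regmap = regmap, atac_peaks = atac_peaks,
       truth = list(emtfs = config$planted_emtfs,
                    protectors = config$protector_tfs,
                    emcpg = truth_emcpg, protected = protected_ids,
                    links = links))
}

#' Simulate one cohort over a synthetic genome
#'
#' Draws per-sample tumour purity and TF expression (log-normal; purity
#' loadings enter the latent log-expression before standardization, so
#' planted correlations are preserved), methylation betas per CpG class,
#' target-gene and decoy expression, and ATAC counts.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()] under the same config.
#' @param cohort_index 1-based cohort number (own RNG stream).
#' @return list with `cohort` ([align_cohort()] bundle), `purity` (named
#'   vector), `atac_counts` (peak-by-sample matrix), and `truth` (genome
#'   truth plus the purity vector and loadings).
#' @export
simulate_cohort <- function(config, genome, cohort_index = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 3) stop("n_samples must be >= 3", call. = FALSE)
  set.seed(config$seed + 10000L * cohort_index)
  n <- config$n_samples
  cname <- sprintf("C%d", cohort_index)
  samples <- sprintf("%s_S%03d", cname, seq_len(n))

  purity <- rbeta(n, config$purity_beta_params[1], config$purity_beta_params[2])
  names(purity) <- samples

  ## TF latents; purity loading enters before row standardization
  u <- matrix(rnorm(config$n_tfs * n), config$n_tfs, n,
              dimnames = list(config$tf_names, samples))
  pz <- as.numeric(scale(purity))
  for (tf in names(config$purity_loadings)) {
    u[tf, ] <- u[tf, ] + config$purity_loadings[[tf]] * pz
  }
  u <- t(scale(t(u)))
  tf_expr <- exp(log(50) + u)

  ## methylation
  manifest <- genome$manifest
  beta <- matrix(NA_real_, nrow(manifest), n,
                 dimnames = list(manifest$probe_id, samples))
  tr <- genome$truth
  if (nrow(tr$emcpg)) {
    for (tf in unique(tr$emcpg$tf)) {
      rows <- tr$emcpg$probe_id[tr$emcpg$tf == tf]
      s <- ifelse(tr$emcpg$direction[tr$emcpg$tf == tf][1] == "demethylating",
                  -1, 1)
      m <- length(rows)
      a <- runif(m, -1, 1)
      lin <- a + s * config$effect_slope *
        matrix(u[tf, ], m, n, byrow = TRUE) +
        matrix(rnorm(m * n, 0, config$noise_sd), m, n)
      beta[rows, ] <- stats::plogis(lin)
    }
  }
  if (length(tr$protected)) {
    beta[tr$protected, ] <- rbeta(length(tr$protected) * n,
                                  config$protected_beta_params[1],
                                  config$protected_beta_params[2])
  }
  null_ids <- setdiff(manifest$probe_id, c(tr$emcpg$probe_id, tr$protected))
  if (length(null_ids)) {
    m <- length(null_ids)
    variable <- runif(m) < 0.7  # mixture: IQR above and below the filter
    mv <- sum(variable)
    if (mv) {
      a <- runif(mv, -1.5, 1.5)
      beta[null_ids[variable], ] <- stats::plogis(
        a + matrix(rnorm(mv * n), mv, n))
    }
    mt <- m - mv
    if (mt) {
      mu <- runif(mt, 0.05, 0.95)
      beta[null_ids[!variable], ] <- matrix(
        rbeta(mt * n, rep(mu * 100, n), rep((1 - mu) * 100, n)), mt, n)
    }
  }

  ## gene expression: true targets respond to their CpG's beta on the log
  ## scale (monotone, keeps expression positive); decoys independent
  links <- tr$links
  gene_expr <- NULL
  if (nrow(links)) {
    b_link <- beta[links$probe_id, , drop = FALSE]
    ge <- exp(3 - config$link_slope * b_link +
                matrix(rnorm(nrow(links) * n, 0, config$link_noise_sd),
                       nrow(links), n))
    rownames(ge) <- links$gene_id
    gene_expr <- ge
  }
  decoy_ids <- grep("^DEC", genome$annotation$gene_id, value = TRUE)
  if (length(decoy_ids)) {
    de <- matrix(exp(rnorm(length(decoy_ids) * n, 3, 1)),
                 length(decoy_ids), n,
                 dimnames = list(decoy_ids, samples))
    gene_expr <- rbind(gene_expr, de)
  }
  expression <- rbind(tf_expr, gene_expr)

  ## ATAC counts decrease monotonically with beta at the underlying CpG
  atac_counts <- NULL
  if (nrow(genome$atac_peaks) && config$atac_n_samples >= 1) {
    asamp <- samples[seq_len(min(config$atac_n_samples, n))]
    pb <- beta[genome$atac_peaks$probe_id, asamp, drop = FALSE]
    atac_counts <- round(exp(6 - config$atac_slope * pb +
                               matrix(rnorm(length(pb), 0, config$atac_noise_sd),
                                      nrow(pb), ncol(pb))))
    rownames(atac_counts) <- genome$atac_peaks$peak_id
  }

  cohort <- align_cohort(expression, beta, name = cname)
  list(cohort = cohort, purity = purity, atac_counts = atac_counts,
       truth = c(tr, list(purity = purity,
                          purity_loadings = config$purity_loadings)))
}

#' Write a complete simulated fixture to disk
#'
#' Emits every external-interface format consumed by the pipeline: CpG
#' manifest TSV (1-based positions, Illumina convention), TFBS BED,
#' regulatory-map BED, ATAC peak BED, gene annotation TSV, per-cohort
#' expression/methylation/purity/ATAC TSVs, and a ground-truth TSV with
#' one row per planted emCpG, protected CpG, and true link.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @param force overwrite a non-empty directory.
#' @return named list of written paths, invisibly.
#' @export
write_fixture <- function(config, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop("directory ", dir, " is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(config)
  paths <- list()

  man <- genome$manifest
  man_out <- data.frame(probe_id = man$probe_id, chrom = man$chrom,
                        pos = man$pos + 1L)  # 1-based on disk
  paths$manifest <- file.path(dir, "manifest.tsv")
  write.table(man_out, paths$manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)

  paths$tfbs <- file.path(dir, "tfbs.bed")
  write_bed(data.frame(genome$tfbs$sites[c("chrom", "start", "end")],
                       name = genome$tfbs$sites$tf), paths$tfbs)
  paths$regmap <- file.path(dir, "regmap.bed")
  write_bed(data.frame(genome$regmap[c("chrom", "start", "end")],
                       name = genome$regmap$gene_id), paths$regmap)
  paths$atac_peaks <- file.path(dir, "atac_peaks.bed")
  write_bed(data.frame(genome$atac_peaks[c("chrom", "start", "end")],
                       name = genome$atac_peaks$peak_id), paths$atac_peaks)

  ann <- genome$annotation
  paths$annotation <- file.path(dir, "genes.tsv")
  write.table(ann[c("gene_id", "chrom", "start", "end", "strand", "tss")],
              paths$annotation, sep = "\t", quote = FALSE, row.names = FALSE)

  tr <- genome$truth
  gt <- rbind(
    data.frame(type = "emcpg", probe_id = tr$emcpg$probe_id,
               tf = tr$emcpg$tf, gene_id = NA_character_,
               direction = tr$emcpg$direction),
    if (length(tr$protected))
      data.frame(type = "protected", probe_id = tr$protected,
                 tf = NA_character_, gene_id = NA_character_,
                 direction = NA_character_),
    if (nrow(tr$links))
      data.frame(type = "link", probe_id = tr$links$probe_id,
                 tf = NA_character_, gene_id = tr$links$gene_id,
                 direction = tr$links$source)
  )
  paths$ground_truth <- file.path(dir, "ground_truth.tsv")
  write.table(gt, paths$ground_truth, sep = "\t", quote = FALSE,
              row.names = FALSE)

  for (i in seq_len(config$n_cohorts)) {
    sim <- simulate_cohort(config, genome, i)
    cname <- sim$cohort$name
    paths[[paste0("expression_", cname)]] <-
      write_matrix(signif(sim$cohort$expression, 7),
                   file.path(dir, paste0("expression_", cname, ".tsv")),
                   id_name = "gene_id")
    paths[[paste0("methylation_", cname)]] <-
      write_matrix(round(sim$cohort$methylation, 6),
                   file.path(dir, paste0("methylation_", cname, ".tsv")),
                   id_name = "probe_id")
    pu <- data.frame(sample = names(sim$purity),
                     purity = round(sim$purity, 6))
    paths[[paste0("purity_", cname)]] <- file.path(
      dir, paste0("purity_", cname, ".tsv"))
    write.table(pu, paths[[paste0("purity_", cname)]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(sim$atac_counts)) {
      paths[[paste0("atac_counts_", cname)]] <-
        write_matrix(sim$atac_counts,
                     file.path(dir, paste0("atac_counts_", cname, ".tsv")),
                     id_name = "peak_id")
    }
  }
  invisible(paths)
}
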