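## End-to-end orchestration: stage functions over a shared state list, a
## flat threshold config with the published defaults, TSV outputs, and a
## machine-readable run manifest with checksums.

#' Pipeline configuration with published defaults
#'
#' Every threshold of the screen and its downstream stages, with the
#' defaults used for real-scale cohorts: Bonferroni alpha 0.01, 200 bp
#' proximity window, beta IQR > 0.1, at least 5000 significant CpGs,
#' pooled 95th-percentile fraction cutoff, MWU familywise alpha 0.01,
#' recurrence in >= 2 cohorts, +/-200 bp signature flanks, link alpha
#' 0.01, ORA alpha 0.05, purity p 0.05, and >= 20 matched ATAC samples.
#' For small synthetic universes scale `min_sig` with [scale_min_sig()]
#' and lower `percentile` to match the planted prevalence.
#'
#' @param alpha,window,iqr,min_sig,percentile,mwu_alpha,min_cohorts,flank
#'   screen and calling thresholds.
#' @param link_alpha,ora_alpha,purity_p,atac_min_samples downstream
#'   thresholds.
#' @param max_missing per-CpG missingness tolerance.
#' @param seed RNG seed recorded in the run manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.01, window = 200, iqr = 0.1,
                            min_sig = 5000, percentile = 95,
                            mwu_alpha = 0.01, min_cohorts = 2, flank = 200,
                            link_alpha = 0.01, ora_alpha = 0.05,
                            purity_p = 0.05, atac_min_samples = 20,
                            max_missing = 0.2, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Pipeline thresholds matched to a synthetic universe
#'
#' Scales the data-scale-dependent gates of [pipeline_config()] to a
#' simulated cohort: `min_sig` is scaled to the simulated CpG count with
#' [scale_min_sig()], and the pooled fraction percentile is lowered to
#' leave room for the planted TF-cohort prevalence. The published 95th
#' percentile presumes that well under 5% of TF-cohort pairs carry signal;
#' with `n_planted / n_tfs` planted pairs the cutoff percentile must stay
#' below `100 * (1 - n_planted / n_tfs)`, and a `slack` margin (default 10
#' percentage points) keeps the pooled cutoff clear of the planted
#' fraction distribution.
#'
#' @param sim_cfg a [sim_config()].
#' @param slack percentage-point margin below the prevalence bound.
#' @param ... further overrides passed to [pipeline_config()].
#' @return a [pipeline_config()].
#' @export
synthetic_pipeline_config <- function(sim_cfg, slack = 10, ...) {
  stopifnot(inherits(sim_cfg, "sim_config"))
  pct <- 100 * (1 - sim_cfg$n_planted / sim_cfg$n_tfs) - slack
  pct <- max(5, min(95, pct))
  pipeline_config(min_sig = scale_min_sig(sim_cfg$n_cpgs),
                  percentile = pct, seed = sim_cfg$seed, ...)
}

#' Load pipeline inputs from files
#'
#' Reads the external-interface files (as written by [write_fixture()])
#' into the in-memory objects [run_pipeline()] consumes. Any missing file
#' aborts naming the path.
#'
#' @param dir fixture directory.
#' @param cohorts cohort names (default: inferred from expression files).
#' @return list of pipeline inputs.
#' @export
load_pipeline_inputs <- function(dir, cohorts = NULL) {
  need <- function(p) {
    if (!file.exists(p)) stop("required input file missing: ", p,
                              call. = FALSE)
    p
  }
  if (is.null(cohorts)) {
    cohorts <- sub("^expression_(.*)\\.tsv$", "\\1",
                   basename(Sys.glob(file.path(dir, "expression_*.tsv"))))
    if (!length(cohorts)) stop("no expression_*.tsv files under ", dir,
                               call. = FALSE)
  }
  manifest <- read_manifest(need(file.path(dir, "manifest.tsv")))
  tfbs <- read_bed(need(file.path(dir, "tfbs.bed")), group_by_name = TRUE)
  regmap_path <- file.path(dir, "regmap.bed")
  regmap <- if (file.exists(regmap_path) && length(readLines(regmap_path))) {
    rm <- read_bed(regmap_path)
    names(rm)[names(rm) == "name"] <- "gene_id"
    rm
  } else NULL
  ann_path <- file.path(dir, "genes.tsv")
  annotation <- if (file.exists(ann_path)) read.delim(ann_path,
                                                      stringsAsFactors = FALSE)
                else NULL
  peaks_path <- file.path(dir, "atac_peaks.bed")
  atac_peaks <- if (file.exists(peaks_path) &&
                      length(readLines(peaks_path))) {
    pk <- read_bed(peaks_path)
    names(pk)[names(pk) == "name"] <- "peak_id"
    pk
  } else NULL

  bundles <- list()
  purity <- list()
  atac_counts <- list()
  for (cn in cohorts) {
    expr <- read_matrix(need(file.path(dir, paste0("expression_", cn, ".tsv"))),
                        type = "expression")
    meth <- read_matrix(need(file.path(dir, paste0("methylation_", cn, ".tsv"))),
                        type = "methylation")
    bundles[[cn]] <- align_cohort(expr, meth, name = cn)
    pu_path <- file.path(dir, paste0("purity_", cn, ".tsv"))
    if (file.exists(pu_path)) {
      pu <- read.delim(pu_path, stringsAsFactors = FALSE)
      purity[[cn]] <- setNames(pu$purity, pu$sample)
    }
    ac_path <- file.path(dir, paste0("atac_counts_", cn, ".tsv"))
    if (file.exists(ac_path)) atac_counts[[cn]] <- read_matrix(ac_path)
  }
  list(cohorts = bundles, manifest = manifest, tfbs = tfbs,
       regmap = regmap, annotation = annotation, atac_peaks = atac_peaks,
       purity = purity, atac_counts = atac_counts)
}

#' Screen stage: filter, proximity map, Spearman screen, Bonferroni flags
#'
#' @param inputs list with `cohorts` (named list of [align_cohort()]
#'   bundles), `manifest`, `tfbs`, and optional downstream inputs.
#' @param config a [pipeline_config()].
#' @param tf_list TFs to screen (default: all TFs with binding sites that
#'   are present in every cohort's expression matrix).
#' @return `inputs` extended with `proximity`, `considered` (per cohort)
#'   and `tables` (per-cohort flagged screen tables).
#' @export
stage_screen <- function(inputs, config, tf_list = NULL) {
  if (is.null(tf_list)) {
    tf_list <- tf_names(inputs$tfbs)
    for (b in inputs$cohorts) tf_list <- intersect(tf_list,
                                                   rownames(b$expression))
  }
  inputs$tf_list <- tf_list
  inputs$proximity <- map_cpgs_to_tfbs(inputs$manifest, inputs$tfbs,
                                       window = config$window)
  inputs$considered <- list()
  inputs$tables <- list()
  for (cn in names(inputs$cohorts)) {
    b <- inputs$cohorts[[cn]]
    meth <- drop_missing_cpgs(b$methylation, config$max_missing)
    meth <- iqr_filter(meth, config$iqr)
    considered <- rownames(meth)
    b_f <- b
    b_f$methylation <- meth
    tab <- spearman_screen(b_f, tf_list, considered)
    tab <- bonferroni_flag(tab, alpha = config$alpha,
                           family_size = length(tf_list) * length(considered))
    inputs$considered[[cn]] <- considered
    inputs$tables[[cn]] <- tab
  }
  inputs
}

#' Calling stage: fractions, MWU enrichment, gates, recurrence
#'
#' @param state output of [stage_screen()].
#' @param config a [pipeline_config()].
#' @return state extended with `pair_stats`, `callset`, and `fractions`
#'   (per-cohort [proximal_fraction()] tables).
#' @export
stage_call <- function(state, config) {
  if (is.null(state$tables)) stop("stage_call requires stage_screen output",
                                  call. = FALSE)
  state$fractions <- list()
  rows <- list()
  for (cn in names(state$tables)) {
    tab <- state$tables[[cn]]
    fr <- proximal_fraction(tab, state$proximity)
    state$fractions[[cn]] <- fr
    sig_total <- table(tab$tf[tab$significant])
    for (i in seq_len(nrow(fr))) {
      tf <- fr$tf[i]
      mwu <- mwu_proximity_enrichment(tab, state$proximity, tf)
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, cohort = cn,
        n_sig_total = if (tf %in% names(sig_total))
          as.integer(sig_total[[tf]]) else 0L,
        n_proximal = fr$n_proximal[i], n_proximal_sig = fr$n_proximal_sig[i],
        fraction = fr$fraction[i], mwu_p = mwu$p,
        stringsAsFactors = FALSE)
    }
  }
  stats <- do.call(rbind, rows)
  stats <- select_candidates(stats, percentile = config$percentile,
                             min_sig = config$min_sig,
                             mwu_alpha = config$mwu_alpha)
  state$pair_stats <- stats
  state$callset <- call_emtfs(stats, state$tables, state$proximity,
                              min_cohorts = config$min_cohorts)
  state
}

#' Sign-partition stage
#' @param state output of [stage_call()].
#' @return state extended with `sign_summary` (per emTF-cohort
#'   negative/positive emCpG proportions).
#' @export
stage_partition <- function(state) {
  if (is.null(state$callset)) stop("stage_partition requires stage_call output",
                                   call. = FALSE)
  rows <- list()
  for (tf in state$callset$emtfs) {
    for (cn in names(state$callset$emcpgs[[tf]])) {
      fr <- state$fractions[[cn]]
      n_prox <- fr$n_proximal[fr$tf == tf]
      if (!length(n_prox)) next
      part <- partition_sign(state$callset$emcpgs[[tf]][[cn]], n_prox)
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, cohort = cn, n_proximal = n_prox,
        n_negative = length(part$negative), n_positive = length(part$positive),
        prop_negative = part$prop_negative, prop_positive = part$prop_positive,
        stringsAsFactors = FALSE)
    }
  }
  state$sign_summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(0), cohort = character(0),
               n_proximal = integer(0), n_negative = integer(0),
               n_positive = integer(0), prop_negative = numeric(0),
               prop_positive = numeric(0))
  state
}

#' Signature stage: emCpG vs non-correlated CpG flank enrichment
#'
#' For every called (emTF, cohort) pair, contrasts the +/-flank windows of
#' the emCpGs against those of the non-correlated proximal CpGs (both
#' directions) over all TFBS sets.
#'
#' @param state output of [stage_call()].
#' @param config a [pipeline_config()].
#' @return state extended with `signatures` (TF -> cohort -> list of
#'   `emcpg_fg` and `noncor_fg` enrichment tables).
#' @export
stage_signatures <- function(state, config) {
  if (is.null(state$callset)) stop("stage_signatures requires stage_call output",
                                   call. = FALSE)
  state$signatures <- list()
  for (tf in state$callset$emtfs) {
    for (cn in names(state$callset$emcpgs[[tf]])) {
      em_ids <- state$callset$emcpgs[[tf]][[cn]]$probe_id
      prox <- intersect(state$proximity[[tf]], state$considered[[cn]])
      noncor <- setdiff(prox, em_ids)
      if (!length(em_ids) || !length(noncor)) next
      fg <- window_regions(em_ids, state$manifest, flank = config$flank)
      bg <- window_regions(noncor, state$manifest, flank = config$flank)
      key <- function(df) paste(df$chrom, df$start, df$end)
      bg <- bg[!(key(bg) %in% key(fg)), , drop = FALSE]
      state$signatures[[tf]][[cn]] <- list(
        emcpg_fg = differential_tfbs_enrichment(fg, bg, state$tfbs),
        noncor_fg = differential_tfbs_enrichment(bg, fg, state$tfbs))
    }
  }
  state
}

#' Linking stage: CpG-to-gene links with the anti-correlation filter
#' @param state output of [stage_call()].
#' @param config a [pipeline_config()].
#' @return state extended with `links` (TF -> cohort -> filtered link
#'   table); skipped (with a message) when annotation is absent.
#' @export
stage_link <- function(state, config) {
  if (is.null(state$callset)) stop("stage_link requires stage_call output",
                                   call. = FALSE)
  if (is.null(state$annotation)) {
    message("stage_link: no gene annotation supplied; stage skipped")
    return(state)
  }
  state$links <- list()
  for (tf in state$callset$emtfs) {
    for (cn in names(state$callset$emcpgs[[tf]])) {
      em_ids <- state$callset$emcpgs[[tf]][[cn]]$probe_id
      if (!length(em_ids)) next
      lk <- link_cpgs(em_ids, state$manifest, state$regmap, state$annotation)
      lk <- anticorrelation_filter(lk, state$cohorts[[cn]],
                                   alpha = config$link_alpha)
      state$links[[tf]][[cn]] <- lk
    }
  }
  state
}

#' Context stage: purity classification and ATAC-methylation coupling
#' @param state output of [stage_call()].
#' @param config a [pipeline_config()].
#' @return state extended with `purity_calls` and `atac` (per cohort).
#' @export
stage_context <- function(state, config) {
  if (is.null(state$callset)) stop("stage_context requires stage_call output",
                                   call. = FALSE)
  state$purity_calls <- list()
  state$atac <- list()
  for (cn in names(state$cohorts)) {
    if (!is.null(state$purity[[cn]]) && length(state$callset$emtfs)) {
      state$purity_calls[[cn]] <- purity_classification(
        state$cohorts[[cn]]$expression, state$purity[[cn]],
        tfs = state$callset$emtfs, p_threshold = config$purity_p)
    }
    if (!is.null(state$atac_counts[[cn]]) && !is.null(state$atac_peaks)) {
      em_all <- unique(unlist(lapply(state$callset$emcpgs, function(x)
        x[[cn]]$probe_id), use.names = FALSE))
      if (length(em_all)) {
        state$atac[[cn]] <- atac_methylation_correlation(
          em_all, state$manifest, state$atac_peaks,
          state$atac_counts[[cn]], state$cohorts[[cn]]$methylation,
          flank = config$flank, min_samples = config$atac_min_samples)
      }
    }
  }
  state
}

#' Report stage: summary TSVs and a checksummed run manifest
#'
#' Writes the per-pair selection statistics (the fraction table), the
#' emQTL table restricted to significant pairs, the sign-proportion
#' summary, link tables, purity calls, ATAC correlations, and a
#' `run_manifest.json` carrying the config, seed, and md5 checksum of
#' every emitted file. Output is a deterministic function of inputs and
#' seed.
#'
#' @param state pipeline state after the analysis stages.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return state with `out_dir` and `run_manifest` recorded.
#' @export
stage_report <- function(state, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    name
  }
  files <- character(0)
  files <- c(files, wt(state$pair_stats, "pair_stats.tsv"))
  sig <- do.call(rbind, lapply(names(state$tables), function(cn) {
    tab <- state$tables[[cn]][state$tables[[cn]]$significant, , drop = FALSE]
    if (!nrow(tab)) return(NULL)
    data.frame(cohort = cn, tab, stringsAsFactors = FALSE)
  }))
  if (is.null(sig)) sig <- data.frame(cohort = character(0), tf = character(0),
                                      probe_id = character(0), rho = numeric(0),
                                      p_raw = numeric(0), n = integer(0),
                                      significant = logical(0))
  files <- c(files, wt(sig, "emqtl_significant.tsv"))
  files <- c(files, wt(data.frame(tf = state$callset$emtfs), "emtfs.tsv"))
  files <- c(files, wt(state$sign_summary, "sign_summary.tsv"))
  if (!is.null(state$links)) {
    lk <- do.call(rbind, lapply(names(state$links), function(tf)
      do.call(rbind, lapply(names(state$links[[tf]]), function(cn)
        data.frame(tf = tf, cohort = cn, state$links[[tf]][[cn]],
                   stringsAsFactors = FALSE)))))
    if (!is.null(lk)) files <- c(files, wt(lk, "links.tsv"))
  }
  if (length(state$purity_calls)) {
    pc <- do.call(rbind, lapply(names(state$purity_calls), function(cn)
      data.frame(cohort = cn, state$purity_calls[[cn]],
                 stringsAsFactors = FALSE)))
    files <- c(files, wt(pc, "purity_calls.tsv"))
  }
  if (length(state$atac)) {
    at <- do.call(rbind, lapply(names(state$atac), function(cn) {
      x <- state$atac[[cn]]
      if (is.null(x) || !nrow(x)) return(NULL)
      data.frame(cohort = cn, x, stringsAsFactors = FALSE)
    }))
    if (!is.null(at)) files <- c(files, wt(at, "atac_correlations.tsv"))
  }
  if (!is.null(state$signatures)) {
    sg <- do.call(rbind, lapply(names(state$signatures), function(tf)
      do.call(rbind, lapply(names(state$signatures[[tf]]), function(cn)
        rbind(data.frame(tf = tf, cohort = cn, foreground = "emcpg",
                         state$signatures[[tf]][[cn]]$emcpg_fg),
              data.frame(tf = tf, cohort = cn, foreground = "noncorrelated",
                         state$signatures[[tf]][[cn]]$noncor_fg))))))
    if (!is.null(sg)) files <- c(files, wt(sg, "signature_enrichment.tsv"))
  }

  cfg_path <- file.path(out_dir, "config.json")
  cfg <- unclass(config)
  jsonlite::write_json(cfg[order(names(cfg))], cfg_path, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, "config.json")
  sums <- tools::md5sum(file.path(out_dir, sort(files)))
  manifest <- list(seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   files = as.list(setNames(unname(sums), sort(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  state$out_dir <- out_dir
  state$run_manifest <- manifest
  state
}

#' Run the full emTF-calling pipeline
#'
#' Executes filter, proximity, screen, calling, sign partition,
#' signatures, linking, context and report stages in order. Each stage is
#' also callable standalone on the previous stage's state.
#'
#' @param inputs list with `cohorts` (named list of [align_cohort()]
#'   bundles), `manifest`, `tfbs`, and optional `annotation`, `regmap`,
#'   `purity` (named vectors per cohort), `atac_peaks`, `atac_counts`
#'   (matrices per cohort) — as built by [load_pipeline_inputs()] or from
#'   [simulate_cohort()] objects.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for TSVs and the run manifest.
#' @return final pipeline state list.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir = NULL) {
  state <- stage_screen(inputs, config)
  state <- stage_call(state, config)
  state <- stage_partition(state)
  state <- stage_signatures(state, config)
  state <- stage_link(state, config)
  state <- stage_context(state, config)
  if (!is.null(out_dir)) state <- stage_report(state, config, out_dir)
  state
}

#' Assemble pipeline inputs from simulator objects
#'
#' @param config a [sim_config()].
#' @param genome optional pre-built [simulate_genome()] output.
#' @return inputs list for [run_pipeline()], with the per-cohort ground
#'   truth under `truth`.
#' @export
simulate_pipeline_inputs <- function(config, genome = NULL) {
  if (is.null(genome)) genome <- simulate_genome(config)
  cohorts <- list()
  purity <- list()
  atac_counts <- list()
  for (i in seq_len(config$n_cohorts)) {
    sim <- simulate_cohort(config, genome, i)
    cohorts[[sim$cohort$name]] <- sim$cohort
    purity[[sim$cohort$name]] <- sim$purity
    atac_counts[[sim$cohort$name]] <- sim$atac_counts
  }
  list(cohorts = cohorts, manifest = genome$manifest, tfbs = genome$tfbs,
       annotation = genome$annotation, regmap = genome$regmap,
       atac_peaks = genome$atac_peaks, purity = purity,
       atac_counts = atac_counts, truth = genome$truth)
}
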