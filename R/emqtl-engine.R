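## The emQTL screen and emTF selection cascade:
## IQR filter -> TFBS proximity map -> Spearman screen -> Bonferroni ->
## proximal fraction -> pooled-percentile gate -> MWU enrichment gate ->
## cross-cohort recurrence -> sign partition.

#' Filter CpGs by methylation variability
#'
#' Retains CpGs whose beta-value interquartile range across samples is
#' strictly greater than `threshold`. Quartiles use linear-interpolation
#' (type-7) quantiles.
#'
#' @param methylation CpG-by-sample beta matrix.
#' @param threshold IQR cutoff (default 0.1).
#' @return the filtered matrix (possibly zero rows, with a warning).
#' @export
iqr_filter <- function(methylation, threshold = 0.1) {
  stopifnot(is.matrix(methylation))
  iqr <- apply(methylation, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) return(0)
    q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
    q[2L] - q[1L]
  })
  keep <- iqr > threshold
  if (!any(keep)) warning("iqr_filter removed every CpG", call. = FALSE)
  methylation[keep, , drop = FALSE]
}

#' Map CpGs to TFs by binding-site proximity
#'
#' A CpG at position q is proximal to a TF when its distance to the nearest
#' binding site of that TF is at most `window` bp; the distance is 0 inside
#' \[start, end) and otherwise the gap to the nearest covered base.
#'
#' @param manifest CpG manifest data.frame (`probe_id`, `chrom`, `pos`,
#'   0-based).
#' @param tfbs a [tfbs_collection()].
#' @param window proximity window in bp (default 200).
#' @return named list: TF -> character vector of proximal probe IDs. TFs
#'   with no sites or no proximal CpGs map to empty vectors.
#' @export
map_cpgs_to_tfbs <- function(manifest, tfbs, window = 200) {
  stopifnot(inherits(tfbs, "tfbs_collection"))
  cpg_gr <- cpg_to_gr(manifest)
  padded <- intervals_to_gr(tfbs$sites, pad = as.integer(window))
  hits <- GenomicRanges::findOverlaps(cpg_gr, padded)
  tf_of_hit <- tfbs$sites$tf[S4Vectors::subjectHits(hits)]
  probe_of_hit <- manifest$probe_id[S4Vectors::queryHits(hits)]
  out <- lapply(split(probe_of_hit, tf_of_hit), function(p) sort(unique(p)))
  # TFs without any proximal CpG still appear, with an empty set
  missing_tfs <- setdiff(tf_names(tfbs), names(out))
  out[missing_tfs] <- list(character(0))
  out[order(names(out))]
}

#' Spearman expression-methylation screen
#'
#' Computes the Spearman correlation and two-sided t-approximation p-value
#' between every requested TF's expression and every requested CpG's
#' methylation across the cohort's paired samples.
#'
#' @param cohort a [align_cohort()] bundle.
#' @param tf_list TFs to test (must be rows of the expression matrix).
#' @param cpg_list CpGs to test (rows of the methylation matrix, normally
#'   after [iqr_filter()]).
#' @return data.frame (`tf`, `probe_id`, `rho`, `p_raw`, `n`) — one row per
#'   pair, CpGs nested within TFs; undefined pairs carry `NA`.
#' @export
spearman_screen <- function(cohort, tf_list = rownames(cohort$expression),
                            cpg_list = rownames(cohort$methylation)) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  missing_tf <- setdiff(tf_list, rownames(cohort$expression))
  if (length(missing_tf)) {
    stop("TFs missing from expression matrix: ",
         paste(missing_tf, collapse = ", "), call. = FALSE)
  }
  missing_cpg <- setdiff(cpg_list, rownames(cohort$methylation))
  if (length(missing_cpg)) {
    stop("CpGs missing from methylation matrix: ",
         paste(head(missing_cpg, 5), collapse = ", "), call. = FALSE)
  }
  expr <- cohort$expression[tf_list, , drop = FALSE]
  meth <- cohort$methylation[cpg_list, , drop = FALSE]
  k <- spearman_screen_matrix(expr, meth)
  data.frame(
    tf = rep(tf_list, each = length(cpg_list)),
    probe_id = rep(cpg_list, times = length(tf_list)),
    rho = as.vector(t(k$rho)),
    p_raw = as.vector(t(k$p)),
    n = as.vector(t(k$n)),
    stringsAsFactors = FALSE
  )
}

#' Flag Bonferroni-significant emQTL pairs
#'
#' Marks a pair significant when `p_raw < alpha / family_size`. The default
#' family is the full TF-by-CpG grid tested in the cohort (the most
#' conservative reading); pass `family_size` explicitly for a per-TF family.
#'
#' @param table screen output from [spearman_screen()].
#' @param alpha family-wise error target (default 0.01).
#' @param family_size number of tests in the Bonferroni family; defaults to
#'   `nrow(table)`.
#' @return `table` with a logical `significant` column (`NA` p => FALSE).
#' @export
bonferroni_flag <- function(table, alpha = 0.01, family_size = nrow(table)) {
  if (is.null(family_size) || family_size <= 0) {
    stop("family_size must be positive", call. = FALSE)
  }
  table$significant <- !is.na(table$p_raw) & table$p_raw < alpha / family_size
  table
}

#' Fraction of a TF's proximal CpGs in emQTL with the TF itself
#'
#' @param table flagged screen table ([bonferroni_flag()]).
#' @param proximity named list from [map_cpgs_to_tfbs()].
#' @return data.frame (`tf`, `n_proximal`, `n_proximal_sig`, `fraction`);
#'   TFs with zero proximal CpGs among the tested set are excluded (with a
#'   message).
#' @export
proximal_fraction <- function(table, proximity) {
  tested <- unique(table$probe_id)
  sig_by_tf <- split(table$probe_id[table$significant], table$tf[table$significant])
  tfs <- intersect(names(proximity), unique(table$tf))
  rows <- lapply(tfs, function(tf) {
    prox <- intersect(proximity[[tf]], tested)
    if (!length(prox)) return(NULL)
    nsig <- length(intersect(prox, sig_by_tf[[tf]]))
    data.frame(tf = tf, n_proximal = length(prox), n_proximal_sig = nsig,
               fraction = nsig / length(prox), stringsAsFactors = FALSE)
  })
  dropped <- tfs[vapply(rows, is.null, TRUE)]
  if (length(dropped)) {
    message("proximal_fraction: no tested proximal CpGs for ",
            length(dropped), " TF(s): ",
            paste(head(dropped, 5), collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf = character(0), n_proximal = integer(0),
                      n_proximal_sig = integer(0), fraction = numeric(0))
  }
  out[order(out$tf), , drop = FALSE]
}

#' Mann-Whitney enrichment of correlation strength near a TF's sites
#'
#' Tests whether |rho| values of the TF's proximal CpGs are stochastically
#' greater than |rho| of all other considered CpGs in the cohort (the
#' non-proximal complement of the universe).
#'
#' @param table flagged screen table for one cohort.
#' @param proximity named list from [map_cpgs_to_tfbs()].
#' @param tf TF name.
#' @return list with `U`, `p` (one-sided), `n_proximal`, `n_other`; `p` is
#'   `NA` when either group is empty.
#' @export
mwu_proximity_enrichment <- function(table, proximity, tf) {
  sub <- table[table$tf == tf & !is.na(table$rho), , drop = FALSE]
  prox_ids <- proximity[[tf]]
  is_prox <- sub$probe_id %in% prox_ids
  x <- abs(sub$rho[is_prox])
  y <- abs(sub$rho[!is_prox])
  if (!length(x) || !length(y)) {
    return(list(U = NA_real_, p = NA_real_,
                n_proximal = length(x), n_other = length(y)))
  }
  res <- mwu_greater(x, y)
  list(U = res$U, p = res$p, n_proximal = length(x), n_other = length(y))
}

#' Per-cohort candidate TF selection
#'
#' Applies the three selection gates to every TF-cohort pair:
#' (1) at least `min_sig` Bonferroni-significant CpGs anywhere in the
#' cohort; (2) proximal-CpG fraction at or above the pooled
#' `percentile`-th type-7 quantile of all TF-cohort fractions; (3)
#' Bonferroni-corrected (across tested pairs) MWU enrichment p below
#' `mwu_alpha`.
#'
#' @param stats data.frame with one row per TF-cohort pair and columns
#'   `tf`, `cohort`, `n_sig_total`, `fraction`, `mwu_p`.
#' @param percentile pooled fraction percentile in (0, 100) (default 95).
#' @param min_sig minimum significant CpG count (default 5000; scale for
#'   synthetic cohorts with [scale_min_sig()]).
#' @param mwu_alpha MWU familywise alpha (default 0.01).
#' @return `stats` with `fraction_cutoff`, `passed_min_sig`,
#'   `passed_percentile`, `passed_mwu`, `candidate` columns.
#' @export
select_candidates <- function(stats, percentile = 95, min_sig = 5000,
                              mwu_alpha = 0.01) {
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must lie strictly between 0 and 100", call. = FALSE)
  }
  cutoff <- quantile(stats$fraction, percentile / 100, names = FALSE, type = 7)
  n_pairs <- sum(!is.na(stats$mwu_p))
  stats$fraction_cutoff <- cutoff
  stats$passed_min_sig <- stats$n_sig_total >= min_sig
  stats$passed_percentile <- stats$fraction >= cutoff
  stats$mwu_p_adj <- pmin(1, stats$mwu_p * n_pairs)
  stats$passed_mwu <- !is.na(stats$mwu_p) & stats$mwu_p_adj < mwu_alpha
  stats$candidate <- stats$passed_min_sig & stats$passed_percentile &
    stats$passed_mwu
  stats
}

#' Scale the minimum-significant-CpG gate to a smaller CpG universe
#'
#' The 5000-CpG rule is stated for a 376,997-CpG array universe; synthetic
#' cohorts use the same proportion of their own universe.
#'
#' @param n_cpgs number of CpGs in the universe.
#' @param real_min_sig,real_n_cpgs the reference rule.
#' @return scaled integer threshold (at least 1).
#' @export
scale_min_sig <- function(n_cpgs, real_min_sig = 5000, real_n_cpgs = 376997) {
  max(1L, as.integer(round(real_min_sig * n_cpgs / real_n_cpgs)))
}

#' Call emTFs by cross-cohort recurrence
#'
#' A TF is an emTF when it is a selected candidate in at least
#' `min_cohorts` cohorts. emCpGs per (TF, cohort) are the
#' Bonferroni-significant CpGs proximal to that TF's sites in that cohort.
#'
#' @param candidates data.frame from [select_candidates()] covering all
#'   cohorts (columns `tf`, `cohort`, `candidate`, ...).
#' @param tables named list (cohort -> flagged screen table).
#' @param proximity named list from [map_cpgs_to_tfbs()].
#' @param min_cohorts recurrence threshold (default 2).
#' @return list of class `emtf_callset` with `stats` (the candidate table),
#'   `emtfs` (character), `emcpgs` (list: TF -> cohort -> data.frame
#'   `probe_id`, `rho`).
#' @export
call_emtfs <- function(candidates, tables, proximity, min_cohorts = 2) {
  n_cohorts <- length(unique(candidates$cohort))
  if (n_cohorts < min_cohorts) {
    warning("only ", n_cohorts, " cohort(s) analysed but min_cohorts = ",
            min_cohorts, "; emTF set is empty", call. = FALSE)
  }
  tally <- table(candidates$tf[candidates$candidate])
  emtfs <- sort(names(tally)[tally >= min_cohorts])
  emcpgs <- lapply(setNames(emtfs, emtfs), function(tf) {
    lapply(tables, function(tab) {
      sub <- tab[tab$tf == tf & tab$significant &
                   tab$probe_id %in% proximity[[tf]], , drop = FALSE]
      sub <- sub[order(sub$probe_id), c("probe_id", "rho")]
      rownames(sub) <- NULL
      sub
    })
  })
  structure(list(stats = candidates, emtfs = emtfs, emcpgs = emcpgs,
                 min_cohorts = min_cohorts),
            class = "emtf_callset")
}

#' @export
print.emtf_callset <- function(x, ...) {
  cat("emtf_callset:", length(x$emtfs), "emTF(s)",
      if (length(x$emtfs)) paste0("(", paste(x$emtfs, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Partition emCpGs by correlation sign
#'
#' Splits a (TF, cohort) emCpG set into negatively and positively
#' correlated subsets, with proportions expressed relative to all proximal
#' CpGs of the TF considered in the cohort.
#'
#' @param emcpg data.frame (`probe_id`, `rho`) for one TF-cohort pair.
#' @param n_proximal number of considered CpGs proximal to the TF.
#' @return list with `negative`, `positive` (probe ID vectors),
#'   `prop_negative`, `prop_positive` (fractions of `n_proximal`).
#' @export
partition_sign <- function(emcpg, n_proximal) {
  stopifnot(n_proximal >= nrow(emcpg))
  # rho == 0 cannot reach Bonferroni significance; guarded anyway
  neg <- emcpg$probe_id[emcpg$rho < 0]
  pos <- emcpg$probe_id[emcpg$rho > 0]
  list(negative = neg, positive = pos,
       prop_negative = length(neg) / n_proximal,
       prop_positive = length(pos) / n_proximal)
}
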