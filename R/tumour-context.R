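## Cellular-context stages: tumour-purity classification of TFs and
## ATAC-methylation anti-correlation at emCpGs.

#' Classify TFs by tumour-purity correlation
#'
#' Pearson correlation between each TF's expression and per-sample tumour
#' purity. A TF is `cancer_cell` when r > 0 and p < `p_threshold`,
#' `microenvironment` when r < 0 and p < `p_threshold`, otherwise
#' `ambiguous` (including undefined correlations).
#'
#' @param expression gene/TF-by-sample matrix.
#' @param purity named numeric vector (sample -> purity in \[0, 1\]).
#' @param tfs TFs to classify (default: all expression rows).
#' @param p_threshold two-sided p cutoff (default 0.05).
#' @return data.frame (`tf`, `pearson_r`, `p`, `n`, `class`).
#' @export
purity_classification <- function(expression, purity,
                                  tfs = rownames(expression),
                                  p_threshold = 0.05) {
  samples <- intersect(colnames(expression), names(purity))
  if (length(samples) < 3L) {
    stop("fewer than 3 samples with both expression and purity",
         call. = FALSE)
  }
  pu <- purity[samples]
  rows <- lapply(tfs, function(tf) {
    x <- expression[tf, samples]
    ok <- complete.cases(x, pu)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(pu[ok]) == 0) {
      return(data.frame(tf = tf, pearson_r = NA_real_, p = NA_real_,
                        n = sum(ok), class = "ambiguous",
                        stringsAsFactors = FALSE))
    }
    ct <- cor.test(x[ok], pu[ok], method = "pearson")
    cls <- if (!is.na(ct$p.value) && ct$p.value < p_threshold) {
      if (ct$estimate > 0) "cancer_cell" else "microenvironment"
    } else "ambiguous"
    data.frame(tf = tf, pearson_r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation between ATAC signal and methylation at emCpGs
#'
#' Intersects the +/- `flank` bp windows of the emCpGs with ATAC peaks and
#' computes, for every (CpG, overlapping peak) pair, the Spearman
#' correlation between the CpG's beta values and the peak's normalized
#' counts across matched samples. A CpG overlapped by several peaks yields
#' one correlation per peak.
#'
#' @param probe_ids emCpGs to test.
#' @param manifest CpG manifest.
#' @param peaks ATAC peak interval data.frame with a `peak_id` column
#'   matching `counts` row names.
#' @param counts peak-by-sample ATAC count matrix.
#' @param methylation CpG-by-sample beta matrix.
#' @param flank window half-width (default 200).
#' @param min_samples minimum matched samples; fewer aborts the cohort with
#'   `NULL` (and a message).
#' @return data.frame (`probe_id`, `peak_id`, `rho`, `p`, `n`) plus a
#'   `median_rho` attribute, or `NULL` when the sample gate fails; zero
#'   rows when no peak overlaps any window.
#' @export
atac_methylation_correlation <- function(probe_ids, manifest, peaks, counts,
                                         methylation, flank = 200,
                                         min_samples = 20) {
  samples <- intersect(colnames(counts), colnames(methylation))
  if (length(samples) < min_samples) {
    message("atac_methylation_correlation: only ", length(samples),
            " matched sample(s) (< ", min_samples, "); cohort skipped")
    return(NULL)
  }
  win <- window_regions(probe_ids, manifest, flank = flank)
  hits <- GenomicRanges::findOverlaps(intervals_to_gr(win),
                                      intervals_to_gr(peaks))
  if (!length(hits)) {
    message("atac_methylation_correlation: no ATAC peak overlaps any window")
    return(data.frame(probe_id = character(0), peak_id = character(0),
                      rho = numeric(0), p = numeric(0), n = integer(0)))
  }
  pairs <- data.frame(probe_id = win$name[S4Vectors::queryHits(hits)],
                      peak_id = peaks$peak_id[S4Vectors::subjectHits(hits)],
                      stringsAsFactors = FALSE)
  pairs <- pairs[pairs$probe_id %in% rownames(methylation) &
                   pairs$peak_id %in% rownames(counts), , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    spearman_test(methylation[pairs$probe_id[i], samples],
                  counts[pairs$peak_id[i], samples])
  })
  pairs$rho <- vapply(res, `[[`, numeric(1), "rho")
  pairs$p <- vapply(res, `[[`, numeric(1), "p")
  pairs$n <- vapply(res, `[[`, numeric(1), "n")
  attr(pairs, "median_rho") <- stats::median(pairs$rho, na.rm = TRUE)
  pairs
}
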