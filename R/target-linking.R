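## Linking emCpGs to candidate target genes (regulatory-element map with a
## nearest-TSS fallback), refinement by methylation-expression
## anti-correlation, and basic over-representation analysis.

#' Link CpGs to candidate target genes
#'
#' A CpG lying inside one or more regulatory elements is linked to every
#' target gene of those elements (source `regulatory_map`); a CpG outside
#' all elements is linked to the gene with the nearest TSS (source
#' `nearest_tss`; ties broken by the lexicographically smallest gene ID,
#' with all tied candidates reported in `tie_with`).
#'
#' @param probe_ids CpGs to link.
#' @param manifest CpG manifest.
#' @param regmap regulatory map data.frame (`chrom`, `start`, `end`,
#'   `gene_id`) or `NULL` to force nearest-TSS linking throughout.
#' @param annotation gene annotation (`gene_id`, `chrom`, `tss`, ...).
#' @return data.frame (`probe_id`, `gene_id`, `source`, `tie_with`); every
#'   CpG receives at least one link.
#' @export
link_cpgs <- function(probe_ids, manifest, regmap, annotation) {
  if (is.null(annotation) || !nrow(annotation)) {
    stop("gene annotation is empty", call. = FALSE)
  }
  idx <- match(probe_ids, manifest$probe_id)
  stopifnot(!anyNA(idx))
  m <- manifest[idx, , drop = FALSE]

  links <- NULL
  linked <- character(0)
  if (!is.null(regmap) && nrow(regmap)) {
    cpg_gr <- cpg_to_gr(m)
    el_gr <- intervals_to_gr(regmap)
    hits <- GenomicRanges::findOverlaps(cpg_gr, el_gr)
    if (length(hits)) {
      links <- unique(data.frame(
        probe_id = m$probe_id[S4Vectors::queryHits(hits)],
        gene_id = regmap$gene_id[S4Vectors::subjectHits(hits)],
        source = "regulatory_map", tie_with = NA_character_,
        stringsAsFactors = FALSE))
      linked <- unique(links$probe_id)
    }
  }

  rest <- m[!(m$probe_id %in% linked), , drop = FALSE]
  if (nrow(rest)) {
    near <- lapply(seq_len(nrow(rest)), function(i) {
      same <- annotation[annotation$chrom == rest$chrom[i], , drop = FALSE]
      if (!nrow(same)) same <- annotation  # no same-chrom gene: global fallback
      d <- abs(rest$pos[i] - same$tss)
      cand <- sort(same$gene_id[d == min(d)])
      data.frame(probe_id = rest$probe_id[i], gene_id = cand[1],
                 source = "nearest_tss",
                 tie_with = if (length(cand) > 1)
                   paste(cand[-1], collapse = ",") else NA_character_,
                 stringsAsFactors = FALSE)
    })
    links <- rbind(links, do.call(rbind, near))
  }
  rownames(links) <- NULL
  links[order(links$probe_id, links$gene_id), , drop = FALSE]
}

#' Summarize the per-source split of a link table
#' @param links output of [link_cpgs()].
#' @return data.frame with per-source CpG counts and percentages.
#' @export
link_source_summary <- function(links) {
  per_cpg <- tapply(links$source, links$probe_id,
                    function(s) if ("regulatory_map" %in% s)
                      "regulatory_map" else "nearest_tss")
  tab <- table(factor(per_cpg, levels = c("regulatory_map", "nearest_tss")))
  data.frame(source = names(tab), n_cpgs = as.integer(tab),
             percent = 100 * as.integer(tab) / sum(tab))
}

#' Refine links by methylation-expression anti-correlation
#'
#' Computes the Spearman correlation between each linked CpG's methylation
#' and its candidate gene's expression across cohort samples; a link is
#' retained iff rho < 0 and the Bonferroni-adjusted p (family = number of
#' links tested) is below `alpha`.
#'
#' @param links link table from [link_cpgs()].
#' @param cohort a [align_cohort()] bundle containing the linked genes'
#'   expression and the CpGs' methylation.
#' @param alpha familywise alpha (default 0.01).
#' @param method "spearman" (default) or "pearson".
#' @return `links` with `rho`, `p_raw`, `n`, `retained` columns; links to
#'   genes absent from the expression matrix are dropped with a message.
#' @export
anticorrelation_filter <- function(links, cohort, alpha = 0.01,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  have_gene <- links$gene_id %in% rownames(cohort$expression)
  have_cpg <- links$probe_id %in% rownames(cohort$methylation)
  dropped <- sum(!(have_gene & have_cpg))
  if (dropped) {
    message("anticorrelation_filter: dropped ", dropped,
            " link(s) with gene or CpG absent from the cohort")
  }
  links <- links[have_gene & have_cpg, , drop = FALSE]
  n_tests <- nrow(links)
  res <- lapply(seq_len(n_tests), function(i) {
    x <- cohort$methylation[links$probe_id[i], ]
    y <- cohort$expression[links$gene_id[i], ]
    if (method == "spearman") {
      spearman_test(x, y)
    } else {
      ok <- complete.cases(x, y)
      if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
        list(rho = NA_real_, p = NA_real_, n = sum(ok))
      } else {
        ct <- cor.test(x[ok], y[ok], method = "pearson")
        list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
      }
    }
  })
  links$rho <- vapply(res, `[[`, numeric(1), "rho")
  links$p_raw <- vapply(res, `[[`, numeric(1), "p")
  links$n <- vapply(res, `[[`, numeric(1), "n")
  links$retained <- !is.na(links$rho) & links$rho < 0 &
    links$p_raw * n_tests < alpha
  links
}

#' Read gene sets in GMT format
#' @param path GMT file (set name, description, member genes per line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("GMT parse error at line ", bad[1],
         ": need name, description and at least one gene", call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the one-sided hypergeometric tail for the overlap
#' with the query, BH-adjusted across sets; reports sets with adjusted
#' p < `alpha`, at most `top_k`, ranked by adjusted then raw p.
#'
#' @param genes query gene list (subset of `universe`).
#' @param gene_sets named list of gene vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all eligible genes.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param top_k report at most this many sets (default 10).
#' @return data.frame (`set`, `overlap`, `set_size`, `query_size`,
#'   `p_raw`, `p_adjusted`); zero rows for an empty query.
#' @export
over_representation <- function(genes, gene_sets, universe, alpha = 0.05,
                                top_k = 10) {
  genes <- unique(genes)
  universe <- unique(universe)
  stopifnot(all(genes %in% universe))
  if (!length(genes) || !length(gene_sets)) {
    return(data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      p_raw = numeric(0), p_adjusted = numeric(0)))
  }
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(genes, s))
    p <- hyper_tail(k, marked = length(s), universe = length(universe),
                    draws = length(genes))
    data.frame(set = nm, overlap = k, set_size = length(s),
               query_size = length(genes), p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_raw, method = "BH")
  out <- out[out$p_adjusted < alpha, , drop = FALSE]
  out <- out[order(out$p_adjusted, out$p_raw, out$set), , drop = FALSE]
  head(out, top_k)
}
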