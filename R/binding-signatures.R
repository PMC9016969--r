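## Characterization of CpG flanking regions: window construction, GC
## content, two-set differential TFBS enrichment (emCpGs vs non-correlated
## CpGs), genomic-context annotation, and TF-list overlap tests.

#' Build flanking windows around CpGs
#'
#' Each CpG at position q yields the region \[q - flank, q + flank + 1),
#' clipped at chromosome bounds; regions are deduplicated by coordinates.
#'
#' @param probe_ids CpGs to window.
#' @param manifest CpG manifest (`probe_id`, `chrom`, `pos`, 0-based).
#' @param flank half-width in bp (default 200; full width 2*flank + 1).
#' @param chrom_sizes optional named vector of chromosome lengths for
#'   right-clipping.
#' @return interval data.frame (`chrom`, `start`, `end`, `name` = probe).
#' @export
window_regions <- function(probe_ids, manifest, flank = 200,
                           chrom_sizes = NULL) {
  idx <- match(probe_ids, manifest$probe_id)
  if (anyNA(idx)) {
    stop("unknown probe ID(s): ",
         paste(head(probe_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  m <- manifest[idx, , drop = FALSE]
  start <- pmax(0L, m$pos - as.integer(flank))
  end <- m$pos + as.integer(flank) + 1L
  if (!is.null(chrom_sizes)) {
    end <- pmin(end, as.integer(chrom_sizes[m$chrom]))
  }
  df <- data.frame(chrom = m$chrom, start = start, end = end,
                   name = m$probe_id, stringsAsFactors = FALSE)
  df[!duplicated(df[c("chrom", "start", "end")]), , drop = FALSE]
}

#' GC content of regions from a FASTA sequence set
#'
#' Fraction (G + C) / region length, case-insensitive; ambiguous bases (N)
#' count only in the denominator.
#'
#' @param regions interval data.frame.
#' @param fasta path to a FASTA file or a [Biostrings::DNAStringSet].
#' @return numeric vector of per-region GC fractions.
#' @export
gc_content <- function(regions, fasta) {
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing <- setdiff(unique(regions$chrom), names(seqs))
  if (length(missing)) {
    stop("contigs absent from FASTA: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(regions$end > Biostrings::width(seqs)[match(regions$chrom, names(seqs))])) {
    stop("region extends beyond its contig", call. = FALSE)
  }
  vapply(seq_len(nrow(regions)), function(i) {
    s <- Biostrings::subseq(seqs[[regions$chrom[i]]],
                            start = regions$start[i] + 1L,
                            end = regions$end[i])
    gc <- sum(Biostrings::letterFrequency(s, c("G", "C")))
    gc / length(s)
  }, numeric(1))
}

region_overlap_flags <- function(regions, site_gr) {
  gr <- intervals_to_gr(regions)
  countOv <- GenomicRanges::countOverlaps(gr, site_gr, minoverlap = 1L)
  countOv > 0L
}

#' Differential TFBS enrichment between two region sets
#'
#' For each TF's binding-site set, counts regions with at least 1 bp of
#' site overlap in the foreground versus the other set (the combined set is
#' the background universe) and computes a one-sided Fisher (hypergeometric
#' tail) p-value for foreground enrichment, with BH adjustment across TFs.
#'
#' @param foreground,other deduplicated interval data.frames with no shared
#'   regions.
#' @param tfbs a [tfbs_collection()].
#' @return data.frame (`tf`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_one_sided`, `p_adjusted`) sorted by p then decreasing odds ratio.
#'   Empty TFBS sets yield `odds_ratio = NA`, `p = 1`. Zero cells use the
#'   Haldane 0.5 correction for the odds ratio only.
#' @export
differential_tfbs_enrichment <- function(foreground, other, tfbs) {
  key <- function(df) paste(df$chrom, df$start, df$end)
  foreground <- foreground[!duplicated(key(foreground)), , drop = FALSE]
  other <- other[!duplicated(key(other)), , drop = FALSE]
  if (length(intersect(key(foreground), key(other)))) {
    stop("foreground and other region sets overlap after deduplication",
         call. = FALSE)
  }
  nf <- nrow(foreground)
  no <- nrow(other)
  tfs <- tf_names(tfbs)
  rows <- lapply(tfs, function(tf) {
    sites <- tfbs$sites[tfbs$sites$tf == tf, , drop = FALSE]
    if (!nrow(sites)) {
      return(data.frame(tf = tf, a = 0L, b = nf, c = 0L, d = no,
                        odds_ratio = NA_real_, p_one_sided = 1,
                        stringsAsFactors = FALSE))
    }
    gr <- intervals_to_gr(sites)
    a <- sum(region_overlap_flags(foreground, gr))
    c_ <- sum(region_overlap_flags(other, gr))
    b <- nf - a
    d <- no - c_
    or <- if (a == 0 || b == 0 || c_ == 0 || d == 0) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    } else {
      (a * d) / (b * c_)
    }
    p <- hyper_tail(a, marked = a + c_, universe = nf + no, draws = nf)
    data.frame(tf = tf, a = a, b = b, c = c_, d = d, odds_ratio = or,
               p_one_sided = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_one_sided, method = "BH")
  out[order(out$p_one_sided, -out$odds_ratio, out$tf), , drop = FALSE]
}

#' Annotate CpGs by genomic context
#'
#' Assigns each CpG one of `promoter` (within -1000..+100 of a TSS,
#' strand-aware), `exon`, `intron` (inside a gene body but not an exon), or
#' `intergenic`, with precedence promoter > exon > intron > intergenic.
#'
#' @param probe_ids CpGs to annotate.
#' @param manifest CpG manifest.
#' @param annotation gene annotation data.frame (`gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`) with optional `exons` list column of
#'   two-column start/end matrices.
#' @param promoter_window c(upstream, downstream) of TSS in bp.
#' @return list with `category` (named character vector per probe) and
#'   `distribution` (named count table over the four categories).
#' @export
annotate_genomic_context <- function(probe_ids, manifest, annotation,
                                     promoter_window = c(1000, 100)) {
  idx <- match(probe_ids, manifest$probe_id)
  stopifnot(!anyNA(idx))
  m <- manifest[idx, , drop = FALSE]
  cpg_gr <- cpg_to_gr(m)

  up <- promoter_window[1]
  dn <- promoter_window[2]
  prom_start <- ifelse(annotation$strand == "+",
                       annotation$tss - up, annotation$tss - dn)
  prom_end <- ifelse(annotation$strand == "+",
                     annotation$tss + dn + 1L, annotation$tss + up + 1L)
  prom <- data.frame(chrom = annotation$chrom,
                     start = pmax(0L, prom_start), end = prom_end)
  in_prom <- region_overlap_flags_points(cpg_gr, prom)

  exon_df <- annotation_exons(annotation)
  in_exon <- if (nrow(exon_df)) region_overlap_flags_points(cpg_gr, exon_df)
             else rep(FALSE, nrow(m))
  body <- annotation[c("chrom", "start", "end")]
  in_body <- region_overlap_flags_points(cpg_gr, body)

  category <- ifelse(in_prom, "promoter",
              ifelse(in_exon, "exon",
              ifelse(in_body, "intron", "intergenic")))
  names(category) <- m$probe_id
  lev <- c("promoter", "exon", "intron", "intergenic")
  list(category = category,
       distribution = table(factor(category, levels = lev)))
}

region_overlap_flags_points <- function(point_gr, regions) {
  gr <- intervals_to_gr(regions)
  GenomicRanges::countOverlaps(point_gr, gr) > 0L
}

annotation_exons <- function(annotation) {
  if (is.null(annotation$exons)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  pieces <- lapply(seq_len(nrow(annotation)), function(i) {
    ex <- annotation$exons[[i]]
    if (is.null(ex) || !nrow(ex)) return(NULL)
    data.frame(chrom = annotation$chrom[i], start = ex[, 1], end = ex[, 2])
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) data.frame(chrom = character(0), start = integer(0),
                               end = integer(0)) else out
}

#' Fisher test for the overlap of two labelled lists
#'
#' One-sided hypergeometric tail P(X >= |A intersect B|) for drawing |A|
#' elements from a universe of `universe_size` containing |B| marked
#' elements. The universe size is a required explicit argument.
#'
#' @param setA,setB character vectors (e.g. TF name lists).
#' @param universe_size size of the common universe.
#' @return list with `overlap`, `odds_ratio` (Haldane-corrected when a cell
#'   is zero), and `p`.
#' @export
list_overlap_fisher <- function(setA, setB, universe_size) {
  setA <- unique(setA)
  setB <- unique(setB)
  stopifnot(universe_size >= length(setA), universe_size >= length(setB))
  k <- length(intersect(setA, setB))
  a <- k
  b <- length(setA) - k
  c_ <- length(setB) - k
  d <- universe_size - length(setA) - length(setB) + k
  or <- if (a == 0 || b == 0 || c_ == 0 || d == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  list(overlap = k, odds_ratio = or,
       p = hyper_tail(k, marked = length(setB), universe = universe_size,
                      draws = length(setA)))
}
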