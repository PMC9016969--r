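## Domain containers and file I/O.
##
## All coordinates inside the package are 0-based half-open (BED convention):
## an interval covers bases [start, end); a CpG is a single base at `pos`.
## GRanges/IRanges (1-based closed) are used only as transient overlap
## indexes, converted at the boundary.

#' Normalize chromosome names to the "chr"-prefixed dialect
#' @param chrom character vector of chromosome names ("1" or "chr1").
#' @return character vector with a "chr" prefix.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom))
}

#' Validate a table of genomic intervals
#'
#' Checks the 0-based half-open interval invariants: non-empty chromosome
#' names, integer coordinates with 0 <= start < end.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`.
#' @param where label used in error messages.
#' @return the input, invisibly, with coordinates as integers.
#' @export
validate_intervals <- function(df, where = "interval table") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (any(is.na(df$chrom)) || any(!nzchar(df$chrom))) {
    stop(where, ": empty chromosome name", call. = FALSE)
  }
  bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                 df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop(where, ": invalid interval at row ", bad[1],
         " (require 0 <= start < end)", call. = FALSE)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  invisible(df)
}

## transient overlap index; `pad` symmetrically extends every interval
intervals_to_gr <- function(df, pad = 0L) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L - pad, end = df$end + pad)
  )
}

cpg_to_gr <- function(manifest) {
  GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$pos + 1L, width = 1L)
  )
}

#' Read a BED file of genomic intervals
#'
#' Reads a 3+ column tab-separated BED file into an interval data.frame
#' (0-based half-open coordinates preserved verbatim). A 4th column is kept
#' as `name` and, with `group_by_name = TRUE`, interpreted as the TF owning
#' each binding site.
#'
#' @param path file path.
#' @param group_by_name return a [tfbs_collection()] grouped by the name
#'   column instead of a flat data.frame.
#' @param normalize normalize chromosome names to the "chr" dialect
#'   (default TRUE).
#' @return data.frame with columns `chrom`, `start`, `end` and any of
#'   `name`, `score`, `strand` present in the file, or a `tfbs_collection`.
#' @export
read_bed <- function(path, group_by_name = FALSE, normalize = TRUE) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("BED file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED parse error at line ", which(nf < 3L)[1],
         ": fewer than 3 tab-separated columns", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop("BED parse error at line ", bad[1],
         ": require integer 0 <= start < end", call. = FALSE)
  }
  df <- data.frame(chrom = if (normalize) normalize_chrom(chrom) else chrom,
                   start = start, end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4L)) df$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) df$score <- vapply(fields, `[[`, "", 5L)
  if (all(nf >= 6L)) df$strand <- vapply(fields, `[[`, "", 6L)
  if (group_by_name) {
    if (is.null(df$name)) {
      stop("group_by_name requires a 4-column BED with a name field",
           call. = FALSE)
    }
    return(tfbs_collection(df[c("chrom", "start", "end", "name")]))
  }
  df
}

#' Write an interval data.frame as BED
#' @param df data.frame as returned by [read_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df, "write_bed")
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  write.table(df[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-TF binding-site collection with an overlap index
#'
#' Groups binding-site intervals by TF and pre-builds a GRanges index used
#' by proximity and enrichment queries.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `name` (TF).
#' @return object of class `tfbs_collection` with elements `sites`
#'   (validated data.frame, `name` renamed to `tf`) and `gr` (index).
#' @export
tfbs_collection <- function(df) {
  if (!is.null(df$tf) && is.null(df$name)) df$name <- df$tf
  stopifnot(!is.null(df$name))
  validate_intervals(df, "tfbs_collection")
  sites <- data.frame(chrom = df$chrom, start = as.integer(df$start),
                      end = as.integer(df$end), tf = as.character(df$name),
                      stringsAsFactors = FALSE)
  gr <- intervals_to_gr(sites)
  S4Vectors::mcols(gr)$tf <- sites$tf
  structure(list(sites = sites, gr = gr), class = "tfbs_collection")
}

#' @export
print.tfbs_collection <- function(x, ...) {
  cat("tfbs_collection:", length(unique(x$sites$tf)), "TFs,",
      nrow(x$sites), "sites\n")
  invisible(x)
}

tf_names <- function(tfbs) sort(unique(tfbs$sites$tf))

#' Read a row-by-sample numeric matrix from TSV
#'
#' First column holds row identifiers (CpG probes or genes/TFs), the header
#' row holds sample identifiers. Empty cells become `NA`.
#'
#' @param path file path.
#' @param type "expression" (values must be non-negative) or "methylation"
#'   (beta values must lie in \[0, 1\]); `NULL` skips range validation.
#' @return numeric matrix with row and column names.
#' @export
read_matrix <- function(path, type = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate row ID in ", path, ": ",
         ids[duplicated(ids)][1], call. = FALSE)
  }
  m <- as.matrix(df[-1L])
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ID in ", path, call. = FALSE)
  }
  if (!is.numeric(m)) {
    num <- suppressWarnings(apply(m, 2L, as.numeric))
    bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
    if (nrow(bad)) {
      stop("non-numeric cell in ", path, " at row '", ids[bad[1, 1]],
           "', sample '", colnames(m)[bad[1, 2]], "'", call. = FALSE)
    }
    m <- num
  }
  rownames(m) <- ids
  validate_matrix(m, type, where = path)
}

#' Validate a sample matrix against its declared value type
#' @param m numeric matrix.
#' @param type "expression", "methylation" or `NULL`.
#' @param where label for error messages.
#' @return the matrix, invisibly usable.
#' @export
validate_matrix <- function(m, type = NULL, where = "matrix") {
  if (!is.null(type)) {
    type <- match.arg(type, c("expression", "methylation"))
    v <- m[!is.na(m)]
    if (type == "methylation" && (any(v < 0) || any(v > 1))) {
      stop(where, ": methylation beta values must lie in [0, 1]",
           call. = FALSE)
    }
    if (type == "expression" && any(v < 0)) {
      stop(where, ": expression values must be non-negative", call. = FALSE)
    }
  }
  m
}

#' Write a matrix as TSV (row IDs in the first column)
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_name header for the row-ID column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CpG manifest (probe positions)
#'
#' TSV with columns `probe_id`, `chrom`, `pos`. Illumina manifests are
#' 1-based; positions are converted to the package's 0-based convention
#' when `one_based = TRUE` (the default).
#'
#' @param path file path.
#' @param one_based whether input positions are 1-based.
#' @return data.frame `probe_id`, `chrom`, `pos` (0-based).
#' @export
read_manifest <- function(path, one_based = TRUE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(df)))
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe_id in manifest: ",
         df$probe_id[duplicated(df$probe_id)][1], call. = FALSE)
  }
  df$chrom <- normalize_chrom(df$chrom)
  df$pos <- as.integer(df$pos) - if (one_based) 1L else 0L
  if (any(df$pos < 0)) stop("manifest position < ", if (one_based) 1 else 0,
                            call. = FALSE)
  df[c("probe_id", "chrom", "pos")]
}

#' Align an expression and a methylation matrix into a cohort bundle
#'
#' Restricts both matrices to the (sorted) intersection of their sample IDs
#' so that columns are paired one-to-one in identical order.
#'
#' @param expression gene/TF-by-sample matrix.
#' @param methylation CpG-by-sample beta matrix.
#' @param name cohort label.
#' @return object of class `cohort_bundle` with elements `name`,
#'   `expression`, `methylation`, `samples`.
#' @export
align_cohort <- function(expression, methylation, name = "cohort") {
  samples <- sort(intersect(colnames(expression), colnames(methylation)))
  if (!length(samples)) {
    stop("no shared samples between expression and methylation", call. = FALSE)
  }
  if (length(samples) < 3L) {
    stop("cohort '", name, "' has fewer than 3 shared samples", call. = FALSE)
  }
  structure(
    list(name = name,
         expression = expression[, samples, drop = FALSE],
         methylation = methylation[, samples, drop = FALSE],
         samples = samples),
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle '", x$name, "': ", nrow(x$expression),
      " expression rows x ", nrow(x$methylation), " CpGs x ",
      length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' Drop CpGs with excessive missingness
#'
#' Removes methylation rows missing in more than `max_missing` of samples;
#' remaining missing cells are handled pairwise-complete by the screen.
#'
#' @param methylation CpG-by-sample matrix.
#' @param max_missing maximum tolerated missing fraction per CpG.
#' @return filtered matrix.
#' @export
drop_missing_cpgs <- function(methylation, max_missing = 0.2) {
  frac <- rowMeans(is.na(methylation))
  methylation[frac <= max_missing, , drop = FALSE]
}
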