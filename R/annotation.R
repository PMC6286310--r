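#' Genome annotations
#'
#' A `genome_annotation` bundles gene records with arm lengths and an
#' optional set of intergenic intervals. Genes live in a data frame with
#' columns `gene_id`, `arm`, `start`, `end`, `is_hrpg` (1-based inclusive
#' coordinates); `arm_length_bp` is a named vector of arm sizes.
#'
#' @param genes Data frame with columns `gene_id`, `arm`, `start`, `end`,
#'   `is_hrpg`.
#' @param arm_length_bp Named numeric vector of arm lengths in bp.
#' @param intergenic Optional data frame (`arm`, `start`, `end`) of
#'   intergenic intervals, 1-based inclusive.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, arm_length_bp, intergenic = NULL) {
  required <- c("gene_id", "arm", "start", "end", "is_hrpg")
  if (!is.data.frame(genes) || !all(required %in% names(genes)))
    stop("annotation error: 'genes' must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("annotation error: duplicated gene_id", call. = FALSE)
  if (is.null(names(arm_length_bp)) || any(!nzchar(names(arm_length_bp))))
    stop("annotation error: arm_length_bp must be a named vector",
         call. = FALSE)
  if (any(arm_length_bp < 1))
    stop("annotation error: arm lengths must be positive", call. = FALSE)
  if (nrow(genes) > 0) {
    unknown <- setdiff(unique(genes$arm), names(arm_length_bp))
    if (length(unknown))
      stop("annotation error: genes on arms with no length: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (any(genes$start < 1) || any(genes$start > genes$end))
      stop("annotation error: invalid gene coordinates", call. = FALSE)
    if (any(genes$end > arm_length_bp[genes$arm]))
      stop("annotation error: gene extends past its arm end", call. = FALSE)
  }
  structure(list(genes = genes, arm_length_bp = arm_length_bp,
                 intergenic = intergenic),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes (%d hRPG) on %d arm(s), %s bp\n",
              nrow(x$genes), sum(x$genes$is_hrpg),
              length(x$arm_length_bp),
              format(sum(x$arm_length_bp), big.mark = ",",
                     scientific = FALSE)))
  invisible(x)
}

#' Gene midpoints
#'
#' A gene's position is taken as the midpoint between its start and end,
#' kept as an exact real so half-integers are preserved.
#'
#' @param start,end 1-based inclusive coordinates (vectorised).
#' @return Numeric midpoints `(start + end) / 2`.
#' @examples
#' gene_midpoint(10, 11) # 10.5
#' @export
gene_midpoint <- function(start, end) {
  stopifnot(all(start <= end))
  (start + end) / 2
}

#' Binned gene density per arm
#'
#' Counts genes per fixed-width bin along each arm, assigning each gene to
#' exactly one bin by its midpoint: bin index `floor((midpoint - 1) /
#' bin_size)` (0-based), so position 1 maps to bin 0 and a midpoint exactly
#' on a bin's closing boundary (e.g. 40000 for 40-kbp bins) stays in that
#' bin. The number of bins per arm is `ceiling(arm_length / bin_size)`.
#' Bin counts on an arm always sum to the arm's gene count.
#'
#' @param annotation A [genome_annotation()].
#' @param bin_size_bp Bin width in bp (default 40 kbp).
#' @return Data frame with columns `arm`, `bin_start_bp` (1-based start of
#'   the bin), `count`.
#' @export
bin_gene_density <- function(annotation, bin_size_bp = 40000L) {
  stopifnot(inherits(annotation, "genome_annotation"),
            length(bin_size_bp) == 1L, bin_size_bp >= 1)
  out <- lapply(names(annotation$arm_length_bp), function(arm) {
    len <- annotation$arm_length_bp[[arm]]
    nbin <- ceiling(len / bin_size_bp)
    counts <- numeric(nbin)
    g <- annotation$genes[annotation$genes$arm == arm, , drop = FALSE]
    if (nrow(g) > 0) {
      mid <- gene_midpoint(g$start, g$end)
      idx <- floor((mid - 1) / bin_size_bp) # 0-based bin index
      if (any(idx < 0) || any(idx >= nbin))
        stop("annotation error: gene midpoint outside arm bounds",
             call. = FALSE)
      tab <- table(idx)
      counts[as.numeric(names(tab)) + 1] <- as.numeric(tab)
    }
    data.frame(arm = arm,
               bin_start_bp = seq_len(nbin) * bin_size_bp - bin_size_bp + 1,
               count = counts)
  })
  do.call(rbind, out)
}

#' Intragenic percentage of a genome
#'
#' The fraction of the genome covered by gene bodies, computed as the
#' complement of the summed intergenic sequence:
#' `100 * (genome_size - sum(intergenic lengths)) / genome_size`.
#'
#' @param genome_size_bp Total genome size in bp.
#' @param intergenic Data frame (`arm`, `start`, `end`) of non-overlapping
#'   intergenic intervals, 1-based inclusive, or a list of
#'   [genomic_interval()] objects.
#' @return Percentage in `[0, 100]`.
#' @export
intragenic_percentage <- function(genome_size_bp, intergenic) {
  stopifnot(length(genome_size_bp) == 1L, genome_size_bp >= 1)
  df <- as_interval_df(intergenic)
  if (nrow(df) == 0) return(100)
  if (any(df$start < 1) || any(df$start > df$end))
    stop("input error: invalid intergenic interval", call. = FALSE)
  for (arm in unique(df$arm)) {
    a <- df[df$arm == arm, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) > 1 && any(a$start[-1] <= a$end[-nrow(a)]))
      stop("input error: overlapping intergenic intervals on arm ", arm,
           call. = FALSE)
  }
  total <- sum(df$end - df$start + 1)
  if (total > genome_size_bp)
    stop("input error: intergenic total exceeds genome size", call. = FALSE)
  100 * (genome_size_bp - total) / genome_size_bp
}

as_interval_df <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("arm", "start", "end") %in% names(x)))
    return(x)
  }
  if (is.null(x) || length(x) == 0)
    return(data.frame(arm = character(), start = numeric(),
                      end = numeric()))
  if (inherits(x, "genomic_interval")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "genomic_interval")))
  data.frame(arm = vapply(x, `[[`, character(1), "arm"),
             start = vapply(x, `[[`, numeric(1), "start"),
             end = vapply(x, `[[`, numeric(1), "end"))
}

#' Read and write gene annotations as BED
#'
#' The BED boundary applies the 1-based inclusive to 0-based half-open
#' shift of [to_bed()] / [from_bed()]; the hRPG flag travels in the BED
#' score column (1 = hRPG, 0 = not).
#'
#' @param annotation A [genome_annotation()].
#' @param path Output (or input) file path.
#' @return `write_annotation_bed()` returns `path` invisibly;
#'   `read_annotation_bed()` returns a data frame of gene records in
#'   1-based inclusive coordinates.
#' @export
write_annotation_bed <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  bed <- data.frame(chrom = g$arm,
                    start = g$start - 1,
                    end = g$end,
                    name = g$gene_id,
                    score = as.integer(g$is_hrpg),
                    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  if (any(bed$start < 0))
    stop("parse error: negative BED start", call. = FALSE)
  data.frame(gene_id = bed$name, arm = bed$chrom,
             start = bed$start + 1, end = bed$end,
             is_hrpg = bed$score == 1)
}

#' @rdname write_annotation_bed
#' @export
write_annotation_tsv <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- annotation$genes
  df <- data.frame(gene_id = g$gene_id,
                   location = sprintf("%s:%s..%s", g$arm,
                                      format(g$start, scientific = FALSE,
                                             trim = TRUE),
                                      format(g$end, scientific = FALSE,
                                             trim = TRUE)),
                   is_hrpg = as.integer(g$is_hrpg))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
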