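#' Genomic intervals in the FlyBase dialect
#'
#' A `genomic_interval` is a coordinate span on a named chromosome arm,
#' fixed to the 1-based inclusive convention used by FlyBase
#' (`"arm:start..end"`). All internal coordinates in this package use this
#' convention; conversion to the 0-based half-open BED convention happens
#' only at the file boundary via [to_bed()] / [from_bed()].
#'
#' @param arm Chromosome arm label, e.g. `"2R"`.
#' @param start,end 1-based inclusive coordinates; `start <= end`, both
#'   positive integers.
#' @return An object of class `genomic_interval` with fields `arm`,
#'   `start`, `end`.
#' @examples
#' iv <- genomic_interval("2R", 24967017, 24970096)
#' interval_length_bp(iv)
#' @export
genomic_interval <- function(arm, start, end) {
  if (!is.character(arm) || length(arm) != 1L || !nzchar(arm))
    stop("coordinate error: 'arm' must be a non-empty string", call. = FALSE)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L ||
      is.na(start) || is.na(end) ||
      start != floor(start) || end != floor(end))
    stop("coordinate error: start/end must be single integers", call. = FALSE)
  if (start < 1 || end < 1)
    stop("coordinate error: coordinates are 1-based and must be >= 1",
         call. = FALSE)
  if (start > end)
    stop(sprintf("coordinate error: start (%s) > end (%s)",
                 format(start, scientific = FALSE),
                 format(end, scientific = FALSE)), call. = FALSE)
  structure(list(arm = arm, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(format_flybase_interval(x), "\n")
  invisible(x)
}

#' @rdname genomic_interval
#' @param interval A `genomic_interval`.
#' @export
interval_length_bp <- function(interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  interval$end - interval$start + 1
}

#' Interval length in kilobase pairs
#'
#' Length of a 1-based inclusive interval in kbp, rounded half-up to the
#' requested number of decimals (half-up matches how published construct
#' sizes such as "3.08 kbp" are reported; base R `round()` is
#' round-half-even and is deliberately not used).
#'
#' @param interval A [genomic_interval()].
#' @param decimals Non-negative integer number of decimals to keep.
#' @return Length in kbp as a numeric scalar.
#' @examples
#' interval_length_kb(genomic_interval("2R", 24967017, 24970096), 2) # 3.08
#' @export
interval_length_kb <- function(interval, decimals = 2L) {
  stopifnot(inherits(interval, "genomic_interval"),
            length(decimals) == 1L, decimals >= 0)
  round_half_up(interval_length_bp(interval) / 1000, decimals)
}

round_half_up <- function(x, decimals) {
  p <- 10^decimals
  floor(x * p + 0.5) / p
}

#' Parse a FlyBase-style interval string
#'
#' Parses `"arm:start..end"` text, tolerating an optional trailing
#' genome-release token (e.g. `"2R:24967017..24970096 Dmel_r6.08"`).
#'
#' @param text A single interval string.
#' @return A [genomic_interval()].
#' @examples
#' parse_flybase_interval("2R:24968426..24969517 Dmel_r6.08")
#' @export
parse_flybase_interval <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("parse error: expected a single string", call. = FALSE)
  core <- strsplit(trimws(text), "[[:space:]]+")[[1]][1]
  m <- regexec("^([^:]+):([0-9]+)\\.\\.([0-9]+)$", core)[[1]]
  if (m[1] == -1L)
    stop(sprintf("parse error: '%s' is not '<arm>:<start>..<end>'", core),
         call. = FALSE)
  parts <- regmatches(core, regexec("^([^:]+):([0-9]+)\\.\\.([0-9]+)$",
                                    core))[[1]]
  genomic_interval(parts[2], as.numeric(parts[3]), as.numeric(parts[4]))
}

#' @rdname parse_flybase_interval
#' @param interval A `genomic_interval` to format.
#' @export
format_flybase_interval <- function(interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  sprintf("%s:%s..%s", interval$arm,
          format(interval$start, scientific = FALSE),
          format(interval$end, scientific = FALSE))
}

#' Sequence changes (ref > alt)
#'
#' Parses the `"REF > ALT"` allele notation used for point mutations and
#' small indels (e.g. `"C > GATCCC"`, `"TC > ACA"`), attaching the arm and
#' 1-based position the change is anchored at.
#'
#' @param text A single string matching `<REF> > <ALT>`.
#' @param arm Chromosome arm label.
#' @param position 1-based position of the first reference base.
#' @return An object of class `sequence_change` with fields `arm`,
#'   `position`, `ref`, `alt`.
#' @examples
#' parse_sequence_change("C > GATCCC", "3R", 18925226)
#' @export
parse_sequence_change <- function(text, arm, position) {
  if (!is.character(text) || length(text) != 1L)
    stop("parse error: expected a single string", call. = FALSE)
  parts <- strsplit(trimws(text), ">", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop(sprintf("parse error: '%s' is not '<REF> > <ALT>'", text),
         call. = FALSE)
  ref <- toupper(trimws(parts[1])); alt <- toupper(trimws(parts[2]))
  for (allele in c(ref, alt)) {
    if (!nzchar(allele) || grepl("[^ACGT]", allele))
      stop(sprintf("parse error: allele '%s' contains non-DNA characters",
                   allele), call. = FALSE)
  }
  if (identical(ref, alt))
    stop("parse error: ref and alt alleles are identical", call. = FALSE)
  position <- as.numeric(position)
  if (length(position) != 1L || is.na(position) || position < 1 ||
      position != floor(position))
    stop("coordinate error: position must be a positive integer",
         call. = FALSE)
  structure(list(arm = arm, position = position, ref = ref, alt = alt),
            class = "sequence_change")
}

#' @export
print.sequence_change <- function(x, ...) {
  cat(sprintf("%s > %s at %s:%s\n", x$ref, x$alt, x$arm,
              format(x$position, scientific = FALSE)))
  invisible(x)
}

#' Net length change and frameshift status of a sequence change
#'
#' `net_length_change()` is `nchar(alt) - nchar(ref)` in bp (positive for
#' insertions). `is_frameshift()` is `TRUE` iff that net change is not a
#' multiple of 3, i.e. the change shifts the reading frame of any
#' transcript it lands in.
#'
#' @param change A [parse_sequence_change()] result.
#' @return Integer bp for `net_length_change()`; logical for
#'   `is_frameshift()`.
#' @examples
#' ins <- parse_sequence_change("C > GATCCC", "3R", 18925226)
#' net_length_change(ins) # +5
#' is_frameshift(ins)     # TRUE
#' @export
net_length_change <- function(change) {
  stopifnot(inherits(change, "sequence_change"))
  nchar(change$alt) - nchar(change$ref)
}

#' @rdname net_length_change
#' @export
is_frameshift <- function(change) {
  net_length_change(change) %% 3 != 0
}

#' Convert between 1-based inclusive and BED coordinates
#'
#' BED is 0-based half-open, so `start_bed = start - 1` and
#' `end_bed = end`. The round trip `from_bed(to_bed(x))` is lossless.
#'
#' @param interval A [genomic_interval()].
#' @return `to_bed()` returns a list `(chrom, start, end)` in BED
#'   convention; `from_bed()` returns a [genomic_interval()].
#' @examples
#' to_bed(genomic_interval("2R", 1, 1))        # chrom 2R, 0, 1
#' from_bed("2R", 24967016, 24970096)          # 2R:24967017..24970096
#' @export
to_bed <- function(interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  list(chrom = interval$arm, start = interval$start - 1, end = interval$end)
}

#' @rdname to_bed
#' @param chrom BED chromosome name.
#' @param start,end BED 0-based half-open coordinates.
#' @export
from_bed <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(c(start, end))) || start < 0)
    stop("parse error: BED start must be >= 0", call. = FALSE)
  if (end <= start)
    stop("parse error: BED requires end > start", call. = FALSE)
  genomic_interval(chrom, start + 1, end)
}
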