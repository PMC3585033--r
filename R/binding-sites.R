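#' Construct a binding-site dataset for one transcription factor
#'
#' A `tf_dataset` holds the ChIP-seq binding sites of one transcription factor
#' at one developmental stage. Coordinates are 0-based half-open throughout the
#' package; the summit is the absolute genomic coordinate of maximal read
#' density within the site and must satisfy `start <= summit < end`.
#' Significance is stored on the -log10 scale, so a q-value cutoff of 1e-5
#' corresponds to a stored value of 5.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open interval per site.
#' @param summit integer vector; absolute coordinate of maximal read density.
#' @param q_value numeric vector of site significance on the -log10 scale
#'   (larger is more significant); must be non-negative.
#' @param tf single factor name.
#' @param stage single developmental-stage label.
#' @return A data frame of class `tf_dataset` with columns `chrom`, `start`,
#'   `end`, `summit`, `q_value` and attributes `tf` and `stage`. Input order is
#'   preserved.
#' @examples
#' tf_dataset("chrI", 100, 200, 150, 8, tf = "unc-62", stage = "YA")
#' @export
tf_dataset <- function(chrom, start, end, summit, q_value, tf, stage = "NA") {
  lens <- c(length(chrom), length(start), length(end), length(summit),
            length(q_value))
  n <- max(lens)
  if (!all(lens == n | lens == 1L))
    stop("all site fields must have equal length (or length 1)", call. = FALSE)
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n); summit <- rep_len(summit, n)
  q_value <- rep_len(q_value, n)
  start <- as.numeric(start); end <- as.numeric(end)
  summit <- as.numeric(summit); q_value <- as.numeric(q_value)
  bad <- which(!(start < end))
  if (length(bad))
    stop(sprintf("malformed site %d: start (%s) must be < end (%s)",
                 bad[1], start[bad[1]], end[bad[1]]), call. = FALSE)
  bad <- which(!(start <= summit & summit < end))
  if (length(bad))
    stop(sprintf("malformed site %d: summit %s outside [%s, %s)",
                 bad[1], summit[bad[1]], start[bad[1]], end[bad[1]]),
         call. = FALSE)
  if (any(is.na(q_value)) || any(q_value < 0))
    stop("q_value must be non-negative on the -log10 scale", call. = FALSE)
  x <- data.frame(chrom = as.character(chrom), start = start, end = end,
                  summit = summit, q_value = q_value,
                  stringsAsFactors = FALSE)
  attr(x, "tf") <- as.character(tf)[1]
  attr(x, "stage") <- as.character(stage)[1]
  class(x) <- c("tf_dataset", "data.frame")
  x
}

#' @export
print.tf_dataset <- function(x, ...) {
  cat(sprintf("<tf_dataset> %s (%s): %d sites on %d chromosome(s)\n",
              attr(x, "tf"), attr(x, "stage"), nrow(x),
              length(unique(x$chrom))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Read binding sites from a BED-like peak file
#'
#' Ingests a tab-delimited peak-call file with columns chrom, start, end,
#' summit, q-value (at least five columns; extras ignored). BED coordinates are
#' 0-based half-open and kept as-is. Because upstream peak callers differ in
#' how they record the summit and the significance, the dialect must be
#' declared: the summit column may be an absolute genomic coordinate or an
#' offset from `start`, and the q-value column may already be -log10 or a raw
#' probability (converted to -log10 on read).
#'
#' @param path file path.
#' @param tf,stage labels attached to the dataset.
#' @param summit `"absolute"` or `"offset"`; how column 4 encodes the summit.
#' @param q_scale `"neglog10"` or `"raw"`; how column 5 encodes significance.
#' @return A [tf_dataset()] preserving input record order.
#' @seealso [write_binding_sites()]
#' @export
read_binding_sites <- function(path, tf, stage = "NA",
                               summit = c("absolute", "offset"),
                               q_scale = c("neglog10", "raw")) {
  summit <- match.arg(summit)
  q_scale <- match.arg(q_scale)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 5)
    stop(sprintf("'%s': expected >= 5 tab-delimited columns (chrom, start, end, summit, q), found %d",
                 path, ncol(raw)), call. = FALSE)
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  smt <- suppressWarnings(as.numeric(raw[[4]]))
  qv <- suppressWarnings(as.numeric(raw[[5]]))
  bad <- which(is.na(start) | is.na(end) | is.na(smt) | is.na(qv))
  if (length(bad))
    stop(sprintf("'%s' line %d: non-numeric coordinate or q-value", path, bad[1]),
         call. = FALSE)
  if (summit == "offset") smt <- start + smt
  if (q_scale == "raw") {
    if (any(qv < 0 | qv > 1))
      stop(sprintf("'%s': raw q-values must lie in [0, 1]", path), call. = FALSE)
    qv <- -log10(qv)
  }
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("'%s' line %d: start >= end", path, bad[1]), call. = FALSE)
  bad <- which(smt < start | smt >= end)
  if (length(bad))
    stop(sprintf("'%s' line %d: summit outside [start, end)", path, bad[1]),
         call. = FALSE)
  tf_dataset(raw[[1]], start, end, smt, qv, tf = tf, stage = stage)
}

#' Write a binding-site dataset to a BED-like peak file
#'
#' Writes the tab-delimited dialect [read_binding_sites()] reads back with the
#' default flags (absolute summit, -log10 q-value), so write-then-read is an
#' exact round trip.
#'
#' @param x a [tf_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_binding_sites <- function(x, path) {
  stopifnot(inherits(x, "tf_dataset"))
  utils::write.table(
    data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE),
               format(x$summit, scientific = FALSE, trim = TRUE), x$q_value),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a one-gene-per-line gene list
#'
#' @param path file path; blank lines and `#` comments are ignored.
#' @return Character vector of unique gene identifiers, in first-seen order.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}
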