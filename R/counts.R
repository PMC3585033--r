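#' Construct a paired count matrix
#'
#' Integer read counts with rows as transcripts (or genes) and columns as
#' samples, for a balanced paired design: every control replicate i is paired
#' with treatment replicate i. Pairing must be a bijection.
#'
#' @param counts integer matrix with row and column names.
#' @param condition character vector, one of `"control"`/`"treatment"` per
#'   column.
#' @param replicate integer vector of replicate indices per column; each index
#'   must appear exactly once per condition.
#' @return The matrix with class `count_matrix` and attributes `condition` and
#'   `replicate`.
#' @export
count_matrix <- function(counts, condition, replicate) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row and column names", call. = FALSE)
  if (length(condition) != ncol(counts) || length(replicate) != ncol(counts))
    stop("condition and replicate must have one entry per column", call. = FALSE)
  if (!all(condition %in% c("control", "treatment")))
    stop("condition must be 'control' or 'treatment'", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  ctrl <- replicate[condition == "control"]
  trt <- replicate[condition == "treatment"]
  if (length(ctrl) != length(trt))
    stop(sprintf("unbalanced design: %d control vs %d treatment columns",
                 length(ctrl), length(trt)), call. = FALSE)
  if (anyDuplicated(ctrl) || anyDuplicated(trt) ||
      !setequal(ctrl, trt))
    stop("replicate pairing must be a bijection between conditions",
         call. = FALSE)
  storage.mode(counts) <- "double"
  structure(counts, condition = as.character(condition),
            replicate = as.integer(replicate),
            class = c("count_matrix", class(counts)))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d rows x %d samples (%d replicate pairs)\n",
              nrow(x), ncol(x), sum(attr(x, "condition") == "control")))
  print(utils::head(unclass(x)[, , drop = FALSE], 5))
  invisible(x)
}

# Column indices of the control and treatment member of each replicate pair,
# ordered by replicate index.
cm_pairs <- function(x) {
  cond <- attr(x, "condition"); rep <- attr(x, "replicate")
  reps <- sort(unique(rep))
  list(control = vapply(reps, function(r)
         which(cond == "control" & rep == r), integer(1)),
       treatment = vapply(reps, function(r)
         which(cond == "treatment" & rep == r), integer(1)),
       replicate = reps)
}

# Rebuild a count_matrix from a plain matrix, inheriting design attributes.
cm_like <- function(counts, template) {
  count_matrix(counts, attr(template, "condition"),
               attr(template, "replicate"))
}

#' Read a transcript-by-sample count table
#'
#' @param path TSV with a first column of row identifiers and a header of
#'   sample names.
#' @param condition_map data frame with columns `sample`, `condition`
#'   (`"control"`/`"treatment"`) and `replicate` (integer pairing index)
#'   covering every sample column.
#' @return A [count_matrix()] with columns ordered as in the file.
#' @export
read_count_table <- function(path, condition_map) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- x[[1]]
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop(sprintf("'%s': non-numeric count value", path), call. = FALSE)
  if (any(m != round(m)))
    stop(sprintf("'%s': non-integer count value", path), call. = FALSE)
  rownames(m) <- ids
  miss <- setdiff(colnames(m), condition_map$sample)
  if (length(miss))
    stop(sprintf("no condition assigned to sample(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  i <- match(colnames(m), condition_map$sample)
  count_matrix(m, condition_map$condition[i], condition_map$replicate[i])
}

#' Write a count matrix as TSV
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove reads with long A or T homopolymer runs
#'
#' 3'-tag RNA-seq libraries are primed on the poly(A) tail, so reads containing
#' long runs of A or T are likely reverse-transcription artifacts. A read is
#' removed when its longest run of consecutive A's, or of consecutive T's,
#' reaches `max_run` (default 10, i.e. "10 or more" are removed). Quality
#' strings play no role; the rule is sequence-only. The filter is idempotent.
#'
#' @param reads character vector of read sequences over A/C/G/T/N.
#' @param max_run minimum run length that triggers removal; `>= 1`.
#' @return List with `reads` (the retained sequences, order preserved) and
#'   `n_removed`.
#' @export
filter_homopolymer_reads <- function(reads, max_run = 10) {
  stopifnot_scalar_number(max_run, "max_run")
  if (max_run < 1) stop("'max_run' must be >= 1", call. = FALSE)
  if (length(reads) == 0) return(list(reads = character(0), n_removed = 0L))
  bad_chr <- grepl("[^ACGTN]", reads)
  if (any(bad_chr))
    stop(sprintf("read %d contains a non-ACGTN character", which(bad_chr)[1]),
         call. = FALSE)
  pat <- sprintf("A{%d}|T{%d}", as.integer(max_run), as.integer(max_run))
  drop <- grepl(pat, reads)
  list(reads = reads[!drop], n_removed = sum(drop))
}

#' Filter a FASTQ file for homopolymer artifact reads
#'
#' File-level wrapper around [filter_homopolymer_reads()]; qualities are
#' carried through unchanged for retained reads.
#'
#' @param input,output FASTQ paths.
#' @param max_run see [filter_homopolymer_reads()].
#' @return Number of reads removed, invisibly.
#' @export
filter_fastq_file <- function(input, output, max_run = 10) {
  fq <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(input))
  res <- filter_homopolymer_reads(as.character(fq), max_run = max_run)
  keep <- !grepl(sprintf("A{%d}|T{%d}", as.integer(max_run),
                         as.integer(max_run)), as.character(fq))
  Biostrings::writeXStringSet(fq[keep], output, format = "fastq",
                              qualities = Biostrings::quality(fq[keep]))
  invisible(res$n_removed)
}
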