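#' Construct a transcript-level genome annotation
#'
#' Transcripts are stored in 0-based half-open coordinates with a strand-aware
#' transcription start site: `tss = start` on the plus strand and
#' `tss = end - 1` on the minus strand (the biologically 5' base). Every
#' transcript belongs to exactly one gene; transcript identifiers must be
#' unique.
#'
#' @param transcript_id,gene_id character vectors mapping each transcript to
#'   its gene.
#' @param chrom chromosome name per transcript.
#' @param start,end 0-based half-open transcript extent.
#' @param strand `"+"` or `"-"` per transcript.
#' @param chrom_len optional named numeric vector of chromosome lengths,
#'   carried as an attribute for window clipping.
#' @return A data frame of class `genome_annotation` with an added `tss`
#'   column.
#' @export
genome_annotation <- function(transcript_id, gene_id, chrom, start, end,
                              strand, chrom_len = NULL) {
  lens <- c(length(transcript_id), length(gene_id), length(chrom),
            length(start), length(end), length(strand))
  n <- max(lens)
  if (!all(lens == n | lens == 1L))
    stop("all annotation fields must have equal length (or length 1)",
         call. = FALSE)
  transcript_id <- rep_len(transcript_id, n)
  gene_id <- rep_len(gene_id, n)
  chrom <- rep_len(chrom, n)
  start <- rep_len(start, n); end <- rep_len(end, n)
  strand <- rep_len(strand, n)
  start <- as.numeric(start); end <- as.numeric(end)
  if (anyDuplicated(transcript_id))
    stop(sprintf("duplicate transcript id '%s'",
                 transcript_id[anyDuplicated(transcript_id)]), call. = FALSE)
  if (!all(strand %in% c("+", "-")))
    stop(sprintf("unknown strand symbol '%s'",
                 setdiff(unique(strand), c("+", "-"))[1]), call. = FALSE)
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("transcript '%s': start >= end", transcript_id[bad[1]]),
         call. = FALSE)
  x <- data.frame(transcript_id = as.character(transcript_id),
                  gene_id = as.character(gene_id),
                  chrom = as.character(chrom),
                  start = start, end = end, strand = as.character(strand),
                  stringsAsFactors = FALSE)
  x$tss <- ifelse(x$strand == "+", x$start, x$end - 1)
  if (!is.null(chrom_len)) attr(x, "chrom_len") <- chrom_len
  class(x) <- c("genome_annotation", "data.frame")
  x
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d transcripts, %d genes, %d chromosome(s)\n",
              nrow(x), length(unique(x$gene_id)), length(unique(x$chrom))))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Read a transcript annotation from GFF3 or TSV
#'
#' GFF3 input (1-based closed intervals) is converted to the package's 0-based
#' half-open convention on read; rows of type `mRNA` or `transcript` are used,
#' with the gene taken from the `Parent` attribute (falling back to `gene_id`
#' or the record `ID`). TSV input must carry a header with columns
#' `transcript_id`, `gene_id`, `chrom`, `start`, `end`, `strand`, already
#' 0-based half-open.
#'
#' @param path file path; format is inferred from the extension unless given.
#' @param format `"auto"`, `"gff3"` or `"tsv"`.
#' @return A [genome_annotation()].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "tsv"
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    keep <- tolower(as.character(gr$type)) %in% c("mrna", "transcript")
    gr <- gr[keep]
    if (!length(gr)) stop(sprintf("'%s': no mRNA/transcript records", path),
                          call. = FALSE)
    parent <- vapply(as.list(gr$Parent), function(p)
      if (length(p)) sub("^gene:", "", p[1]) else NA_character_, character(1))
    gid <- parent
    if (!is.null(gr$gene_id)) gid[is.na(gid)] <- gr$gene_id[is.na(gid)]
    tid <- sub("^transcript:", "", gr$ID %||% as.character(seq_along(gr)))
    gid[is.na(gid)] <- tid[is.na(gid)]
    strand <- as.character(BiocGenerics::strand(gr))
    genome_annotation(tid, gid, as.character(GenomeInfoDb::seqnames(gr)),
                      BiocGenerics::start(gr) - 1, BiocGenerics::end(gr),
                      strand)
  } else {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop(sprintf("'%s': missing column(s) %s", path,
                   paste(miss, collapse = ", ")), call. = FALSE)
    genome_annotation(x$transcript_id, x$gene_id, x$chrom, x$start, x$end,
                      x$strand)
  }
}

#' Write a transcript annotation as TSV
#'
#' @param x a [genome_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(x, path) {
  stopifnot(inherits(x, "genome_annotation"))
  utils::write.table(as.data.frame(x)[c("transcript_id", "gene_id", "chrom",
                                        "start", "end", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Upstream intergenic distance of every transcript
#'
#' For each transcript, the distance (bp) from its TSS to the nearest boundary
#' of a transcript belonging to a *different* gene in the upstream direction
#' (5' of the TSS, strand-aware). A neighbouring gene overlapping the TSS
#' yields 0; `Inf` when no other gene lies upstream on the chromosome (minus
#' strand) and the distance to the chromosome start on the plus strand.
#'
#' @param annotation a [genome_annotation()].
#' @return Named numeric vector (names = transcript ids).
#' @export
upstream_gap <- function(annotation) {
  nb <- upstream_neighbor_bound(annotation)
  gap <- ifelse(annotation$strand == "+",
                annotation$tss - nb,
                nb - (annotation$tss + 1))
  stats::setNames(gap, annotation$transcript_id)
}

# Nearest other-gene boundary upstream of each TSS, as a clamp coordinate:
# plus strand -> largest min(end_j, tss) over other-gene transcripts starting
# before the TSS (0, i.e. chromosome start, when none); minus strand ->
# smallest max(start_j, end_i) over other-gene transcripts ending after the
# transcript end (Inf when none).
upstream_neighbor_bound <- function(annotation) {
  nb <- numeric(nrow(annotation))
  for (ch in unique(annotation$chrom)) {
    idx <- which(annotation$chrom == ch)
    a <- annotation[idx, ]
    for (r in seq_along(idx)) {
      other <- a$gene_id != a$gene_id[r]
      if (a$strand[r] == "+") {
        t0 <- a$tss[r]
        cand <- other & a$start < t0
        nb[idx[r]] <- if (any(cand)) max(pmin(a$end[cand], t0)) else 0
      } else {
        e0 <- a$end[r]
        cand <- other & a$end > e0
        nb[idx[r]] <- if (any(cand)) min(pmax(a$start[cand], e0)) else Inf
      }
    }
  }
  nb
}

# Assignment windows for summit-based peak-to-gene mapping: per transcript the
# gene body [start, end) plus the strand-aware upstream window, truncated both
# at `upstream_max` ("less than" => strict, so the window spans distances
# 1 .. upstream_max-1) and at the nearest other-gene boundary.
transcript_windows <- function(annotation, upstream_max = 3000) {
  nb <- upstream_neighbor_bound(annotation)
  plus <- annotation$strand == "+"
  up_start <- ifelse(plus,
                     pmax(annotation$tss - upstream_max + 1, nb, 0),
                     annotation$end)
  up_end <- ifelse(plus,
                   annotation$tss,
                   pmin(annotation$end + upstream_max - 1, nb))
  w <- rbind(
    data.frame(chrom = annotation$chrom, start = annotation$start,
               end = annotation$end, gene_id = annotation$gene_id,
               type = "body", stringsAsFactors = FALSE),
    data.frame(chrom = annotation$chrom, start = up_start, end = up_end,
               gene_id = annotation$gene_id, type = "upstream",
               stringsAsFactors = FALSE))
  w[w$start < w$end & is.finite(w$start), , drop = FALSE]
}
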