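#' Construct a core/flank site-sequence set
#'
#' Holds, per binding site, the core sequence around the summit and the two
#' flanking sequences that serve as the composition-matched negative control
#' for k-mer enrichment. All cores share one length, all flanks another.
#'
#' @param core,left,right character vectors (or `DNAStringSet`s) over
#'   A/C/G/T/N; equal lengths within each slot.
#' @param id site identifiers (default sequential).
#' @return List of class `site_seqs` with `DNAStringSet` slots `core`, `left`,
#'   `right` and character `id`.
#' @export
site_seqs <- function(core, left, right, id = NULL) {
  core <- Biostrings::DNAStringSet(core)
  left <- Biostrings::DNAStringSet(left)
  right <- Biostrings::DNAStringSet(right)
  n <- length(core)
  if (length(left) != n || length(right) != n)
    stop("core, left and right must have one sequence per site", call. = FALSE)
  if (n) {
    if (length(unique(Biostrings::width(core))) > 1)
      stop("all core sequences must share one length", call. = FALSE)
    if (length(unique(c(Biostrings::width(left),
                        Biostrings::width(right)))) > 1)
      stop("all flank sequences must share one length", call. = FALSE)
  }
  structure(list(core = core, left = left, right = right,
                 id = as.character(id %||% seq_len(n))),
            class = "site_seqs")
}

#' @export
print.site_seqs <- function(x, ...) {
  cat(sprintf("<site_seqs> %d sites: core %d bp, flanks %d bp each\n",
              length(x$core),
              if (length(x$core)) Biostrings::width(x$core)[1] else 0,
              if (length(x$left)) Biostrings::width(x$left)[1] else 0))
  invisible(x)
}

#' Extract core and flanking sequences around binding-site summits
#'
#' The core window is centred on the summit, `[summit - w/2, summit + w/2)`
#' for core width w, and the two flank windows of `flank_width` bp abut the
#' core on each side. Sites whose combined window would cross a chromosome
#' boundary are dropped with a warning so every retained site contributes
#' identical window denominators.
#'
#' @param dataset a [tf_dataset()].
#' @param genome a named `DNAStringSet` or path to a FASTA file.
#' @param core_width core window size in bp (default 100).
#' @param flank_width size of each flank in bp (default 200).
#' @return A [site_seqs()]; `id` gives the retained site row numbers.
#' @export
extract_core_flank <- function(dataset, genome, core_width = 100,
                               flank_width = 200) {
  if (is.character(genome) && length(genome) == 1)
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  miss <- setdiff(unique(dataset$chrom), names(genome))
  if (length(miss))
    stop(sprintf("chromosome '%s' absent from the genome", miss[1]),
         call. = FALSE)
  half <- core_width %/% 2
  c0 <- dataset$summit - half
  c1 <- c0 + core_width
  lo <- c0 - flank_width
  hi <- c1 + flank_width
  len <- Biostrings::width(genome)[match(dataset$chrom, names(genome))]
  keep <- lo >= 0 & hi <= len
  if (any(!keep))
    warning(sprintf("%d site(s) too close to a chromosome boundary dropped",
                    sum(!keep)), call. = FALSE)
  idx <- which(keep)
  grab <- function(s, e) {
    out <- character(length(idx))
    for (ch in unique(dataset$chrom[idx])) {
      i <- which(dataset$chrom[idx] == ch)
      out[i] <- as.character(Biostrings::extractAt(
        genome[[ch]], IRanges::IRanges(s[idx][i] + 1, e[idx][i])))
    }
    out
  }
  site_seqs(grab(c0, c1), grab(lo, c0), grab(c1, hi), id = idx)
}

#' Count overlapping k-mer windows in a set of sequences
#'
#' Every overlapping window of length k is counted; windows containing a
#' non-ACGT letter (e.g. N) are skipped. With `both_strands = TRUE` each
#' window is scanned on both strands and a k-mer is pooled with its reverse
#' complement under the lexicographically smaller of the two as the canonical
#' key (total scanned windows double accordingly).
#'
#' @param seqs `DNAStringSet` or character vector.
#' @param k word length (>= 1).
#' @param both_strands pool reverse complements (default `TRUE`).
#' @return Named numeric vector of counts (only k-mers observed at least
#'   once), with attribute `windows` = total number of scanned windows.
#' @export
count_kmers <- function(seqs, k, both_strands = TRUE) {
  stopifnot_scalar_number(k, "k")
  if (k < 1) stop("'k' must be >= 1", call. = FALSE)
  seqs <- Biostrings::DNAStringSet(seqs)
  seqs <- seqs[Biostrings::width(seqs) >= k]
  if (!length(seqs)) {
    out <- numeric(0); attr(out, "windows") <- 0
    return(out)
  }
  cnt <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = k))
  windows <- sum(cnt)
  if (both_strands) {
    kmers <- names(cnt)
    rc <- revcomp_chr(kmers)
    canon <- ifelse(kmers <= rc, kmers, rc)
    cnt <- vapply(split(cnt, canon), sum, numeric(1))
    windows <- 2 * windows
  }
  cnt <- cnt[cnt > 0]
  attr(cnt, "windows") <- windows
  cnt
}

#' Core-vs-flank k-mer enrichment
#'
#' Screens all k-mers for enrichment in the core windows relative to the
#' flanking windows. In the default `"windows"` mode the 2x2 table counts
#' k-mer windows vs non-matching windows in core and flank, so fold is the
#' ratio of per-window frequencies; `"presence"` mode counts sites containing
#' the k-mer at least once. The one-sided Fisher (hypergeometric) enrichment
#' p-value is reported for each table.
#'
#' @param sset a [site_seqs()] with at least one site.
#' @param k word length (default 7).
#' @param both_strands pool reverse complements (default `TRUE`).
#' @param mode `"windows"` (default) or `"presence"`.
#' @return Data frame of class `kmer_enrichment`, sorted by p-value then
#'   decreasing fold, with columns `kmer`, `core_count`, `flank_count`,
#'   `core_positions`, `flank_positions`, `fold`, `p_value`. A k-mer absent
#'   from the flanks has infinite fold with the p-value still from the table.
#' @export
kmer_enrichment <- function(sset, k = 7, both_strands = TRUE,
                            mode = c("windows", "presence")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sset, "site_seqs"))
  if (!length(sset$core)) stop("no sites in 'sset'", call. = FALSE)
  if (mode == "windows") {
    core <- count_kmers(sset$core, k, both_strands)
    flank <- count_kmers(c(sset$left, sset$right), k, both_strands)
    core_pos <- attr(core, "windows")
    flank_pos <- attr(flank, "windows")
  } else {
    per_site <- function(seqs) {
      of <- Biostrings::oligonucleotideFrequency(
        Biostrings::DNAStringSet(seqs), width = k)
      if (both_strands) {
        kmers <- colnames(of)
        rc <- revcomp_chr(kmers)
        canon <- ifelse(kmers <= rc, kmers, rc)
        of <- t(rowsum(t(of), canon))
      }
      of > 0
    }
    core <- colSums(per_site(sset$core))
    flank <- colSums(per_site(sset$left) | per_site(sset$right))
    core_pos <- length(sset$core)
    flank_pos <- length(sset$core)
  }
  kmers <- union(names(core), names(flank))
  a <- ifelse(is.na(core[kmers]), 0, core[kmers])        # core hits
  b <- ifelse(is.na(flank[kmers]), 0, flank[kmers])      # flank hits
  fold <- (a / core_pos) / (b / flank_pos)
  # one-sided enrichment tail of the hypergeometric on the 2x2 table
  p <- stats::phyper(a - 1, a + b, (core_pos - a) + (flank_pos - b),
                     core_pos, lower.tail = FALSE)
  out <- data.frame(kmer = kmers, core_count = as.numeric(a),
                    flank_count = as.numeric(b),
                    core_positions = core_pos, flank_positions = flank_pos,
                    fold = as.numeric(fold), p_value = as.numeric(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_value, -out$fold, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("kmer_enrichment", "data.frame")
  out
}

#' Fisher-Yates shuffle of core sequences
#'
#' Independently permutes the letters of every core sequence (preserving each
#' core's nucleotide multiset exactly) while leaving the flanks untouched.
#' Shuffled cores destroy positional motifs but keep composition, providing
#' the negative control in which planted-motif enrichment should collapse.
#'
#' @param sset a [site_seqs()].
#' @param seed mandatory RNG seed; identical seeds give identical shuffles.
#' @return A [site_seqs()] with shuffled cores.
#' @export
shuffle_control <- function(sset, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(inherits(sset, "site_seqs"))
  cores <- as.character(sset$core)
  shuffled <- with_local_seed(seed, vapply(strsplit(cores, ""), function(ch)
    paste(sample(ch), collapse = ""), character(1)))
  site_seqs(shuffled, sset$left, sset$right, id = sset$id)
}
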