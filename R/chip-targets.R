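#' Maximum per-base co-binding count within a site
#'
#' For one binding site, the largest number of *distinct* other transcription
#' factors whose sites cover any single base of the interval. Multiple sites
#' (or multiple stages) of one factor covering a base count once; this is the
#' per-base statistic behind the HOT-region ("highly occupied target")
#' specificity filter.
#'
#' @param site a single-row [tf_dataset()] (or list with `chrom`, `start`,
#'   `end`).
#' @param others list of [tf_dataset()] objects for the *other* factors; all
#'   stages of the site's own factor must be excluded by the caller.
#' @return Integer; 0 when nothing overlaps.
#' @export
max_other_tf_count <- function(site, others) {
  if (!length(others)) return(0L)
  tfs <- vapply(others, attr, character(1), "tf")
  w0 <- site$start[1]; w1 <- site$end[1]; ch <- site$chrom[1]
  width <- w1 - w0
  acc <- integer(width)
  for (tf in unique(tfs)) {
    ir <- do.call(rbind, lapply(others[tfs == tf], function(d)
      d[d$chrom == ch, c("start", "end"), drop = FALSE]))
    if (is.null(ir) || !nrow(ir)) next
    # clip to the window, then mark covered bases once per factor
    s <- pmax(ir$start, w0) - w0
    e <- pmin(ir$end, w1) - w0
    keep <- s < e
    if (!any(keep)) next
    hit <- logical(width)
    for (j in which(keep)) hit[(s[j] + 1):e[j]] <- TRUE
    acc <- acc + hit
  }
  if (length(acc)) max(acc) else 0L
}

# Per-chromosome run-length co-binding coverage for a whole collection:
# summing each factor's binary (reduced) coverage gives, at every base, the
# number of distinct factors bound there. Built once and shared across the
# datasets of a screen.
build_cobinding_cov <- function(collection) {
  tfs <- vapply(collection, attr, character(1), "tf")
  chroms <- unique(unlist(lapply(collection, function(d) d$chrom)))
  out <- list()
  for (ch in chroms) {
    width <- max(unlist(lapply(collection, function(d)
      d$end[d$chrom == ch])))
    per_tf <- list()
    total <- S4Vectors::Rle(0L, width)
    for (tf in unique(tfs)) {
      segs <- do.call(rbind, lapply(collection[tfs == tf], function(d)
        d[d$chrom == ch, c("start", "end"), drop = FALSE]))
      if (is.null(segs) || !nrow(segs)) next
      cov <- IRanges::coverage(
        IRanges::reduce(IRanges::IRanges(segs$start + 1, segs$end)),
        width = width)
      per_tf[[tf]] <- cov
      total <- total + cov
    }
    out[[ch]] <- list(total = total, per_tf = per_tf, width = width)
  }
  out
}

# Per-site max count of distinct *other* factors: the dataset's own factor is
# subtracted from the pooled coverage before taking window maxima.
specificity_counts <- function(dataset, collection, cov = NULL) {
  cov <- cov %||% build_cobinding_cov(collection)
  out <- integer(nrow(dataset))
  own <- attr(dataset, "tf")
  for (ch in unique(dataset$chrom)) {
    si <- which(dataset$chrom == ch)
    cc <- cov[[ch]]
    if (is.null(cc)) next
    other <- cc$total
    if (!is.null(cc$per_tf[[own]])) other <- other - cc$per_tf[[own]]
    v <- IRanges::Views(other, IRanges::IRanges(dataset$start[si] + 1,
                                                pmin(dataset$end[si],
                                                     cc$width)))
    out[si] <- as.integer(IRanges::viewMaxs(v))
  }
  out
}

#' Filter a dataset to factor-specific binding sites
#'
#' Keeps the sites that are significant for the dataset's own factor
#' (`q_value >= q_min` on the -log10 scale) and at which no base is covered by
#' more than `max_other` distinct other factors — i.e. discards promiscuously
#' co-bound (HOT-region) sites, which are poor predictors of factor-specific
#' regulation. With the defaults a site co-bound by 9 or more of the other
#' factors at any base is removed.
#'
#' @param dataset the [tf_dataset()] to filter; must be an element of
#'   `collection`.
#' @param collection list of all [tf_dataset()] objects in the compendium
#'   (including `dataset`); all stages of one factor count as that one factor.
#' @param max_other largest tolerated per-base count of distinct other factors.
#' @param q_min significance floor on the -log10 scale (5 = q-value 1e-5).
#' @param .cov internal: precomputed co-binding coverage (used by the screen).
#' @return A [tf_dataset()] with the retained sites, order preserved.
#' @export
factor_specific_sites <- function(dataset, collection, max_other = 8,
                                  q_min = 5, .cov = NULL) {
  in_coll <- any(vapply(collection, function(d)
    identical(attr(d, "tf"), attr(dataset, "tf")) &&
      identical(attr(d, "stage"), attr(dataset, "stage")), logical(1)))
  if (!in_coll)
    stop("'dataset' is not part of 'collection'", call. = FALSE)
  sig <- dataset$q_value >= q_min
  cnt <- specificity_counts(dataset, collection, cov = .cov)
  keep <- sig & cnt <= max_other
  out <- dataset[keep, , drop = FALSE]
  attr(out, "tf") <- attr(dataset, "tf")
  attr(out, "stage") <- attr(dataset, "stage")
  class(out) <- class(dataset)
  rownames(out) <- NULL
  out
}

#' Assign binding sites to target genes by summit position
#'
#' A site is assigned to every transcript whose gene body contains the summit,
#' and to every transcript whose strand-aware upstream window contains it. The
#' upstream window covers distances of strictly less than `upstream_max` bp
#' from the TSS (a summit exactly `upstream_max` bp upstream is not assigned)
#' and is truncated at the nearest boundary of a neighbouring gene, so only
#' the intergenic stretch up to the neighbour is used. The result is the union
#' of the mapped gene identifiers.
#'
#' @param dataset a [tf_dataset()]; summits are the assignment points.
#' @param annotation a [genome_annotation()].
#' @param upstream_max upstream reach in bp (strict; default 3000).
#' @return Sorted character vector of target gene ids. Summits on chromosomes
#'   absent from the annotation are skipped with a warning.
#' @export
assign_targets <- function(dataset, annotation, upstream_max = 3000) {
  w <- transcript_windows(annotation, upstream_max = upstream_max)
  assign_targets_windows(dataset, w, unique(annotation$chrom))
}

# Core of assign_targets against precomputed windows (reused by the screen so
# the neighbour index is built once per annotation).
assign_targets_windows <- function(dataset, windows, known_chroms) {
  unknown <- !(dataset$chrom %in% known_chroms)
  if (any(unknown)) {
    warning(sprintf("%d summit(s) on chromosome(s) absent from the annotation skipped",
                    sum(unknown)), call. = FALSE)
    dataset <- dataset[!unknown, , drop = FALSE]
  }
  hits <- character(0)
  for (ch in unique(dataset$chrom)) {
    s <- dataset$summit[dataset$chrom == ch]
    wc <- windows[windows$chrom == ch, , drop = FALSE]
    if (!nrow(wc) || !length(s)) next
    ov <- IRanges::findOverlaps(IRanges::IRanges(s + 1, s + 1),
                                IRanges::IRanges(wc$start + 1, wc$end))
    hits <- c(hits, wc$gene_id[S4Vectors::subjectHits(ov)])
  }
  sort(unique(hits))
}

#' Overlap enrichment of two gene sets within a universe
#'
#' Tests whether `targets` and `query` overlap more than expected by chance in
#' `universe`, via the 2x2 contingency table. The exact hypergeometric
#' (Fisher) test is used unless both the observed and the expected overlap
#' exceed 5, in which case the classical chi-square approximation (no
#' continuity correction) is applied. The default p-value is the one-sided
#' enrichment tail; `two_sided = TRUE` doubles it (capped at 1).
#'
#' @param targets,query character vectors of gene ids; members outside
#'   `universe` are dropped with a warning.
#' @param universe character vector of all genes eligible for both sets.
#' @param two_sided report a two-sided p-value.
#' @return An object of class `enrichment_result`: list with `n_overlap`,
#'   `n_targets`, `n_query`, `n_universe`, `expected`, `fold`
#'   (`(n_overlap/n_targets) / (n_query/n_universe)`), `p_value`, `test_used`.
#' @export
overlap_enrichment <- function(targets, query, universe, two_sided = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  targets <- unique(targets); query <- unique(query)
  out_t <- setdiff(targets, universe); out_q <- setdiff(query, universe)
  if (length(out_t) || length(out_q))
    warning(sprintf("%d target(s) and %d query gene(s) outside the universe dropped",
                    length(out_t), length(out_q)), call. = FALSE)
  targets <- intersect(targets, universe)
  query <- intersect(query, universe)
  N <- length(universe); nt <- length(targets); nq <- length(query)
  k <- length(intersect(targets, query))
  expected <- nt * nq / N
  if (nt == 0) {
    res <- list(n_overlap = 0L, n_targets = 0L, n_query = nq, n_universe = N,
                expected = 0, fold = NA_real_, p_value = 1,
                test_used = "exact")
    class(res) <- "enrichment_result"
    return(res)
  }
  fold <- (k / nt) / (nq / N)
  # chi-square approximation only where classical conditions hold and the
  # table is non-degenerate (no zero margin)
  margins_ok <- all(c(nq, N - nq, nt, N - nt) > 0)
  if (k > 5 && expected > 5 && margins_ok) {
    test_used <- "chi_square"
    tab <- matrix(c(k, nt - k, nq - k, N - nt - nq + k), 2)
    e <- outer(rowSums(tab), colSums(tab)) / N
    x2 <- sum((tab - e)^2 / e)
    z <- sign(k - expected) * sqrt(x2)
    p1 <- stats::pnorm(z, lower.tail = FALSE)
  } else {
    test_used <- "exact"
    p1 <- stats::phyper(k - 1, nq, N - nq, nt, lower.tail = FALSE)
  }
  p <- if (two_sided) min(1, 2 * p1) else p1
  res <- list(n_overlap = k, n_targets = nt, n_query = nq, n_universe = N,
              expected = expected, fold = fold, p_value = p,
              test_used = test_used)
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment> %d/%d targets in query of %d (universe %d): %.2f-fold, p = %.3g (%s)\n",
              x$n_overlap, x$n_targets, x$n_query, x$n_universe,
              x$fold, x$p_value, x$test_used))
  invisible(x)
}

#' Screen a ChIP-seq compendium for candidate regulators of a gene label set
#'
#' Runs the full target-calling chain on every factor/stage dataset: datasets
#' with fewer than `min_sites` significant sites are excluded (reported as
#' skipped); for the rest, factor-specific sites are selected, assigned to
#' genes by summit, and the target set is tested for overlap enrichment with
#' `query` in `universe`. Datasets with enrichment `p < alpha` are flagged as
#' candidate regulators.
#'
#' @param collection list of [tf_dataset()] objects, one per factor x stage.
#' @param query character vector of label genes (e.g. age-regulated genes).
#' @param annotation a [genome_annotation()].
#' @param universe gene universe; default all genes in the annotation.
#' @param alpha enrichment significance cutoff for flagging.
#' @param min_sites minimum number of significant sites for a dataset to be
#'   tested.
#' @param max_other,q_min,upstream_max passed to [factor_specific_sites()] and
#'   [assign_targets()].
#' @return A data frame of class `screen_report`, one row per dataset, with
#'   columns `tf`, `stage`, `n_significant`, `n_specific`, `n_targets`,
#'   `n_overlap`, `fold`, `p_value`, `test_used`, `skipped`, `flagged`.
#' @export
screen_regulators <- function(collection, query, annotation, universe = NULL,
                              alpha = 1e-5, min_sites = 100, max_other = 8,
                              q_min = 5, upstream_max = 3000) {
  if (!length(collection)) {
    rep0 <- data.frame(tf = character(0), stage = character(0),
                       n_significant = integer(0), n_specific = integer(0),
                       n_targets = integer(0), n_overlap = integer(0),
                       fold = numeric(0), p_value = numeric(0),
                       test_used = character(0), skipped = logical(0),
                       flagged = logical(0))
    class(rep0) <- c("screen_report", "data.frame")
    return(rep0)
  }
  universe <- universe %||% unique(annotation$gene_id)
  windows <- transcript_windows(annotation, upstream_max = upstream_max)
  known <- unique(annotation$chrom)
  cov <- build_cobinding_cov(collection)
  query <- intersect(unique(query), universe)
  rows <- lapply(collection, function(d) {
    n_sig <- sum(d$q_value >= q_min)
    if (n_sig < min_sites)
      return(data.frame(tf = attr(d, "tf"), stage = attr(d, "stage"),
                        n_significant = n_sig, n_specific = NA_integer_,
                        n_targets = NA_integer_, n_overlap = NA_integer_,
                        fold = NA_real_, p_value = NA_real_,
                        test_used = NA_character_, skipped = TRUE,
                        flagged = FALSE, stringsAsFactors = FALSE))
    spec <- factor_specific_sites(d, collection, max_other = max_other,
                                  q_min = q_min, .cov = cov)
    targets <- intersect(
      assign_targets_windows(spec, windows, known), universe)
    enr <- overlap_enrichment(targets, query, universe)
    data.frame(tf = attr(d, "tf"), stage = attr(d, "stage"),
               n_significant = n_sig, n_specific = nrow(spec),
               n_targets = length(targets), n_overlap = enr$n_overlap,
               fold = enr$fold, p_value = enr$p_value,
               test_used = enr$test_used, skipped = FALSE,
               flagged = is.finite(enr$p_value) && enr$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  attr(rep, "alpha") <- alpha
  class(rep) <- c("screen_report", "data.frame")
  rep
}

#' @export
print.screen_report <- function(x, ...) {
  if (is.null(x$skipped)) {  # column subset: plain data-frame printing
    NextMethod()
    return(invisible(x))
  }
  cat(sprintf("<screen_report> %d dataset(s): %d tested, %d skipped, %d flagged (alpha = %g)\n",
              nrow(x), sum(!x$skipped), sum(x$skipped), sum(x$flagged),
              attr(x, "alpha") %||% NA))
  df <- as.data.frame(x)
  class(df) <- "data.frame"
  print(utils::head(df[order(x$p_value), ], 10))
  invisible(x)
}
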