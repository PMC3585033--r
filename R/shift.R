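#' Mean-centered log2 fold-changes per gene
#'
#' For each replicate pair i, the per-gene log2 fold-change
#' `log2((treatment_i + pseudocount) / (control_i + pseudocount))` is
#' computed, then centred by subtracting the replicate's mean over all genes
#' (removing global shifts such as compositional effects from a few very
#' highly expressed transcripts). The per-gene summary is the average of the
#' centred values across replicates.
#'
#' @param counts a paired [count_matrix()] (ideally already expression
#'   filtered).
#' @param pseudocount added inside the ratio; set to 0 for an already
#'   pseudocounted matrix (default 1).
#' @return List of class `fc_profile`: `lfc` and `centered` (genes x
#'   replicates matrices) and `summary` (named per-gene vector).
#' @export
mean_centered_fold_changes <- function(counts, pseudocount = 1) {
  pr <- cm_pairs(counts)
  m <- unclass(counts)
  lfc <- log2((m[, pr$treatment, drop = FALSE] + pseudocount) /
                (m[, pr$control, drop = FALSE] + pseudocount))
  colnames(lfc) <- paste0("rep", pr$replicate)
  centered <- sweep(lfc, 2, colMeans(lfc))
  structure(list(lfc = lfc, centered = centered,
                 summary = stats::setNames(rowMeans(centered), rownames(m))),
            class = "fc_profile")
}

#' @export
print.fc_profile <- function(x, ...) {
  cat(sprintf("<fc_profile> %d genes, %d replicates; summary fold-change range [%.2f, %.2f] (log2)\n",
              length(x$summary), ncol(x$lfc), min(x$summary), max(x$summary)))
  invisible(x)
}

#' Distribution shift of a gene set's fold-changes
#'
#' Two-sample Kolmogorov-Smirnov test comparing the summary mean-centered
#' fold-changes of the genes in `set` against the complement (default) or the
#' full profile, to detect a coordinate expression shift of the set. The
#' direction is the sign of the difference in medians.
#'
#' @param profile an [mean_centered_fold_changes()] profile.
#' @param set character vector of gene ids; at least 3 must intersect the
#'   profile.
#' @param against `"complement"` (default; keeps the two samples disjoint) or
#'   `"all"`.
#' @param threshold linear fold-change threshold for the reported percentage
#'   (default 1.25).
#' @param name label carried into the result.
#' @return List of class `shift_result`: `name`, `n_set`, `D`, `p_value`,
#'   `direction` (`"increased"`/`"decreased"`), `pct_above_threshold`.
#' @export
gene_set_shift <- function(profile, set, against = c("complement", "all"),
                           threshold = 1.25, name = "set") {
  against <- match.arg(against)
  stopifnot(inherits(profile, "fc_profile"))
  genes <- names(profile$summary)
  set <- intersect(unique(set), genes)
  if (length(set) < 3)
    stop("fewer than 3 set genes present in the profile", call. = FALSE)
  other <- if (against == "complement") setdiff(genes, set) else genes
  if (!length(other))
    stop("set covers the whole profile; no background remains", call. = FALSE)
  xs <- profile$summary[set]
  xo <- profile$summary[other]
  ks <- suppressWarnings(stats::ks.test(xs, xo))
  structure(list(name = name, n_set = length(set),
                 D = unname(ks$statistic), p_value = ks$p.value,
                 direction = if (stats::median(xs) >= stats::median(xo))
                   "increased" else "decreased",
                 pct_above_threshold = fraction_above(profile, set,
                                                      threshold = threshold)),
            class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf("<shift> %s (n = %d): D = %.3f, p = %.3g, %s; %.1f%% with fold >= threshold\n",
              x$name, x$n_set, x$D, x$p_value, x$direction,
              x$pct_above_threshold))
  invisible(x)
}

#' Percent of genes at or above a fold-change threshold
#'
#' The percentage of genes in `set` whose summary fold-change `2^summary` is
#' at least `threshold` on the linear scale (inclusive: a gene at exactly the
#' threshold counts).
#'
#' @param profile an [mean_centered_fold_changes()] profile.
#' @param set gene ids (default: all profiled genes); must be non-empty after
#'   intersection.
#' @param threshold linear fold-change (default 1.25).
#' @return Percentage in `[0, 100]`.
#' @export
fraction_above <- function(profile, set = NULL, threshold = 1.25) {
  stopifnot(inherits(profile, "fc_profile"))
  genes <- names(profile$summary)
  set <- if (is.null(set)) genes else intersect(unique(set), genes)
  if (!length(set)) stop("empty gene set", call. = FALSE)
  100 * mean(2^profile$summary[set] >= threshold)
}

#' Construct a qPCR Ct table
#'
#' @param sample,gene character vectors (one entry per measurement).
#' @param ct numeric Ct values (> 0); `NA` marks an undetected measurement.
#' @return Data frame of class `ct_table`.
#' @export
ct_table <- function(sample, gene, ct) {
  if (any(!is.na(ct) & ct <= 0)) stop("Ct values must be > 0", call. = FALSE)
  x <- data.frame(sample = as.character(sample), gene = as.character(gene),
                  ct = as.numeric(ct), stringsAsFactors = FALSE)
  class(x) <- c("ct_table", "data.frame")
  x
}

#' Relative expression ratio by the delta-delta-Ct method
#'
#' Computes `ddct = (Ct_target,a - Ct_ref,a) - (Ct_target,b - Ct_ref,b)` and
#' the expression ratio `2^(-ddct)` of the target gene in sample `a` relative
#' to sample `b`, normalised to a single reference gene. If the target is
#' undetected (NA) in a sample its Ct is set to `ct_ceiling` (default 40, the
#' last qPCR cycle) and the result is flagged as a bound rather than an
#' estimate. An undetected reference gene is an error.
#'
#' @param ct a [ct_table()].
#' @param target_gene,reference gene ids.
#' @param sample_a,sample_b sample ids; the ratio is a relative to b.
#' @param ct_ceiling upper-bound Ct substituted for undetected targets.
#' @return List of class `ddct_result`: `ratio`, `ddct`, `bound` (logical).
#' @export
ddct_ratio <- function(ct, target_gene, sample_a, sample_b, reference,
                       ct_ceiling = 40) {
  stopifnot(inherits(ct, "ct_table"))
  get_ct <- function(g, s) {
    i <- which(ct$gene == g & ct$sample == s)
    if (!length(i))
      stop(sprintf("no measurement for gene '%s' in sample '%s'", g, s),
           call. = FALSE)
    mean(ct$ct[i])  # technical replicates averaged
  }
  ref_a <- get_ct(reference, sample_a)
  ref_b <- get_ct(reference, sample_b)
  if (is.na(ref_a) || is.na(ref_b))
    stop("reference gene undetected", call. = FALSE)
  tgt_a <- get_ct(target_gene, sample_a)
  tgt_b <- get_ct(target_gene, sample_b)
  bound <- is.na(tgt_a) || is.na(tgt_b)
  if (is.na(tgt_a)) tgt_a <- ct_ceiling
  if (is.na(tgt_b)) tgt_b <- ct_ceiling
  ddct <- (tgt_a - ref_a) - (tgt_b - ref_b)
  structure(list(ratio = 2^(-ddct), ddct = ddct, bound = bound),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("<ddct> ratio = %.3g (ddCt = %.2f)%s\n", x$ratio, x$ddct,
              if (x$bound) " [bound: target undetected, Ct ceiling applied]"
              else ""))
  invisible(x)
}
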