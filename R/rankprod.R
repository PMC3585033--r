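#' Collapse transcripts to the major isoform per gene
#'
#' For genes with multiple annotated isoforms, only the transcript with the
#' highest mean count across *all* samples (both conditions) is retained; ties
#' are broken by the lexicographically smallest transcript id. Rows are
#' re-labelled with gene ids.
#'
#' @param counts a [count_matrix()] with transcript rows.
#' @param gene_map named character vector mapping transcript id to gene id;
#'   must cover every row.
#' @return A [count_matrix()] with one row per gene, carrying the chosen
#'   transcript ids in attribute `selected_transcript` (named by gene).
#' @export
select_major_isoform <- function(counts, gene_map) {
  tx <- rownames(counts)
  miss <- setdiff(tx, names(gene_map))
  if (length(miss))
    stop(sprintf("transcript '%s' missing from gene_map", miss[1]),
         call. = FALSE)
  gene <- gene_map[tx]
  m <- rowMeans(unclass(counts))
  ord <- order(gene, -m, tx)  # per gene: highest mean first, then lexicographic
  first <- ord[!duplicated(gene[ord])]
  sel <- sort(first)
  out <- unclass(counts)[sel, , drop = FALSE]
  picked <- stats::setNames(tx[sel], gene[sel])
  rownames(out) <- gene[sel]
  out <- cm_like(out, counts)
  attr(out, "selected_transcript") <- picked
  out
}

#' Expression filter and pseudocount for rank-products analysis
#'
#' Keeps genes observed with at least `min_reads` reads in *every* control
#' column or in *every* treatment column (either condition suffices), then
#' adds a pseudocount to every retained cell so fold-changes are defined for
#' zero counts.
#'
#' @param counts a [count_matrix()].
#' @param min_reads expression floor (default 10).
#' @param pseudocount value added to each retained cell (default 1).
#' @return A filtered, pseudocounted [count_matrix()].
#' @export
filter_and_pseudocount <- function(counts, min_reads = 10, pseudocount = 1) {
  cond <- attr(counts, "condition")
  m <- unclass(counts)
  keep <- apply(m[, cond == "control", drop = FALSE] >= min_reads, 1, all) |
    apply(m[, cond == "treatment", drop = FALSE] >= min_reads, 1, all)
  cm_like(m[keep, , drop = FALSE] + pseudocount, counts)
}

#' Per-replicate fold-change ranks
#'
#' For each replicate pair i, the fold-change `treatment_i / control_i` is
#' computed per gene and ranked within the replicate: `direction = "down"`
#' ranks by increasing fold-change (rank 1 = most down-regulated),
#' `direction = "up"` by decreasing fold-change. Tied fold-changes receive the
#' average of the tied rank positions.
#'
#' @param counts a pseudocounted [count_matrix()] (no zero denominators).
#' @param direction `"down"` or `"up"`.
#' @return Numeric matrix, genes x replicates, of ranks in 1..G.
#' @export
replicate_fc_ranks <- function(counts, direction = c("down", "up")) {
  direction <- match.arg(direction)
  pr <- cm_pairs(counts)
  m <- unclass(counts)
  if (any(m[, pr$control] == 0))
    stop("zero control counts: apply filter_and_pseudocount() first",
         call. = FALSE)
  fc <- m[, pr$treatment, drop = FALSE] / m[, pr$control, drop = FALSE]
  r <- apply(fc, 2, function(v)
    if (direction == "down") rank(v) else rank(-v))
  rownames(r) <- rownames(m)
  colnames(r) <- paste0("rep", pr$replicate)
  r
}

#' Rank product per gene
#'
#' The product of a gene's fold-change ranks across replicates; a small rank
#' product indicates consistently extreme regulation in the chosen direction.
#'
#' @param ranks genes x replicates rank matrix from [replicate_fc_ranks()].
#' @return Named numeric vector of rank products.
#' @export
rank_product <- function(ranks) {
  apply(as.matrix(ranks), 1, prod)
}

# Shared permutation engine. For each of n_perm draws, each replicate's rank
# column is independently permuted and per-gene null rank products formed; the
# count of null values at or below each observed rank product is accumulated.
# `rank_mats` is a named list of rank matrices (all G x k, same dimensions)
# evaluated against the same permutation draws, which is what makes
# up/down analyses and label-swap symmetry share a null exactly.
rp_perm_counts <- function(rank_mats, n_perm, seed) {
  # rank products overflow 32-bit integers already at G ~ 1300 for k = 3
  rank_mats <- lapply(rank_mats, function(r) {
    storage.mode(r) <- "double"
    r
  })
  G <- nrow(rank_mats[[1]]); k <- ncol(rank_mats[[1]])
  obs <- lapply(rank_mats, function(r) apply(r, 1, prod))
  ord <- lapply(obs, order)
  sorted <- Map(function(o, od) o[od], obs, ord)
  counts <- lapply(obs, function(o) numeric(G))
  with_local_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- lapply(seq_len(k), function(j) sample.int(G))
      for (nm in names(rank_mats)) {
        r <- rank_mats[[nm]]
        null_rp <- r[idx[[1]], 1]
        for (j in seq_len(k)[-1]) null_rp <- null_rp * r[idx[[j]], j]
        counts[[nm]] <- counts[[nm]] +
          findInterval(sorted[[nm]], sort(null_rp))
      }
    }
  })
  # map counts (aligned to sorted order) back to gene order
  Map(function(cnt, od, o) {
    out <- numeric(G); out[od] <- cnt
    stats::setNames(out, names(o))
  }, counts, ord, obs)
}

# Turn observed rank products + accumulated null tail counts into the
# reported statistics.
rp_statistics <- function(rp, null_count, n_perm) {
  G <- length(rp)
  e_value <- null_count / n_perm
  # smoothed permutation probability of seeing an RP at least this small
  p_rp <- (null_count / G + 1) / (n_perm + 1)
  position <- rank(rp, ties.method = "max")
  pfp_raw <- e_value / position
  ord <- order(rp)
  pfp_sorted <- rev(cummin(rev(pfp_raw[ord])))
  pfp <- numeric(G); pfp[ord] <- pfp_sorted
  data.frame(rp = rp, p_rp = p_rp, e_value = e_value, pfp = pfp,
             position = position, row.names = names(rp))
}

#' Permutation significance of rank products
#'
#' Converts observed rank products into permutation statistics by permuting
#' each replicate's rank column independently `n_perm` times. For gene g with
#' rank product `rp_g`, let `c_g` be the number of null per-gene rank products
#' (pooled over all genes and permutations) at or below `rp_g`. Then
#' `e_value = c_g / n_perm` is the expected number of genes at or below this
#' rank product under the null, `p_rp = (c_g / G + 1) / (n_perm + 1)` is the
#' smoothed per-gene null probability, and `pfp = e_value / position` (the
#' gene's 1-based position in the RP-sorted list, ties sharing the maximal
#' position) is the percent-false-positive rate, made monotone non-decreasing
#' down the sorted list so gene lists at a cutoff are contiguous.
#'
#' @param ranks genes x replicates rank matrix.
#' @param n_perm number of permutations (>= 1).
#' @param seed mandatory RNG seed; identical seeds give identical output.
#' @return Data frame with columns `rp`, `p_rp`, `e_value`, `pfp`, `position`,
#'   row names as in `ranks`.
#' @export
permutation_significance <- function(ranks, n_perm = 10000, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot_scalar_number(n_perm, "n_perm")
  if (n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
  ranks <- as.matrix(ranks)
  cnt <- rp_perm_counts(list(x = ranks), n_perm = n_perm, seed = seed)$x
  rp_statistics(apply(ranks, 1, prod), cnt, n_perm)
}

#' Call differentially expressed genes from directional rank-product results
#'
#' A gene is called in a direction when its PFP is at or below `pfp_cutoff`
#' *and* it lies in the top third of fold-changes (rank `<= floor(G/3)`) in
#' that direction in every replicate. Genes passing the PFP cutoff but failing
#' the replicate-consistency requirement are reported separately.
#'
#' @param up_results,down_results data frames from
#'   [permutation_significance()] for the up and down rankings, over the same
#'   genes.
#' @param ranks_up,ranks_down the matching rank matrices.
#' @param pfp_cutoff PFP threshold (default 0.10).
#' @return List of class `de_calls`: `up`, `down` (character vectors of gene
#'   ids), `discarded_for_consistency`, `pfp_cutoff`.
#' @export
call_de <- function(up_results, down_results, ranks_up, ranks_down,
                    pfp_cutoff = 0.10) {
  G <- nrow(ranks_up)
  top <- floor(G / 3)
  consistent <- function(r) apply(as.matrix(r) <= top, 1, all)
  pass_up <- up_results$pfp <= pfp_cutoff
  pass_down <- down_results$pfp <= pfp_cutoff
  cons_up <- consistent(ranks_up)
  cons_down <- consistent(ranks_down)
  genes <- rownames(ranks_up)
  up <- genes[pass_up & cons_up]
  down <- genes[pass_down & cons_down]
  if (length(intersect(up, down)))
    stop("gene called in both directions; rank input is inconsistent",
         call. = FALSE)
  disc <- unique(c(genes[pass_up & !cons_up], genes[pass_down & !cons_down]))
  structure(list(up = up, down = down,
                 discarded_for_consistency = disc,
                 pfp_cutoff = pfp_cutoff),
            class = "de_calls")
}

#' @export
print.de_calls <- function(x, ...) {
  cat(sprintf("<de_calls> PFP <= %g: %d up, %d down (%d discarded for replicate consistency)\n",
              x$pfp_cutoff, length(x$up), length(x$down),
              length(x$discarded_for_consistency)))
  invisible(x)
}

#' Fit a rank-products differential-expression model
#'
#' The front end of the rank-products procedure for replicated paired count
#' data (here triplicate 3'-tag RNA-seq of treatment vs control). The counts
#' are optionally collapsed to major isoforms, filtered to genes with at least
#' `min_reads` reads in all columns of either condition, pseudocounted, and
#' ranked by per-replicate fold-change in both directions. Permutation
#' statistics for both directions are computed in a single pass over shared
#' permutation draws, and genes are called at the PFP cutoff subject to the
#' top-third replicate-consistency requirement.
#'
#' @param counts a [count_matrix()] (transcript or gene rows).
#' @param gene_map optional transcript-to-gene map; triggers
#'   [select_major_isoform()].
#' @param min_reads,pseudocount see [filter_and_pseudocount()].
#' @param n_perm number of rank permutations (default 10000).
#' @param pfp_cutoff PFP call threshold (default 0.10).
#' @param seed mandatory RNG seed.
#' @return An object of class `rank_prod`: list with `table` (per-gene data
#'   frame: mean log2 fold-change, per-direction rank product, `p_rp`,
#'   `e_value`, `pfp`, call), `calls` (a `de_calls` object), `ranks_up`,
#'   `ranks_down`, and the fitting parameters. Methods: `print`, `summary`,
#'   `plot`, `as.data.frame`.
#' @examples
#' sim <- simulate_counts(n_genes = 300, frac_up = 0.05, frac_down = 0.05,
#'                        lfc = 2, lib_size = 1e5, seed = 1)
#' fit <- rank_prod(sim$counts, n_perm = 200, seed = 2)
#' fit
#' @export
rank_prod <- function(counts, gene_map = NULL, min_reads = 10,
                      pseudocount = 1, n_perm = 10000, pfp_cutoff = 0.10,
                      seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (!is.null(gene_map)) counts <- select_major_isoform(counts, gene_map)
  filtered <- filter_and_pseudocount(counts, min_reads = min_reads,
                                     pseudocount = pseudocount)
  if (!nrow(filtered)) stop("no genes pass the expression filter", call. = FALSE)
  ranks_down <- replicate_fc_ranks(filtered, "down")
  ranks_up <- replicate_fc_ranks(filtered, "up")
  cnt <- rp_perm_counts(list(down = ranks_down, up = ranks_up),
                        n_perm = n_perm, seed = seed)
  res_down <- rp_statistics(apply(ranks_down, 1, prod), cnt$down, n_perm)
  res_up <- rp_statistics(apply(ranks_up, 1, prod), cnt$up, n_perm)
  calls <- call_de(res_up, res_down, ranks_up, ranks_down,
                   pfp_cutoff = pfp_cutoff)
  pr <- cm_pairs(filtered)
  m <- unclass(filtered)
  lfc <- log2(m[, pr$treatment, drop = FALSE] / m[, pr$control, drop = FALSE])
  genes <- rownames(filtered)
  tab <- data.frame(
    gene = genes,
    mean_lfc = rowMeans(lfc),
    rp_down = res_down$rp, pfp_down = res_down$pfp,
    e_down = res_down$e_value, p_down = res_down$p_rp,
    rp_up = res_up$rp, pfp_up = res_up$pfp,
    e_up = res_up$e_value, p_up = res_up$p_rp,
    call = ifelse(genes %in% calls$up, "up",
                  ifelse(genes %in% calls$down, "down", "none")),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, calls = calls,
                 ranks_up = ranks_up, ranks_down = ranks_down,
                 n_genes = nrow(filtered), n_reps = length(pr$replicate),
                 n_perm = n_perm, pfp_cutoff = pfp_cutoff,
                 min_reads = min_reads, pseudocount = pseudocount,
                 seed = seed, call = match.call()),
            class = "rank_prod")
}

#' @export
print.rank_prod <- function(x, ...) {
  cat("Rank-products differential expression\n")
  cat(sprintf("  %d genes after filtering, %d replicate pairs, %d permutations\n",
              x$n_genes, x$n_reps, x$n_perm))
  cat(sprintf("  PFP <= %g: %d genes up, %d down (%d discarded for replicate consistency)\n",
              x$pfp_cutoff, length(x$calls$up), length(x$calls$down),
              length(x$calls$discarded_for_consistency)))
  invisible(x)
}

#' @export
summary.rank_prod <- function(object, n = 5, ...) {
  print(object)
  tab <- object$table
  for (dir in c("down", "up")) {
    pfp <- tab[[paste0("pfp_", dir)]]
    top <- tab[order(pfp, tab[[paste0("rp_", dir)]]), ][seq_len(min(n, nrow(tab))), ]
    cat(sprintf("\nTop %s-regulated genes:\n", dir))
    print(top[, c("gene", "mean_lfc", paste0("rp_", dir),
                  paste0("e_", dir), paste0("pfp_", dir), "call")],
          row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' @export
as.data.frame.rank_prod <- function(x, ...) x$table

#' Plot PFP profiles of a rank-products fit
#'
#' Draws the monotone PFP against the RP-sorted gene position for both
#' directions, with the call cutoff as a horizontal line.
#'
#' @param x a [rank_prod()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rank_prod <- function(x, ...) {
  tab <- x$table
  od <- order(tab$rp_down); ou <- order(tab$rp_up)
  graphics::plot(seq_len(nrow(tab)), pmin(tab$pfp_down[od], 1), type = "s",
                 log = "x", xlab = "gene position (RP-sorted)",
                 ylab = "PFP", col = "steelblue", ylim = c(0, 1), ...)
  graphics::lines(seq_len(nrow(tab)), pmin(tab$pfp_up[ou], 1), type = "s",
                  col = "firebrick")
  graphics::abline(h = x$pfp_cutoff, lty = 2)
  graphics::legend("bottomright", c("down", "up"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
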