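# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's vectorised/indexed code paths:
# everything here is a direct per-base / per-transcript / per-configuration
# loop over the definition.

# Per-base count of distinct other factors covering any base of [start, end),
# by explicit base iteration.
brute_max_other <- function(chrom, start, end, others) {
  best <- 0L
  for (p in seq(start, end - 1)) {
    n <- 0L
    for (tf in unique(vapply(others, attr, character(1), "tf"))) {
      covered <- FALSE
      for (d in others[vapply(others, attr, character(1), "tf") == tf]) {
        hit <- d$chrom == chrom & d$start <= p & p < d$end
        if (any(hit)) covered <- TRUE
      }
      if (covered) n <- n + 1L
    }
    best <- max(best, n)
  }
  best
}

# Summit-to-gene assignment by exhaustive per-transcript check of the rule:
# summit in the gene body, or strictly less than `upstream_max` bp upstream of
# the TSS with no neighbouring gene's transcript in between.
brute_assign <- function(dataset, annotation, upstream_max = 3000) {
  hits <- character(0)
  for (si in seq_len(nrow(dataset))) {
    ch <- dataset$chrom[si]; s <- dataset$summit[si]
    for (ti in seq_len(nrow(annotation))) {
      if (annotation$chrom[ti] != ch) next
      a <- annotation[ti, ]
      if (a$start <= s && s < a$end) { hits <- c(hits, a$gene_id); next }
      dist <- if (a$strand == "+") a$tss - s else s - a$tss
      if (dist <= 0 || dist >= upstream_max) next
      # truncation: no transcript of another gene may cover any base strictly
      # between the summit and the gene (the neighbouring gene's extent wins)
      blocked <- FALSE
      for (tj in seq_len(nrow(annotation))) {
        b <- annotation[tj, ]
        if (b$chrom != ch || b$gene_id == a$gene_id) next
        bound <- if (a$strand == "+") min(b$end, a$tss) else max(b$start, a$end)
        if (a$strand == "+") {
          if (b$start < a$tss && s < bound) blocked <- TRUE
        } else {
          if (b$end > a$end && s >= bound) blocked <- TRUE
        }
      }
      if (!blocked) hits <- c(hits, a$gene_id)
    }
  }
  sort(unique(hits))
}

# Hypergeometric enrichment tail by direct summation.
brute_hyper_tail <- function(k, n_targets, n_query, n_universe) {
  ks <- k:min(n_targets, n_query)
  sum(stats::dhyper(ks, n_query, n_universe - n_query, n_targets))
}

# Exact rank-product null statistics for G genes, k replicates: expected
# number of genes with RP <= t under independent uniform rank columns is
# G * P(prod of k iid uniform{1..G} <= t); enumerated over the G^k rank
# combinations (each combination occurs ((G-1)!)^k times per gene among the
# (G!)^k configurations, so this equals literal enumeration -- verified
# against a literal loop in the unit tests).
exact_e_value <- function(t, G, k) {
  combos <- as.matrix(expand.grid(rep(list(seq_len(G)), k)))
  rp <- apply(combos, 1, prod)
  G * mean(rp <= t)
}

# A small random annotation with n genes on one chromosome.
random_annotation <- function(n, chrom_len = 50000, seed) {
  set.seed(seed)
  len <- sample(200:1500, n, replace = TRUE)
  gaps <- sample(0:2500, n + 1, replace = TRUE)
  starts <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, len[-n]))
  genome_annotation(sprintf("t%03d.1", seq_len(n)), sprintf("t%03d", seq_len(n)),
                    "chrZ", starts, starts + len,
                    sample(c("+", "-"), n, replace = TRUE))
}

# A random tf_dataset of n sites on one chromosome.
random_sites <- function(n, tf, chrom = "chrZ", span = 50000, width_max = 60,
                         stage = "NA") {
  start <- sample.int(span - width_max, n, replace = TRUE)
  w <- sample.int(width_max, n, replace = TRUE)
  summit <- start + vapply(w, function(x) sample.int(x, 1) - 1L, integer(1))
  tf_dataset(chrom, start, start + w, summit,
             stats::runif(n, 0, 12), tf = tf, stage = stage)
}

# A tiny balanced paired count matrix from a plain matrix.
cm3 <- function(m) {
  k <- ncol(m) / 2
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- c(paste0("c", seq_len(k)), paste0("t", seq_len(k)))
  count_matrix(m, rep(c("control", "treatment"), each = k),
               rep(seq_len(k), 2))
}

# Random DNA as character strings.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}
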