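#' Simulate a genome annotation and sequence
#'
#' Places non-overlapping genes (one transcript each) with random strands and
#' random intergenic gaps on `n_chrom` chromosomes, and optionally draws an
#' i.i.d. uniform A/C/G/T sequence. Gene lengths are gamma distributed with
#' the requested mean. Deterministic given the seed.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp (scalar, or one per chromosome).
#' @param n_genes total number of genes to place.
#' @param mean_gene_len mean gene length in bp.
#' @param seed mandatory RNG seed.
#' @param sequence draw the nucleotide sequence (default `TRUE`); `FALSE`
#'   skips it for interval-only simulations.
#' @return List with `annotation` (a [genome_annotation()] carrying chromosome
#'   lengths) and `genome` (`DNAStringSet`, or `NULL` when `sequence = FALSE`).
#' @export
simulate_genome <- function(n_chrom = 5, chrom_len = 1e6, n_genes = 1000,
                            mean_gene_len = 1000, seed, sequence = TRUE) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  chrom_len <- rep_len(chrom_len, n_chrom)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  with_local_seed(seed, {
    # apportion genes to chromosomes proportionally to length
    per <- diff(round(cumsum(c(0, chrom_len / sum(chrom_len))) * n_genes))
    rows <- vector("list", n_chrom)
    gi <- 0L
    for (ci in seq_len(n_chrom)) {
      nc <- per[ci]
      if (nc == 0) next
      len <- pmax(60, round(stats::rgamma(nc, shape = 4,
                                          scale = mean_gene_len / 4)))
      slack <- chrom_len[ci] - sum(len)
      if (slack < 0)
        stop(sprintf("cannot place %d genes of mean length %g on a %g bp chromosome",
                     nc, mean_gene_len, chrom_len[ci]), call. = FALSE)
      gaps <- as.vector(stats::rmultinom(1, slack, rep(1, nc + 1)))
      starts <- cumsum(gaps[seq_len(nc)]) + cumsum(c(0, len[-nc]))
      ids <- sprintf("g%05d", gi + seq_len(nc))
      gi <- gi + nc
      rows[[ci]] <- data.frame(
        transcript_id = paste0(ids, ".1"), gene_id = ids,
        chrom = chroms[ci], start = starts, end = starts + len,
        strand = sample(c("+", "-"), nc, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    g <- do.call(rbind, rows)
    ann <- genome_annotation(g$transcript_id, g$gene_id, g$chrom, g$start,
                             g$end, g$strand,
                             chrom_len = stats::setNames(chrom_len, chroms))
    genome <- NULL
    if (sequence) {
      genome <- Biostrings::DNAStringSet(vapply(chrom_len, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1)))
      names(genome) <- chroms
    }
    list(annotation = ann, genome = genome)
  })
}

#' Simulate a multi-factor binding-site collection with a planted regulator
#'
#' Emulates the structure of a multi-factor ChIP-seq compendium: a fraction of
#' each factor's sites fall at shared, co-bound (HOT) loci, jittered a few bp
#' per factor so per-base co-binding counts vary; the remaining sites are
#' factor-private, each placed with its summit inside a randomly chosen gene
#' body. One designated factor's private target genes overlap a label gene
#' set at `planted_tf_enrichment` times the background rate; every other
#' factor's targets are independent of the labels.
#'
#' @param annotation a [genome_annotation()] (e.g. from [simulate_genome()]).
#' @param n_tfs number of factors (default 57).
#' @param sites_per_tf sites per factor dataset.
#' @param hot_fraction fraction of each factor's sites at shared loci, in
#'   `[0, 1]`.
#' @param planted_tf_enrichment label enrichment of the planted factor's
#'   targets (>= 1; infeasible combinations error).
#' @param label_set_size size of the label gene set.
#' @param site_width binding-site width in bp.
#' @param hot_jitter per-factor summit jitter at shared loci (bp).
#' @param q_range -log10 q-value range assigned to sites.
#' @param seed mandatory RNG seed.
#' @return List with `collection` (list of [tf_dataset()]), `labels`
#'   (character gene set) and `truth` (list: `planted_tf`, `planted_targets`,
#'   `hot_loci`).
#' @export
simulate_tf_collection <- function(annotation, n_tfs = 57, sites_per_tf = 500,
                                   hot_fraction = 0.3,
                                   planted_tf_enrichment = 3,
                                   label_set_size = 1100, site_width = 200,
                                   hot_jitter = 25, q_range = c(6, 30),
                                   seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (hot_fraction < 0 || hot_fraction > 1)
    stop("'hot_fraction' must be in [0, 1]", call. = FALSE)
  if (planted_tf_enrichment < 1)
    stop("'planted_tf_enrichment' must be >= 1", call. = FALSE)
  genes <- unique(annotation$gene_id)
  U <- length(genes)
  if (label_set_size > U)
    stop("label set larger than the gene universe", call. = FALSE)
  bg_rate <- label_set_size / U
  if (planted_tf_enrichment * bg_rate > 1)
    stop("requested enrichment infeasible for these set sizes", call. = FALSE)
  n_hot <- round(hot_fraction * sites_per_tf)
  n_priv <- sites_per_tf - n_hot
  chrom_len <- attr(annotation, "chrom_len") %||%
    tapply(annotation$end, annotation$chrom, max) + 1e4
  chroms <- names(chrom_len)
  half <- site_width %/% 2
  with_local_seed(seed, {
    # shared (HOT) loci, common to all factors
    hot_chrom <- sample(chroms, n_hot, replace = TRUE,
                        prob = chrom_len / sum(chrom_len))
    hot_pos <- floor(stats::runif(n_hot, site_width + hot_jitter,
                                  chrom_len[hot_chrom] - site_width - hot_jitter))
    gene_row <- function(gids) {
      # summit uniform within the gene body of each chosen gene
      i <- match(gids, annotation$gene_id)
      s <- floor(stats::runif(length(i), annotation$start[i],
                              annotation$end[i]))
      list(chrom = annotation$chrom[i], summit = s)
    }
    planted_targets <- character(0)
    collection <- vector("list", n_tfs)
    for (t in seq_len(n_tfs)) {
      tf <- sprintf("TF%02d", t)
      priv_genes <- sample(genes, n_priv)
      if (t == 1L) planted_targets <- priv_genes
      pg <- gene_row(priv_genes)
      jit <- if (n_hot) sample(seq(-hot_jitter, hot_jitter), n_hot,
                               replace = TRUE) else integer(0)
      chrom <- c(pg$chrom, hot_chrom)
      summit <- c(pg$summit, hot_pos + jit)
      start <- pmax(summit - half, 0)
      end <- start + site_width
      over <- end > chrom_len[chrom]
      end[over] <- chrom_len[chrom][over]
      start[over] <- end[over] - site_width
      qv <- stats::runif(length(summit), q_range[1], q_range[2])
      collection[[t]] <- tf_dataset(chrom, start, end, summit, qv,
                                    tf = tf, stage = "YA")
    }
    # labels: planted targets enter at enrichment x background rate
    n_from_targets <- round(planted_tf_enrichment * bg_rate *
                              length(planted_targets))
    labels <- c(sample(planted_targets, n_from_targets),
                sample(setdiff(genes, planted_targets),
                       label_set_size - n_from_targets))
    list(collection = collection, labels = labels,
         truth = list(planted_tf = "TF01", planted_targets = planted_targets,
                      hot_loci = data.frame(chrom = hot_chrom,
                                            pos = hot_pos)))
  })
}

#' Simulate a paired negative-binomial count matrix with planted DE
#'
#' Gene means are drawn from a broad log-normal distribution and scaled to the
#' requested library size; planted up/down genes have their treatment means
#' multiplied by `2^(+/- lfc)`. Counts are negative binomial with a shared
#' dispersion (variance `mu + dispersion * mu^2`), in a balanced paired
#' design. Deterministic given the seed.
#'
#' @param n_genes number of genes.
#' @param n_reps replicate pairs (default 3).
#' @param frac_up,frac_down fractions of genes planted up/down
#'   (`frac_up + frac_down < 1`).
#' @param lfc absolute log2 effect size of planted genes.
#' @param dispersion negative-binomial dispersion (default 0.1).
#' @param lib_size expected reads per sample (default 1e6).
#' @param seed mandatory RNG seed.
#' @return List with `counts` (a [count_matrix()]) and `truth` (list: `up`,
#'   `down` gene ids, `lfc`, `mu` baseline means).
#' @export
simulate_counts <- function(n_genes, n_reps = 3, frac_up = 0, frac_down = 0,
                            lfc = 2, dispersion = 0.1, lib_size = 1e6,
                            seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down >= 1)
    stop("'frac_up' + 'frac_down' must be < 1 with both >= 0", call. = FALSE)
  with_local_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    w <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.5)
    mu <- lib_size * w / sum(w)
    n_up <- round(frac_up * n_genes)
    n_down <- round(frac_down * n_genes)
    de <- sample(genes, n_up + n_down)
    up <- de[seq_len(n_up)]
    down <- setdiff(de, up)
    mu_trt <- mu
    mu_trt[match(up, genes)] <- mu[match(up, genes)] * 2^lfc
    mu_trt[match(down, genes)] <- mu[match(down, genes)] * 2^-lfc
    size <- 1 / dispersion
    draw <- function(m) matrix(stats::rnbinom(n_genes * n_reps, mu = m,
                                              size = size),
                               n_genes, n_reps)
    ctrl <- draw(mu)
    trt <- draw(mu_trt)
    m <- cbind(ctrl, trt)
    rownames(m) <- genes
    colnames(m) <- c(paste0("ctrl_", seq_len(n_reps)),
                     paste0("trt_", seq_len(n_reps)))
    cm <- count_matrix(m, rep(c("control", "treatment"), each = n_reps),
                       rep(seq_len(n_reps), 2))
    list(counts = cm,
         truth = list(up = up, down = down, lfc = lfc, mu = mu))
  })
}

#' Plant a motif into a fraction of core sequences
#'
#' Overwrites one copy of `motif` at a uniformly random offset in exactly
#' `round(fraction * n_sites)` randomly chosen cores; flanks are untouched.
#' The affected sites and offsets are recorded as ground truth.
#'
#' @param sset a [site_seqs()].
#' @param motif motif string (shorter than the core width).
#' @param fraction fraction of cores receiving a copy, in `[0, 1]`.
#' @param seed mandatory RNG seed.
#' @return List with `sset` (modified [site_seqs()]) and `truth` (data frame
#'   `site` index and 0-based `offset` of each planted copy).
#' @export
plant_motif <- function(sset, motif = "ATTGACA", fraction, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(inherits(sset, "site_seqs"))
  if (fraction < 0 || fraction > 1)
    stop("'fraction' must be in [0, 1]", call. = FALSE)
  n <- length(sset$core)
  w <- if (n) Biostrings::width(sset$core)[1] else 0L
  k <- nchar(motif)
  if (k > w) stop("motif longer than the core width", call. = FALSE)
  n_plant <- round(fraction * n)
  with_local_seed(seed, {
    idx <- sample.int(n, n_plant)
    offs <- sample.int(w - k + 1, n_plant, replace = TRUE) - 1L
    cores <- as.character(sset$core)
    for (j in seq_len(n_plant))
      substr(cores[idx[j]], offs[j] + 1, offs[j] + k) <- motif
    list(sset = site_seqs(cores, sset$left, sset$right, id = sset$id),
         truth = data.frame(site = idx, offset = offs))
  })
}
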