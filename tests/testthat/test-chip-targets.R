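mk_site <- function(start, end, tf = "self", chrom = "chrZ",
                    summit = NULL, q = 8) {
  tf_dataset(chrom, start, end, summit %||% floor((start + end) / 2), q,
             tf = tf)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("per-base co-binding counts distinct factors, not sites or stages", {
  site <- mk_site(100, 200)
  # nothing overlapping
  expect_equal(max_other_tf_count(site, list(mk_site(500, 600, "a"))), 0)
  # two other factors covering disjoint halves never share a base
  expect_equal(max_other_tf_count(site, list(mk_site(100, 150, "a"),
                                             mk_site(150, 200, "b"))), 1)
  # two factors sharing one base, plus a second site of one of them there:
  # distinct factors count, so 2 not 3
  expect_equal(max_other_tf_count(site, list(mk_site(100, 151, "a"),
                                             mk_site(150, 200, "b"),
                                             mk_site(149, 152, "b"))), 2)
  # the same holds when the duplicate is the same factor at another stage
  others <- list(mk_site(100, 151, "a"), mk_site(150, 200, "b"))
  others[[3]] <- tf_dataset("chrZ", 149, 152, 150, 8, tf = "b", stage = "L3")
  expect_equal(max_other_tf_count(site, others), 2)
})

test_that("co-binding counts match the per-base brute-force oracle", {
  set.seed(7)
  for (rep in 1:20) {
    others <- lapply(1:6, function(i)
      random_sites(8, tf = sprintf("tf%d", sample.int(4, 1)), span = 800))
    site <- random_sites(1, tf = "self", span = 800)
    expect_equal(max_other_tf_count(site, others),
                 brute_max_other(site$chrom, site$start, site$end, others))
    # batch path used by the screen agrees too
    ds <- random_sites(10, tf = "self", span = 800)
    fast <- agescreen:::specificity_counts(ds, c(list(ds), others))
    slow <- vapply(seq_len(nrow(ds)), function(i)
      brute_max_other(ds$chrom[i], ds$start[i], ds$end[i], others),
      integer(1))
    expect_equal(fast, slow)
  }
})

test_that("factor-specific filtering applies the q-value floor and HOT cutoff", {
  # one site covered by exactly 8 other factors is kept; 9 removes it
  site <- mk_site(100, 200, tf = "self")
  mk_coll <- function(n_other) c(list(site), lapply(seq_len(n_other),
    function(i) mk_site(120, 180, tf = sprintf("o%d", i))))
  kept8 <- factor_specific_sites(site, mk_coll(8))
  expect_equal(nrow(kept8), 1)
  kept9 <- factor_specific_sites(site, mk_coll(9))
  expect_equal(nrow(kept9), 0)

  # collection containing only the dataset itself keeps all significant sites
  d <- tf_dataset("chrZ", c(0, 100), c(50, 200), c(10, 150), c(8, 3),
                  tf = "self")
  kept <- factor_specific_sites(d, list(d))
  expect_equal(nrow(kept), 1)  # q 3 < q_min 5 dropped
  expect_equal(kept$start, 0)

  expect_error(factor_specific_sites(mk_site(1, 5, tf = "absent"), list(d)),
               "not part of")
})

test_that("factor-specific output is a subset and monotone in max_other", {
  set.seed(11)
  coll <- lapply(1:8, function(i) random_sites(30, tf = sprintf("tf%d", i)))
  d <- coll[[1]]
  prev <- -1
  for (mo in c(0, 1, 3, 7)) {
    kept <- factor_specific_sites(d, coll, max_other = mo, q_min = 0)
    key <- paste(kept$start, kept$end)
    expect_true(all(key %in% paste(d$start, d$end)))
    expect_gte(nrow(kept), prev)
    prev <- nrow(kept)
  }
})

test_that("summit assignment follows the body / <3 kb / neighbour rules", {
  # gene B at [10000, 12000) on +; gene A body ends 1500 bp upstream of B TSS
  ann <- genome_annotation(c("a.1", "b.1"), c("a", "b"), "chrZ",
                           c(2000, 10000), c(8500, 12000), c("+", "+"))
  tgt <- function(summit) assign_targets(mk_site(summit - 5, summit + 5,
                                                 summit = summit), ann)
  expect_equal(tgt(11000), "b")            # inside the gene body
  expect_equal(tgt(9000), "b")             # 1000 bp upstream, intergenic
  expect_equal(tgt(8000), "a")             # 2000 bp up but inside/behind A
  # exactly 3000 bp upstream is excluded (strict "less than")
  ann2 <- genome_annotation("b.1", "b", "chrZ", 10000, 12000, "+")
  tgt2 <- function(s) assign_targets(mk_site(s - 5, s + 5, summit = s), ann2)
  expect_equal(tgt2(7000), character(0))
  expect_equal(tgt2(7001), "b")
  # minus strand mirror: TSS at end-1
  ann3 <- genome_annotation("c.1", "c", "chrZ", 10000, 12000, "-")
  tgt3 <- function(s) assign_targets(mk_site(s - 5, s + 5, summit = s), ann3)
  expect_equal(tgt3(14998), "c")
  expect_equal(tgt3(14999), character(0))

  expect_warning(out <- assign_targets(mk_site(100, 200, chrom = "chrQ"), ann),
                 "absent")
  expect_equal(out, character(0))
})

test_that("summit assignment matches the exhaustive per-transcript oracle", {
  for (s in 1:10) {
    ann <- random_annotation(40, seed = 300 + s)
    set.seed(400 + s)
    ds <- random_sites(25, tf = "x", span = max(ann$end) + 4000)
    expect_equal(assign_targets(ds, ann), brute_assign(ds, ann))
  }
})

test_that("summit assignment is invariant under transcript reordering", {
  ann <- random_annotation(30, seed = 9)
  set.seed(10)
  ds <- random_sites(20, tf = "x", span = max(ann$end) + 2000)
  perm <- sample.int(nrow(ann))
  ann2 <- genome_annotation(ann$transcript_id[perm], ann$gene_id[perm],
                            ann$chrom[perm], ann$start[perm], ann$end[perm],
                            ann$strand[perm])
  expect_equal(assign_targets(ds, ann), assign_targets(ds, ann2))
})

test_that("overlap enrichment builds the 2x2 table and chooses the right test", {
  uni <- sprintf("g%03d", 1:100)
  # query = universe: fold 1, p 1
  r <- overlap_enrichment(uni[1:10], uni, uni)
  expect_equal(r$fold, 1)
  expect_equal(r$p_value, 1)

  # exact path equals the direct hypergeometric tail sum
  targets <- uni[1:10]; query <- uni[8:27]  # overlap 3
  r2 <- overlap_enrichment(targets, query, uni)
  expect_equal(r2$n_overlap, 3)
  expect_equal(r2$test_used, "exact")
  expect_equal(r2$p_value, brute_hyper_tail(3, 10, 20, 100))
  expect_equal(r2$fold, (3 / 10) / (20 / 100))

  # large observed and expected overlap -> chi-square approximation
  uni2 <- sprintf("h%04d", 1:1000)
  r3 <- overlap_enrichment(uni2[1:100], uni2[49:448], uni2)
  expect_equal(r3$n_overlap, 52)
  expect_equal(r3$test_used, "chi_square")
  expect_lt(r3$p_value, 0.05)

  # empty targets: undefined fold, p 1
  r4 <- overlap_enrichment(character(0), query, uni)
  expect_equal(r4$p_value, 1)
  expect_true(is.na(r4$fold))

  expect_error(overlap_enrichment(targets, query, character(0)), "universe")
  expect_warning(overlap_enrichment(c(targets, "nope"), query, uni),
                 "outside the universe")
})

test_that("exact enrichment equals the tail sum on exhaustive small tables", {
  set.seed(21)
  uni <- sprintf("u%03d", 1:60)
  for (i in 1:50) {
    nt <- sample.int(12, 1); nq <- sample.int(25, 1)
    targets <- sample(uni, nt); query <- sample(uni, nq)
    r <- overlap_enrichment(targets, query, uni)
    k <- length(intersect(targets, query))
    if (r$test_used == "exact")
      expect_equal(r$p_value, brute_hyper_tail(k, nt, nq, 60))
  }
})

test_that("the regulator screen flags a planted factor and respects min_sites", {
  g <- simulate_genome(n_chrom = 2, chrom_len = 5e5, n_genes = 800,
                       seed = 31, sequence = FALSE)
  tc <- simulate_tf_collection(g$annotation, n_tfs = 12, sites_per_tf = 80,
                               hot_fraction = 0.25, planted_tf_enrichment = 4,
                               label_set_size = 100, seed = 32)
  rep <- screen_regulators(tc$collection, tc$labels, g$annotation,
                           min_sites = 10, alpha = 1e-4)
  expect_s3_class(rep, "screen_report")
  expect_true(rep$flagged[rep$tf == tc$truth$planted_tf])
  expect_equal(rep$flagged, rep$p_value < 1e-4 & !rep$skipped)

  # an empty query flags nothing
  rep0 <- screen_regulators(tc$collection, character(0), g$annotation,
                            min_sites = 10)
  expect_false(any(rep0$flagged))

  # datasets below the site floor are skipped, not tested
  rep2 <- screen_regulators(tc$collection, tc$labels, g$annotation,
                            min_sites = 81)
  expect_true(all(rep2$skipped))
  expect_false(any(rep2$flagged))

  expect_equal(nrow(screen_regulators(list(), tc$labels, g$annotation)), 0)
})
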