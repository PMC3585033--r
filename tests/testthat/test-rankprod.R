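test_that("major-isoform selection keeps the highest-mean transcript per gene", {
  m <- rbind(a1 = c(10, 10, 10, 10, 10, 10),
             b1 = c(10, 10, 10, 10, 10, 10),
             b2 = c(12, 12, 12, 12, 12, 12),
             c1 = c(5, 5, 5, 5, 5, 5),
             c2 = c(5, 5, 5, 5, 5, 5))
  cm <- cm3(m)
  gm <- c(a1 = "geneA", b1 = "geneB", b2 = "geneB", c1 = "geneC",
          c2 = "geneC")
  out <- select_major_isoform(cm, gm)
  expect_setequal(rownames(out), c("geneA", "geneB", "geneC"))
  sel <- attr(out, "selected_transcript")
  expect_equal(unname(sel["geneA"]), "a1")  # single isoform passes through
  expect_equal(unname(sel["geneB"]), "b2")  # highest mean wins
  expect_equal(unname(sel["geneC"]), "c1")  # tie -> lexicographically first
  expect_error(select_major_isoform(cm, gm[-1]), "missing from gene_map")
})

test_that("expression filter uses the either-condition rule and adds one", {
  m <- rbind(kept_ctrl = c(10, 10, 10, 0, 0, 0),
             dropped = c(9, 10, 11, 0, 0, 5),
             kept_trt = c(0, 1, 2, 10, 11, 12))
  out <- filter_and_pseudocount(cm3(m))
  expect_setequal(rownames(out), c("kept_ctrl", "kept_trt"))
  expect_equal(unclass(out)["kept_ctrl", ], unclass(cm3(m))["kept_ctrl", ] + 1,
               ignore_attr = TRUE)
})

test_that("fold-change ranks handle direction, ties and symmetry", {
  m <- rbind(g1 = c(10, 10, 10, 40, 10, 10),
             g2 = c(10, 10, 10, 20, 20, 30),
             g3 = c(10, 10, 10, 5, 20, 20))
  cm <- filter_and_pseudocount(cm3(m), min_reads = 0)
  rd <- replicate_fc_ranks(cm, "down")
  ru <- replicate_fc_ranks(cm, "up")
  # distinct fold-changes rank as a permutation of 1..3
  expect_setequal(rd[, 1], 1:3)
  # g2 and g3 tie in replicate 2 (both fc = 21/11): average rank
  expect_equal(unname(rd["g2", 2]), 2.5)
  expect_equal(unname(rd["g3", 2]), 2.5)
  # no ties in replicate 1: up = (G+1) - down
  expect_equal(ru[, 1], 4 - rd[, 1])

  expect_equal(unname(rank_product(rbind(c(1, 1, 1), c(2, 3, 4)))), c(1, 24))
  # ordering by rank product equals ordering by geometric mean of ranks
  set.seed(5)
  r <- matrix(sample.int(50, 150, replace = TRUE), 50, 3)
  expect_equal(order(rank_product(r)), order(apply(r, 1, function(x)
    prod(x)^(1 / 3))))
})

test_that("permutation statistics match the analytic null at tiny G", {
  set.seed(1)
  # gene "a" holds rank 1 in every replicate
  ranks <- cbind(c(1, sample(2:5)), c(1, sample(2:5)), c(1, sample(2:5)))
  rownames(ranks) <- letters[1:5]
  res <- permutation_significance(ranks, n_perm = 10000, seed = 99)
  # a gene with rp = 1 has exact null probability (1/5)^3 = 0.008
  se <- sqrt(0.008 * 0.992 / 10000)
  expect_lt(abs(res["a", "p_rp"] - 0.008), 3 * se + 1e-4)
  # identical seed -> bit-identical; different seed -> close
  res2 <- permutation_significance(ranks, n_perm = 2000, seed = 7)
  res3 <- permutation_significance(ranks, n_perm = 2000, seed = 7)
  expect_identical(res2, res3)
  res4 <- permutation_significance(ranks, n_perm = 2000, seed = 8)
  expect_equal(res2$e_value, res4$e_value, tolerance = 0.2)
  expect_error(permutation_significance(ranks, n_perm = 0, seed = 1), "n_perm")
})

test_that("aggregated exact null equals literal enumeration of all configurations", {
  # literal loop over all (3!)^3 = 216 rank configurations at G = 3, k = 3
  G <- 3
  perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  ncol = 3, byrow = TRUE)
  thresholds <- c(1, 2, 4, 6, 9, 27)
  literal <- sapply(thresholds, function(t) {
    cnt <- 0
    for (i in 1:6) for (j in 1:6) for (l in 1:6) {
      rp <- perms[i, ] * perms[j, ] * perms[l, ]
      cnt <- cnt + sum(rp <= t)
    }
    cnt / 216
  })
  aggregated <- sapply(thresholds, exact_e_value, G = G, k = 3)
  expect_equal(literal, aggregated)
})

test_that("DE calls require the PFP cutoff plus top-third replicate consistency", {
  G <- 9
  genes <- sprintf("g%d", 1:G)
  mk_res <- function(pfp) data.frame(pfp = pfp, row.names = genes)
  ranks_down <- matrix(rep(1:G, 3), G, 3, dimnames = list(genes, NULL))
  ranks_up <- (G + 1) - ranks_down
  pfp_down <- rep(1, G); pfp_down[1:3] <- 0.05
  pfp_up <- rep(1, G)
  # g1..g3 pass PFP; only ranks <= floor(9/3) = 3 in every replicate are kept
  calls <- call_de(mk_res(pfp_up), mk_res(pfp_down), ranks_up, ranks_down)
  expect_equal(calls$down, c("g1", "g2", "g3"))
  expect_equal(calls$up, character(0))

  # a replicate outside the top third demotes the gene to discarded
  rd2 <- ranks_down; rd2["g2", 2] <- 5; rd2["g5", 2] <- 2
  calls2 <- call_de(mk_res(pfp_up), mk_res(pfp_down), ranks_up, rd2)
  expect_equal(calls2$down, c("g1", "g3"))
  expect_equal(calls2$discarded_for_consistency, "g2")

  # all PFP above the cutoff: empty call set
  calls3 <- call_de(mk_res(rep(1, G)), mk_res(rep(1, G)), ranks_up,
                    ranks_down)
  expect_equal(length(calls3$up) + length(calls3$down), 0)

  # a gene consistent and significant in both directions is impossible;
  # fabricated input triggers the guard
  expect_error(call_de(mk_res(pfp_down), mk_res(pfp_down), ranks_down,
                       ranks_down), "both directions")
})

test_that("swapping condition labels swaps up and down calls exactly", {
  sim <- simulate_counts(400, frac_up = 0.05, frac_down = 0.05, lfc = 2,
                         lib_size = 2e5, seed = 51)
  cm <- sim$counts
  fit <- rank_prod(cm, n_perm = 400, seed = 52)
  cond <- attr(cm, "condition")
  swapped <- count_matrix(unclass(cm),
                          ifelse(cond == "control", "treatment", "control"),
                          attr(cm, "replicate"))
  fit2 <- rank_prod(swapped, n_perm = 400, seed = 52)
  expect_equal(sort(fit$calls$up), sort(fit2$calls$down))
  expect_equal(sort(fit$calls$down), sort(fit2$calls$up))
  expect_equal(fit$table$pfp_down, fit2$table$pfp_up)
})

test_that("the rank_prod fit recovers planted DE with correct directions", {
  sim <- simulate_counts(600, frac_up = 0.08, frac_down = 0.08, lfc = 2.5,
                         lib_size = 5e5, seed = 61)
  fit <- rank_prod(sim$counts, n_perm = 500, seed = 62)
  expect_s3_class(fit, "rank_prod")
  expect_gt(mean(sim$truth$up %in% fit$calls$up), 0.6)
  expect_gt(mean(sim$truth$down %in% fit$calls$down), 0.6)
  # no called gene contradicts the planted direction
  expect_length(intersect(fit$calls$up, sim$truth$down), 0)
  expect_length(intersect(fit$calls$down, sim$truth$up), 0)
  # methods run
  expect_output(print(fit), "Rank-products")
  expect_output(summary(fit), "Top down-regulated")
  expect_equal(as.data.frame(fit), fit$table)
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp)); unlink(tmp)
})
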