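graph_from_edges <- function(id, src, rel, tgt) {
  new_pathway_graph(id, edges = tibble::tibble(source = src, target = tgt,
                                               interaction = rel))
}

test_that("network merging unions nodes/edges with provenance", {
  g1 <- graph_from_edges("p1", c("a", "b"), "activation", c("b", "c"))
  g2 <- graph_from_edges("p2", c("x"), "inhibition", c("y"))
  g3 <- graph_from_edges("p3", c("a"), "inhibition", c("b")) # shares edge a->b

  single <- merge_priori_network(list(g1))
  expect_setequal(single$nodes, g1$nodes)
  expect_identical(nrow(single$edges), nrow(g1$edges))

  disjoint <- merge_priori_network(list(g1, g2))
  expect_identical(length(disjoint$nodes), length(g1$nodes) + length(g2$nodes))

  shared <- merge_priori_network(list(g1, g3))
  ab <- shared$edges[shared$edges$source == "a" & shared$edges$target == "b", ]
  expect_identical(nrow(ab), 1L)
  expect_setequal(ab$provenance[[1]], c("p1", "p3"))
  expect_identical(ab$interaction, "activation") # first-seen type kept

  # merge is order-independent up to provenance ordering
  rev_merge <- merge_priori_network(list(g3, g1))
  expect_setequal(paste(shared$edges$source, shared$edges$target),
                  paste(rev_merge$edges$source, rev_merge$edges$target))

  expect_error(merge_priori_network(list()), "empty")
})

test_that("cyclic merged networks are reported, not repaired", {
  g <- graph_from_edges("p", c("a", "b"), "activation", c("b", "a"))
  net <- merge_priori_network(list(g))
  expect_true(net$is_cyclic)
  expect_identical(nrow(net$edges), 2L)
})

test_that("adjustment sets are the measured network parents", {
  g <- graph_from_edges("p", c("a", "c", "b"), "activation", c("b", "b", "d"))
  net <- merge_priori_network(list(g))
  expect_setequal(adjustment_set_for(net, "b", c("a", "b", "c", "d")), c("a", "c"))
  expect_identical(adjustment_set_for(net, "a", c("a", "b")), character(0))
  expect_warning(adj <- adjustment_set_for(net, "b", c("a", "b", "d")), "Unmeasured")
  expect_identical(adj, "a")
  expect_error(adjustment_set_for(net, "zz", "a"), "not in the prior network")
})

test_that("a constant outcome yields CEV exactly 0", {
  m <- random_matrix(4, 6, seed = 2)
  md <- make_metadata(colnames(m), groups = rep("CD", 6)) # all one subtype
  res <- estimate_cev(m, md, "g01")
  expect_identical(res$cev, 0)
})

test_that("backdoor adjustment removes planted confounding (continuous outcome)", {
  set.seed(101)
  n <- 2000
  zc <- rnorm(n) # confounder: C -> T and C -> Y
  zt <- 0.8 * zc + rnorm(n, 0, 0.6)
  y <- 0.5 * zt + 0.7 * zc + rnorm(n, 0, 0.5)
  # expressions whose log2(x+1) values equal the latent linear variables
  m <- rbind(tt = 2^(zt + 10) - 1, cc = 2^(zc + 10) - 1,
             filler = rep(1, n))
  colnames(m) <- sprintf("s%04d", 1:n)
  outcome <- stats::setNames(y, colnames(m))

  adj <- estimate_cev(m, metadata = NULL, "tt", adjustment_set = "cc",
                      outcome = outcome)
  naive <- estimate_cev(m, metadata = NULL, "tt", outcome = outcome)
  expect_lt(abs(adj$cev - 0.5), 0.05)
  expect_gt(abs(naive$cev - 0.5), 0.2) # bias through the confounding path
  expect_lt(abs(adj$cev - 0.5), abs(naive$cev - 0.5))
})

test_that("null treatments stay within three standard errors", {
  set.seed(55)
  flags <- vapply(1:100, function(s) {
    n <- 500
    y <- rbinom(n, 1, 0.5)
    tvec <- 2^(rnorm(n) + 8) - 1 # independent of y
    m <- rbind(tt = tvec, filler = rep(1, n))
    colnames(m) <- sprintf("s%03d", 1:n)
    md <- make_metadata(colnames(m), groups = ifelse(y == 1, "CD", "UC"))
    res <- estimate_cev(m, md, "tt")
    lt <- log2p1(m["tt", ])
    se <- summary(stats::lm(y ~ lt))$coefficients["lt", "Std. Error"]
    abs(res$cev) < 3 * se
  }, logical(1))
  expect_gte(sum(flags), 97)
})

test_that("collinear and under-determined designs are rejected with gene names", {
  m <- random_matrix(4, 8, seed = 3)
  m["g02", ] <- (m["g01", ] + 1)^2 - 1 # log2(x+1) exactly collinear with g01
  md <- make_metadata(colnames(m), groups = rep(c("CD", "UC"), 4))
  expect_error(estimate_cev(m, md, "g03", c("g01", "g02")), "Collinear")
  expect_error(estimate_cev(m, md, "g03", c("g01", "g04")),
               NA) # full-rank control case runs
  expect_error(estimate_cev(m[, 1:4], md[1:4, ], "g03", c("g01", "g04")),
               "Under-determined")
  expect_error(estimate_cev(m, md, "g01", "g01"), "exclude the treatment")
})

test_that("permutation significance attains the floor and is deterministic", {
  set.seed(77)
  n <- 60
  zt <- rnorm(n)
  y <- as.numeric(zt + rnorm(n, 0, 0.3) > 0)
  m <- rbind(tt = 2^(zt + 8) - 1, filler = rep(2, n))
  colnames(m) <- sprintf("s%03d", 1:n)
  md <- make_metadata(colnames(m), groups = ifelse(y == 1, "CD", "UC"))
  r1 <- permutation_significance(m, md, "tt", B = 1000, seed = 5)
  expect_identical(r1$p_value, 1 / 1001) # strong effect: exceeds all permutations
  r2 <- permutation_significance(m, md, "tt", B = 1000, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  r3 <- permutation_significance(m, md, "tt", B = 1000, seed = 6)
  expect_true(r3$p_value >= 1 / 1001)
})

test_that("the placebo permutation test is calibrated with correlated covariates", {
  # downstream gene adjusted for its parent: conditionally independent of the
  # outcome, but strongly correlated with the covariate -- the regime where a
  # raw-coefficient permutation comparison would be anti-conservative
  set.seed(88)
  ps <- vapply(1:200, function(s) {
    n <- 80
    zb <- rnorm(n)
    y <- rbinom(n, 1, stats::plogis(1.2 * zb))
    zc <- 0.8 * zb + rnorm(n, 0, 0.5) # child of B, no effect on Y
    m <- rbind(bb = 2^(zb + 8) - 1, cc = 2^(zc + 8) - 1, filler = rep(1, n))
    colnames(m) <- sprintf("s%03d", 1:n)
    md <- make_metadata(colnames(m), groups = ifelse(y == 1, "CD", "UC"))
    permutation_significance(m, md, "cc", "bb", B = 99, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.02)
  expect_lte(mean(ps < 0.05), 0.09)
})

test_that("screening and regulator calling enforce the conjunction rule", {
  tr <- build_truth_network(seed = 7)
  co <- simulate_expression(tr, 100, seed = 12)
  net <- merge_priori_network(tr$pathway_graphs["pw01"])
  causal <- screen_causal_effects(co$matrix, co$metadata, net,
                                  c("regA", "medB", "dsC"), B = 499, seed = 3)
  expect_identical(nrow(causal), 3L)
  expect_true(all(causal$p_value >= 1 / 500))
  regs <- call_subtype_regulators(causal, co$matrix, co$metadata)
  expect_true(all(c("regA", "medB") %in% regs$gene_id[regs$is_regulator]))

  # conjunction: a significant causal p with a non-significant subtype
  # difference is not a regulator, and vice versa
  fake <- causal
  fake$p_value <- c(0.002, 0.45, 0.01)
  fake_regs <- call_subtype_regulators(fake, co$matrix, co$metadata)
  expect_false(fake_regs$is_regulator[fake_regs$gene_id == "medB"]) # causal gate
  hk_causal <- tibble::tibble(gene_id = "hk01", cev = 0.5, p_value = 0.01,
                              n = 200L, B = 499L, n_adjust = 0L,
                              adjustment_set = list(character(0)))
  hk_regs <- call_subtype_regulators(hk_causal, co$matrix, co$metadata)
  expect_false(hk_regs$is_regulator[1]) # subtype gate: housekeeping gene flat

  empty <- call_subtype_regulators(causal[0, ], co$matrix, co$metadata)
  expect_identical(nrow(empty), 0L)
})
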