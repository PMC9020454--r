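test_that("Kruskal-Wallis reproduces the hand-computed statistic", {
  # groups {1,2,3}, {4,5,6}, {7,8,9}: rank sums 6, 15, 24 give H = 7.2
  fx <- group_value_matrix(cd = c(1, 2, 3), uc = c(4, 5, 6), control = c(7, 8, 9))
  kw <- kruskal_wallis_screen(fx$matrix, fx$metadata)
  expect_equal(kw$kw_statistic[kw$gene_id == "target"], 7.2, tolerance = 1e-12)

  # all samples identical: H = 0, p = 1
  fx0 <- group_value_matrix(cd = c(5, 5, 5), uc = c(5, 5, 5), control = c(5, 5, 5))
  kw0 <- kruskal_wallis_screen(fx0$matrix, fx0$metadata)
  expect_identical(kw0$kw_statistic[kw0$gene_id == "target"], 0)
  expect_identical(kw0$kw_p[kw0$gene_id == "target"], 1)

  expect_error(kruskal_wallis_screen(fx$matrix, fx$metadata,
                                     groups = c("CD", "UC", "nope")), "absent")
})

test_that("the KW statistic is invariant under strictly monotone transforms", {
  set.seed(4)
  fx <- group_value_matrix(cd = runif(5, 0, 4), uc = runif(5, 1, 5),
                           control = runif(5, 0, 3))
  kw1 <- kruskal_wallis_screen(fx$matrix, fx$metadata)
  fx$matrix["target", ] <- exp(fx$matrix["target", ]) # monotone
  kw2 <- kruskal_wallis_screen(fx$matrix, fx$metadata)
  expect_equal(kw2$kw_statistic[kw2$gene_id == "target"],
               kw1$kw_statistic[kw1$gene_id == "target"], tolerance = 1e-12)
})

test_that("two-group KW decisions track the exhaustive rank-sum oracle", {
  # exact two-sided Mann-Whitney p by full enumeration of group assignments
  exact_mw_p <- function(x, y) {
    pooled <- c(x, y); n1 <- length(x)
    r_obs <- sum(rank(pooled)[seq_len(n1)])
    combs <- utils::combn(length(pooled), n1)
    r_all <- apply(combs, 2, function(ii) sum(rank(pooled)[ii]))
    mu <- n1 * (length(pooled) + 1) / 2
    mean(abs(r_all - mu) >= abs(r_obs - mu) - 1e-12)
  }
  set.seed(11)
  disagreements <- 0
  for (i in 1:60) {
    n <- sample(4:7, 1)
    x <- round(runif(n, 0, 100), 3); y <- round(runif(n, 0, 100) + runif(1, 0, 40), 3)
    fx <- group_value_matrix(cd = x, uc = y, control = numeric(0))
    md <- fx$metadata[fx$metadata$group != "control", ]
    kw <- kruskal_wallis_screen(fx$matrix, md, groups = c("CD", "UC"))
    kw_reject <- kw$kw_p[kw$gene_id == "target"] < 0.05
    mw_reject <- exact_mw_p(x, y) < 0.05
    disagreements <- disagreements + (kw_reject != mw_reject)
  }
  # the chi-square approximation may differ from the exact tail only at the
  # rejection boundary; demand near-perfect agreement
  expect_lte(disagreements, 3)
})

test_that("Dunnett contrasts behave at the null and at extreme separation", {
  fx <- group_value_matrix(cd = c(1, 2, 3), uc = c(2, 1, 3), control = c(1, 2, 3))
  res <- dunnett_many_to_one(fx$matrix, fx$metadata, mc_draws = 2000, seed = 1)
  p_cd <- res$p_value[res$gene_id == "target" & res$comparison == "CD_vs_control"]
  expect_gt(p_cd, 0.9) # treatment equals control values

  # single-contrast case: the Dunnett statistic reduces to a pooled t, whose
  # exact two-sided p is the closed-form oracle for the Monte-Carlo estimate
  fx2 <- group_value_matrix(cd = c(11, 12, 13), uc = numeric(0), control = c(1, 2, 3))
  res2 <- dunnett_many_to_one(fx2$matrix, fx2$metadata, mc_draws = 200000, seed = 1)
  p_mc <- res2$p_value[res2$gene_id == "target" & res2$comparison == "CD_vs_control"]
  y <- log2p1(c(1, 2, 3, 11, 12, 13))
  s2 <- (sum((y[1:3] - mean(y[1:3]))^2) + sum((y[4:6] - mean(y[4:6]))^2)) / 4
  t_obs <- (mean(y[4:6]) - mean(y[1:3])) / sqrt(s2 * (2 / 3))
  p_exact <- 2 * stats::pt(abs(t_obs), df = 4, lower.tail = FALSE)
  expect_lt(abs(p_mc - p_exact), 5e-4)
  expect_lt(p_mc, 0.01)

  # a 10-SD separation is driven to the exceedance floor
  fx3 <- group_value_matrix(cd = c(300, 310, 320), uc = c(1, 2, 3), control = c(1, 2, 3))
  res3 <- dunnett_many_to_one(fx3$matrix, fx3$metadata, mc_draws = 10000, seed = 1)
  expect_lt(res3$p_value[res3$gene_id == "target" & res3$comparison == "CD_vs_control"],
            0.001)
})

test_that("Monte-Carlo Dunnett p agrees with the multcomp single-step oracle", {
  skip_if_not_installed("multcomp")
  set.seed(21)
  vals <- c(rnorm(8, 5, 1), rnorm(8, 5.9, 1), rnorm(8, 5, 1))
  vals <- pmax(vals, 0)
  fx <- group_value_matrix(cd = vals[1:8], uc = vals[9:16], control = vals[17:24])
  mine <- dunnett_many_to_one(fx$matrix, fx$metadata, mc_draws = 50000, seed = 2)
  y <- log2p1(fx$matrix["target", ])
  g <- factor(fx$metadata$group, levels = c("control", "CD", "UC"))
  fit <- stats::aov(y ~ g)
  glht_p <- summary(multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett")))$test$pvalues
  for (k in 1:2) {
    comp <- paste0(c("CD", "UC")[k], "_vs_control")
    expect_lt(abs(mine$p_value[mine$gene_id == "target" & mine$comparison == comp] -
                    glht_p[k]), 0.02)
  }
})

test_that("the Dunnett family-wise error rate is calibrated under the null", {
  set.seed(31)
  n_sim <- 1000
  m <- matrix(stats::rgamma(n_sim * 30, 4, 0.2), n_sim, 30,
              dimnames = list(sprintf("sim%04d", 1:n_sim), sprintf("s%02d", 1:30)))
  md <- make_metadata(colnames(m), groups = rep(c("CD", "UC", "control"), each = 10))
  res <- dunnett_many_to_one(m, md, mc_draws = 20000, seed = 5)
  fwer <- mean(tapply(res$p_value < 0.05, res$gene_id, any))
  expect_gte(fwer, 0.03)
  expect_lte(fwer, 0.07)
})

test_that("degenerate zero-variance contrasts never emit p = 0", {
  fx <- group_value_matrix(cd = c(7, 7, 7), uc = c(7, 7, 7), control = c(2, 2, 2))
  res <- dunnett_many_to_one(fx$matrix, fx$metadata, mc_draws = 1000, seed = 1)
  row <- res[res$gene_id == "target" & res$comparison == "CD_vs_control", ]
  expect_true(row$degenerate)
  expect_identical(row$p_value, 1 / 1001) # exceedance floor, not 0
})

test_that("log2 fold changes follow the pseudocount arithmetic", {
  fx <- group_value_matrix(cd = c(4, 4, 4), uc = c(2, 2, 2), control = c(1, 1, 1))
  fc0 <- log2_fold_change(fx$matrix, fx$metadata, "CD", "UC", pseudocount = 0)
  expect_equal(fc0$log2_fc[fc0$gene_id == "target"], 1, tolerance = 0)
  fc_eq <- log2_fold_change(fx$matrix, fx$metadata, "CD", "CD")
  expect_identical(fc_eq$log2_fc[fc_eq$gene_id == "target"], 0)

  fx2 <- group_value_matrix(cd = c(0, 0, 0), uc = c(1, 1, 1), control = c(1, 1, 1))
  fc1 <- log2_fold_change(fx2$matrix, fx2$metadata, "CD", "UC", pseudocount = 1)
  expect_equal(fc1$log2_fc[fc1$gene_id == "target"], -1, tolerance = 0)

  fx3 <- group_value_matrix(cd = c(0, 0, 0), uc = c(0, 0, 0), control = c(1, 1, 1))
  expect_error(log2_fold_change(fx3$matrix, fx3$metadata, "CD", "UC", pseudocount = 0),
               "undefined")
})

test_that("BH adjustment matches an independent step-up implementation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4), tolerance = 1e-15)
  expect_identical(bh_adjust(0.2), 0.2)
  expect_identical(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  step_up <- function(p) { # independent textbook implementation
    m <- length(p); o <- order(p); adj <- numeric(m); prev <- 1
    for (i in m:1) {
      prev <- min(prev, p[o[i]] * m / i)
      adj[o[i]] <- prev
    }
    adj
  }
  set.seed(13)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
  }
})

test_that("DEG calling enforces the conjunction of both gates", {
  genes <- c("up_sig", "small_fc", "big_fc_ns")
  stats <- tibble::tibble(
    gene_id = rep(genes, 1),
    comparison = "CD_vs_control",
    kw_statistic = 10, kw_p = 0.001,
    posthoc_p = c(0.005, 1e-10, 0.2),
    log2_fc = c(1.5, 0.9, 3.0)
  )
  out <- call_degs(stats, fc_threshold = 1, alpha = 0.05, gate_on_kw = FALSE)
  expect_true(out$is_deg[out$gene_id == "up_sig"])
  expect_false(out$is_deg[out$gene_id == "small_fc"]) # fold-change gate
  expect_false(out$is_deg[out$gene_id == "big_fc_ns"]) # significance gate
  expect_true(all(out$p_adjusted >= out$posthoc_p - 1e-15))

  # KW gating marks omnibus-insignificant genes as not tested
  stats$kw_p <- c(0.001, 0.5, 0.001)
  gated <- call_degs(stats, gate_on_kw = TRUE)
  expect_true(is.na(gated$p_adjusted[gated$gene_id == "small_fc"]))
  expect_false(gated$is_deg[gated$gene_id == "small_fc"])

  bad <- stats; bad$gene_id[1] <- "other"
  bad$comparison <- rep(c("CD_vs_control", "UC_vs_control"), length.out = 3)
  expect_error(call_degs(bad), "universe")
})

test_that("planted group shifts are recovered with high sensitivity and low FDR", {
  # independent genes, disease shift 2 noise-SDs on two of ten pathways,
  # 15 samples per group -- the regime the DEG gates are tuned for
  tr <- build_truth_network(n_genes = 220, n_pathways = 10, n_housekeeping = 20,
                            cv = 1.5, disease_effect_sd = 2, edge_prob = 0,
                            cascade_spec = cascade_spec(w_ab = 0, w_bc = 0,
                                                        gamma = c(1.5, 1, 0)),
                            n_shifted_pathways = 2, seed = 17)
  planted <- tr$delta$gene_id[tr$delta$CD > 0]
  hits <- 0; total_called <- 0; false_called <- 0
  for (s in 1:4) {
    co <- simulate_expression(tr, 15, seed = 600 + s)
    deg <- run_deg_analysis(co$matrix, co$metadata, mc_draws = 5000, seed = s)
    called <- deg_ids(deg)
    hits <- hits + length(intersect(called, planted))
    total_called <- total_called + length(called)
    false_called <- false_called + length(setdiff(called, planted))
  }
  sensitivity <- hits / (length(planted) * 4)
  fdr <- if (total_called > 0) false_called / total_called else 0
  expect_gte(sensitivity, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("the rank-based many-to-one variant detects shifts too", {
  fx <- group_value_matrix(cd = c(30, 31, 29, 33, 32), uc = c(3, 4, 5, 4, 3),
                           control = c(3, 5, 4, 4, 5))
  res <- dunnett_many_to_one(fx$matrix, fx$metadata, mc_draws = 5000, seed = 3,
                             method = "steel")
  expect_lt(res$p_value[res$gene_id == "target" & res$comparison == "CD_vs_control"],
            0.01)
})
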