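#' Kruskal-Wallis omnibus screen
#'
#' Rank-based omnibus test per gene across the named groups, with midrank
#' ties and the standard tie correction; p from the chi-square approximation
#' with (number of groups - 1) degrees of freedom. A gene whose values are
#' all identical gets H = 0, p = 1.
#'
#' @param matrix Genes-by-samples matrix.
#' @param metadata Sample metadata (`sample_id`, `group`).
#' @param groups Groups to compare; all must be present in the metadata.
#' @return Tibble `gene_id`, `kw_statistic`, `kw_p`.
#' @export
kruskal_wallis_screen <- function(matrix, metadata, groups = c("CD", "UC", "control")) {
  validate_expression_matrix(matrix)
  grp <- groups_of(matrix, metadata)
  missing <- setdiff(groups, unique(grp))
  if (length(missing) > 0) {
    stop("Group(s) absent from metadata: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- grp %in% groups
  g <- factor(grp[keep], levels = groups)
  x <- matrix[, keep, drop = FALSE]
  res <- vapply(rownames(x), function(gene) {
    y <- x[gene, ]
    if (all(y == y[1])) return(c(h = 0, p = 1))
    kt <- suppressWarnings(kruskal.test(y, g))
    c(h = unname(kt$statistic), p = unname(kt$p.value))
  }, c(h = 0, p = 0))
  tibble(gene_id = rownames(x), kw_statistic = unname(res["h", ]),
         kw_p = unname(res["p", ]))
}

# Monte-Carlo null distribution of the max-|t| Dunnett statistic for given
# group sizes: z_i ~ N(0, 1/n_i), s^2 ~ chi^2_df / df shared across
# contrasts, t_k = (z_k - z_0) / (s * sqrt(1/n_k + 1/n_0)).
dunnett_null_maxt <- function(n_control, n_treat, mc_draws, seed) {
  set.seed(seed)
  df <- n_control + sum(n_treat) - (length(n_treat) + 1)
  z0 <- rnorm(mc_draws, 0, sqrt(1 / n_control))
  s <- sqrt(rchisq(mc_draws, df) / df)
  maxt <- rep(0, mc_draws)
  for (k in seq_along(n_treat)) {
    zk <- rnorm(mc_draws, 0, sqrt(1 / n_treat[k]))
    tk <- (zk - z0) / (s * sqrt(1 / n_treat[k] + 1 / n_control))
    maxt <- pmax(maxt, abs(tk))
  }
  maxt
}

#' Dunnett-type many-to-one comparisons with Monte-Carlo family-wise p
#'
#' For every gene, compares each treatment group against the control group
#' with a pooled-variance t statistic on `log2(x + 1)` values. Family-wise
#' two-sided p-values come from the joint null distribution of the contrast
#' statistics (single-step max-|t|), evaluated by Monte Carlo with
#' `mc_draws` draws and the exceedance convention
#' `p = (1 + #\{max|t|_null >= |t_obs|\}) / (mc_draws + 1)` — so p is never
#' exactly 0. A zero-pooled-variance gene with unequal means is flagged
#' `degenerate` and gets the exceedance floor rather than p = 0.
#'
#' The `"steel"` method replaces the raw values by midranks across all
#' samples before forming the same contrasts — a rank-based many-to-one
#' variant for heavy-tailed data.
#'
#' @param matrix Genes-by-samples matrix (linear scale; log2(x+1) applied
#'   internally unless `method = "steel"`).
#' @param metadata Sample metadata.
#' @param control_group Reference group name.
#' @param mc_draws Monte-Carlo draws for the null distribution.
#' @param seed Integer seed.
#' @param method `"dunnett"` (parametric, on log2 scale) or `"steel"`
#'   (rank-transformed).
#' @param genes Optional subset of genes to test.
#' @return Tibble `gene_id`, `comparison`, `estimate` (difference of group
#'   means on the analysis scale), `statistic`, `p_value`, `degenerate`.
#' @export
dunnett_many_to_one <- function(matrix, metadata, control_group = "control",
                                mc_draws = 10000, seed = 1,
                                method = c("dunnett", "steel"), genes = NULL) {
  method <- match.arg(method)
  validate_expression_matrix(matrix)
  grp <- groups_of(matrix, metadata)
  if (!control_group %in% grp) {
    stop("Control group '", control_group, "' absent from metadata.", call. = FALSE)
  }
  treatments <- setdiff(unique(grp), control_group)
  if (length(treatments) == 0) stop("Need at least one treatment group.", call. = FALSE)
  if (is.null(genes)) genes <- rownames(matrix)

  x <- matrix[genes, , drop = FALSE]
  x <- if (method == "steel") {
    t(apply(x, 1, rank)) # midranks across all samples
  } else {
    log2p1(x)
  }
  idx0 <- which(grp == control_group)
  idxs <- lapply(treatments, function(tr) which(grp == tr))
  n0 <- length(idx0); nk <- lengths(idxs)
  if (n0 < 2 || any(nk < 2)) stop("Every group needs >= 2 samples.", call. = FALSE)
  df <- n0 + sum(nk) - (length(nk) + 1)

  maxt <- dunnett_null_maxt(n0, nk, mc_draws, derive_seed(seed, "dunnett-null"))
  maxt <- sort(maxt)

  rows <- lapply(seq_along(treatments), function(k) {
    m0 <- rowMeans(x[, idx0, drop = FALSE])
    mk <- rowMeans(x[, idxs[[k]], drop = FALSE])
    # pooled variance across all groups (control + all treatments)
    contrib <- vapply(c(list(idx0), idxs), function(ii) {
      xi <- x[, ii, drop = FALSE]
      rowSums((xi - rowMeans(xi))^2)
    }, numeric(nrow(x)))
    if (is.null(dim(contrib))) contrib <- matrix(contrib, nrow = 1)
    ss <- rowSums(contrib)
    s2 <- ss / df
    se <- sqrt(s2 * (1 / nk[k] + 1 / n0))
    est <- mk - m0
    stat <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
    degenerate <- se == 0 & est != 0
    # exceedance count against the sorted null: #{maxt >= |t|}
    exceed <- mc_draws - findInterval(abs(stat) - 1e-12, maxt)
    tibble(
      gene_id = rownames(x),
      comparison = paste0(treatments[k], "_vs_", control_group),
      estimate = unname(est),
      statistic = unname(stat),
      p_value = unname((1 + exceed) / (mc_draws + 1)),
      degenerate = unname(degenerate)
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-gene log2 fold change between two groups
#'
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))` on linear-scale
#' (corrected) intensities.
#'
#' @param matrix Genes-by-samples matrix.
#' @param metadata Sample metadata.
#' @param group_a,group_b Comparison and reference group.
#' @param pseudocount Nonnegative stabiliser, default 1.
#' @return Tibble `gene_id`, `log2_fc`.
#' @export
log2_fold_change <- function(matrix, metadata, group_a, group_b, pseudocount = 1) {
  validate_expression_matrix(matrix)
  stopifnot(pseudocount >= 0)
  grp <- groups_of(matrix, metadata)
  for (g in c(group_a, group_b)) {
    if (!g %in% grp) stop("Group '", g, "' absent from metadata.", call. = FALSE)
  }
  ma <- rowMeans(matrix[, grp == group_a, drop = FALSE])
  mb <- rowMeans(matrix[, grp == group_b, drop = FALSE])
  if (pseudocount == 0 && any(ma == 0 & mb == 0)) {
    stop("Fold change undefined: both group means zero with pseudocount 0 for gene(s): ",
         paste(head(rownames(matrix)[ma == 0 & mb == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  tibble(gene_id = rownames(matrix),
         log2_fc = unname(log2((ma + pseudocount) / (mb + pseudocount))))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, order-preserving and
#' capped at 1. Inputs outside `[0, 1]` are an error.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must all lie in [0, 1].", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Combines per-gene, per-comparison statistics into a DEG table. Within each
#' comparison the post hoc p-values are BH-adjusted across tested genes and a
#' gene is a DEG iff `|log2FC| > fc_threshold` and adjusted p `< alpha`. When
#' `gate_on_kw` is `TRUE`, only genes whose Kruskal-Wallis omnibus p is below
#' `alpha` are tested post hoc; others are marked not tested (`NA` adjusted
#' p, not DEGs).
#'
#' @param stats Tibble with columns `gene_id`, `comparison`, `kw_statistic`,
#'   `kw_p`, `posthoc_p`, `log2_fc` (every comparison must cover the same
#'   genes).
#' @param fc_threshold Absolute log2 fold-change gate (default 1).
#' @param alpha Significance gate on BH-adjusted post hoc p (default 0.05).
#' @param gate_on_kw Gate post hoc testing on the omnibus test.
#' @return A `deg_table` tibble: input columns plus `tested`, `p_adjusted`,
#'   `is_deg`.
#' @export
call_degs <- function(stats, fc_threshold = 1, alpha = 0.05, gate_on_kw = TRUE) {
  need <- c("gene_id", "comparison", "kw_statistic", "kw_p", "posthoc_p", "log2_fc")
  if (!all(need %in% names(stats))) {
    stop("stats must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  universes <- lapply(split(stats$gene_id, stats$comparison), sort)
  if (length(unique(universes)) > 1) {
    stop("All comparisons must cover the same gene universe.", call. = FALSE)
  }
  out <- stats |>
    group_by(.data$comparison) |>
    mutate(tested = if (gate_on_kw) .data$kw_p < alpha else TRUE) |>
    mutate(p_adjusted = {
      adj <- rep(NA_real_, dplyr::n())
      adj[.data$tested] <- bh_adjust(.data$posthoc_p[.data$tested])
      adj
    }) |>
    ungroup() |>
    mutate(is_deg = !is.na(.data$p_adjusted) &
             abs(.data$log2_fc) > fc_threshold &
             .data$p_adjusted < alpha)
  structure(out, class = c("deg_table", class(out)),
            fc_threshold = fc_threshold, alpha = alpha)
}

#' Run the full differential-expression stage
#'
#' Kruskal-Wallis screening across CD/UC/control, Dunnett-type many-to-one
#' post hoc tests of CD and UC against control, a two-group contrast of CD
#' against UC with the same Monte-Carlo machinery, per-comparison log2 fold
#' changes on linear scale, BH adjustment and DEG calling.
#'
#' @inheritParams dunnett_many_to_one
#' @inheritParams call_degs
#' @param pseudocount Pseudocount for fold changes.
#' @return A `deg_table` covering comparisons `CD_vs_control`,
#'   `UC_vs_control` and `CD_vs_UC`.
#' @export
run_deg_analysis <- function(matrix, metadata, control_group = "control",
                             fc_threshold = 1, alpha = 0.05, gate_on_kw = TRUE,
                             mc_draws = 10000, seed = 1,
                             method = c("dunnett", "steel"), pseudocount = 1) {
  method <- match.arg(method)
  kw <- kruskal_wallis_screen(matrix, metadata)
  post_ctrl <- dunnett_many_to_one(matrix, metadata, control_group,
                                   mc_draws = mc_draws,
                                   seed = derive_seed(seed, "posthoc-control"),
                                   method = method)
  grp <- groups_of(matrix, metadata)
  sub <- names(grp)[grp %in% c("CD", "UC")]
  post_sub <- dunnett_many_to_one(matrix[, sub, drop = FALSE],
                                  metadata[metadata$sample_id %in% sub, , drop = FALSE],
                                  control_group = "UC",
                                  mc_draws = mc_draws,
                                  seed = derive_seed(seed, "posthoc-subtype"),
                                  method = method)
  post <- dplyr::bind_rows(post_ctrl, post_sub)

  fcs <- dplyr::bind_rows(
    mutate(log2_fold_change(matrix, metadata, "CD", control_group, pseudocount),
           comparison = paste0("CD_vs_", control_group)),
    mutate(log2_fold_change(matrix, metadata, "UC", control_group, pseudocount),
           comparison = paste0("UC_vs_", control_group)),
    mutate(log2_fold_change(matrix, metadata, "CD", "UC", pseudocount),
           comparison = "CD_vs_UC")
  )
  stats <- post |>
    dplyr::rename(posthoc_p = "p_value") |>
    left_join(kw, by = "gene_id") |>
    left_join(fcs, by = c("gene_id", "comparison")) |>
    select("gene_id", "comparison", "kw_statistic", "kw_p", "posthoc_p",
           "log2_fc", "estimate", "statistic", "degenerate")
  call_degs(stats, fc_threshold = fc_threshold, alpha = alpha, gate_on_kw = gate_on_kw)
}

#' Extract DEG identifiers from a DEG table
#'
#' @param deg_table A `deg_table`.
#' @param comparisons Comparisons to pool; default the two vs-control
#'   contrasts (a gene differential in either subtype counts).
#' @return Character vector of gene IDs.
#' @export
deg_ids <- function(deg_table, comparisons = c("CD_vs_control", "UC_vs_control")) {
  unique(deg_table$gene_id[deg_table$is_deg & deg_table$comparison %in% comparisons])
}
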