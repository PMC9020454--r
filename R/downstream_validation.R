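#' Read a qPCR CT table
#'
#' Wide CSV: columns `sample_id`, `group`, then one CT column per assayed
#' gene. CT values must be finite and positive.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `sample_id`, canonical `group`, and CT columns.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("qPCR table needs columns sample_id, group plus CT columns.", call. = FALSE)
  }
  ct_cols <- setdiff(names(df), c("sample_id", "group"))
  if (length(ct_cols) < 2) stop("Need a reference gene plus >= 1 target gene.", call. = FALSE)
  for (g in ct_cols) {
    v <- df[[g]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("CT values for '", g, "' must be finite and > 0.", call. = FALSE)
    }
  }
  out <- as_tibble(df)
  out$group <- canonicalize_group(out$group)
  out
}

#' qPCR relative quantification by 2^-ddCT
#'
#' For each sample and target gene, `dCT = CT_gene - CT_reference`; the
#' calibrator is the arithmetic mean control-group dCT per gene, so
#' `ddCT = dCT - mean(control dCT)` and the relative expression is
#' `fold = 2^-ddCT`. The control group therefore has mean ddCT of 0 by
#' construction.
#'
#' @param qpcr_table Tibble as from [read_qpcr_table()].
#' @param reference_gene Housekeeping assay used for dCT (default the
#'   beta-actin assay, `"ACTB"`).
#' @param control_group Calibrator group (default `"control"`).
#' @return A tibble: `sample_id`, `group`, `gene`, `ct`, `dct`, `ddct`,
#'   `fold`; attribute `calibrator` records the per-gene control mean dCT.
#' @export
ddct_fold_change <- function(qpcr_table, reference_gene = "ACTB",
                             control_group = "control") {
  if (!reference_gene %in% names(qpcr_table)) {
    stop("Reference gene '", reference_gene, "' missing from the CT table.", call. = FALSE)
  }
  if (anyNA(qpcr_table[[reference_gene]])) {
    stop("Missing CT for reference gene '", reference_gene, "'.", call. = FALSE)
  }
  if (!control_group %in% qpcr_table$group) {
    stop("Control group '", control_group, "' has no samples.", call. = FALSE)
  }
  targets <- setdiff(names(qpcr_table), c("sample_id", "group", reference_gene))
  long <- tidyr::pivot_longer(qpcr_table, cols = dplyr::all_of(targets),
                              names_to = "gene", values_to = "ct")
  long$dct <- long$ct - long[[reference_gene]]
  calib <- long |>
    filter(.data$group == control_group) |>
    group_by(.data$gene) |>
    summarise(calibrator = mean(.data$dct), .groups = "drop")
  out <- long |>
    left_join(calib, by = "gene") |>
    mutate(ddct = .data$dct - .data$calibrator,
           fold = 2^(-.data$ddct)) |>
    select("sample_id", "group", "gene", "ct", "dct", "ddct", "fold")
  structure(out, calibrator = calib, reference_gene = reference_gene)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks; exact p by enumeration for n <= 9 without
#' ties, t-approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List with `rho` and `p_value`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("Need at least 4 paired observations.", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("Spearman correlation undefined for a constant vector.", call. = FALSE)
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- length(x) <= 9 && !ties
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Per-group ordinary least-squares fit between two genes
#'
#' OLS of `y` on `x`, both on log2 scale, within one sample group — the
#' regression used to examine regulator-to-downstream relationships within
#' CD, UC and control separately.
#'
#' @param x_log2,y_log2 Named numeric vectors (log2-scale expression, names
#'   are sample IDs) or unnamed vectors aligned with `metadata`.
#' @param metadata Sample metadata; `NULL` to use all points.
#' @param group Group to fit within; ignored when `metadata` is `NULL`.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
per_group_linear_fit <- function(x_log2, y_log2, metadata = NULL, group = NULL) {
  if (!is.null(metadata)) {
    ids <- metadata$sample_id[metadata$group == group]
    if (!is.null(names(x_log2))) {
      ids <- intersect(ids, intersect(names(x_log2), names(y_log2)))
      x_log2 <- x_log2[ids]; y_log2 <- y_log2[ids]
    } else {
      keep <- metadata$group == group
      x_log2 <- x_log2[keep]; y_log2 <- y_log2[keep]
    }
  }
  n <- length(x_log2)
  if (n < 3) stop("Need at least 3 points for a linear fit.", call. = FALSE)
  if (sd(x_log2) == 0) stop("Zero variance in x; slope undefined.", call. = FALSE)
  fit <- lm(y_log2 ~ x_log2)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y_log2 - mean(y_log2))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1, n = n)
}

#' Gene-pair correlation and regression within groups
#'
#' Convenience wrapper pairing [spearman_correlation()] and
#' [per_group_linear_fit()] for a pair of genes in an expression matrix.
#'
#' @param matrix Corrected genes-by-samples matrix.
#' @param metadata Sample metadata.
#' @param gene_x,gene_y Gene IDs.
#' @param groups Groups to fit within (besides the pooled fit).
#' @return Tibble with one row per scope (`pooled` plus each group):
#'   `scope`, `rho`, `rho_p`, `slope`, `intercept`, `r_squared`, `n`.
#' @export
regress_gene_pair <- function(matrix, metadata, gene_x, gene_y,
                              groups = c("CD", "UC", "control")) {
  validate_expression_matrix(matrix)
  x <- log2p1(matrix[gene_x, ]); y <- log2p1(matrix[gene_y, ])
  scopes <- c("pooled", groups)
  rows <- purrr::map(scopes, function(sc) {
    if (sc == "pooled") { xi <- x; yi <- y } else {
      ids <- metadata$sample_id[metadata$group == sc]
      xi <- x[intersect(names(x), ids)]; yi <- y[names(xi)]
    }
    sp <- spearman_correlation(xi, yi)
    fit <- per_group_linear_fit(xi, yi)
    tibble(scope = sc, rho = sp$rho, rho_p = sp$p_value, slope = fit$slope,
           intercept = fit$intercept, r_squared = fit$r_squared, n = fit$n)
  })
  dplyr::bind_rows(rows)
}

#' One-way ANOVA with Dunnett-type post hoc on a single feature
#'
#' Delegates to [dunnett_many_to_one()] for one measured variable (e.g. a
#' qPCR fold-change vector): each non-control group is compared against the
#' control group with Monte-Carlo family-wise p-values.
#'
#' @param values Named numeric vector (names = sample IDs).
#' @param metadata Sample metadata.
#' @param control_group Reference group.
#' @param mc_draws,seed Monte-Carlo settings.
#' @return Tibble `comparison`, `estimate`, `statistic`, `p_value`.
#' @export
anova_dunnett_groups <- function(values, metadata, control_group = "control",
                                 mc_draws = 10000, seed = 1) {
  stopifnot(!is.null(names(values)))
  # lift the vector into a 2-row matrix (the contrast machinery is per-gene);
  # the second row is a constant-free dummy never reported
  m <- rbind(feature = values, .dummy = seq_along(values))
  colnames(m) <- names(values)
  res <- dunnett_many_to_one(m, metadata, control_group, mc_draws = mc_draws,
                             seed = seed, method = "dunnett", genes = "feature")
  select(res, "comparison", "estimate", "statistic", "p_value")
}
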