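#' Select correcting reference genes (CRGs) by cross-group stability
#'
#' Runs a one-way ANOVA across the CD, UC and control groups for every
#' candidate housekeeping gene on `log2(x + 1)` intensities, adjusts the
#' p-values with Benjamini-Hochberg across candidates, and selects the `k`
#' genes with the *largest* adjusted p — the most stable candidates. Ties are
#' broken lexicographically by gene ID so the selection is deterministic.
#'
#' @param matrix Genes-by-samples expression matrix (linear scale).
#' @param metadata Sample metadata tibble (`sample_id`, `group`).
#' @param housekeeping_ids Candidate housekeeping gene IDs.
#' @param k Selection size; default 100, the conventional CRG panel size.
#' @return A `crg_selection` tibble: `gene_id`, `f_statistic`, `p_value`,
#'   `p_adjusted`, `selected`; attribute `k`.
#' @export
select_crgs <- function(matrix, metadata, housekeeping_ids, k = 100) {
  validate_expression_matrix(matrix)
  grp <- groups_of(matrix, metadata)
  tab <- table(grp)
  if (length(tab) < 2) stop("Need at least 2 groups for CRG selection.", call. = FALSE)
  if (any(tab < 2)) {
    stop("Every group needs at least 2 samples for ANOVA; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  candidates <- intersect(housekeeping_ids, rownames(matrix))
  if (length(candidates) == 0) {
    stop("No housekeeping candidate is present in the expression matrix.", call. = FALSE)
  }
  g <- factor(grp)
  logx <- log2p1(matrix[candidates, , drop = FALSE])
  stats <- vapply(candidates, function(gene) {
    y <- logx[gene, ]
    if (stats::var(y) == 0) return(c(f = 0, p = 1)) # perfectly flat gene
    fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
    c(f = unname(fit$statistic), p = unname(fit$p.value))
  }, c(f = 0, p = 0))
  res <- tibble(
    gene_id = candidates,
    f_statistic = unname(stats["f", ]),
    p_value = unname(stats["p", ]),
    p_adjusted = unname(p.adjust(stats["p", ], method = "BH"))
  )
  res <- res[order(-res$p_adjusted, res$gene_id), , drop = FALSE]
  k_eff <- min(k, nrow(res))
  res$selected <- seq_len(nrow(res)) <= k_eff
  structure(res, class = c("crg_selection", class(res)), k = k)
}

crg_ids <- function(selection) selection$gene_id[selection$selected]

#' Fit the median-ratio correction model
#'
#' For a chosen reference sample `i`, the correcting coefficient of sample
#' `j` is the ratio of CRG medians,
#' `coefficient(j) = median(CRG expression in i) / median(CRG expression in j)`,
#' so the reference's coefficient is exactly 1.
#'
#' @param matrix Genes-by-samples matrix (linear scale).
#' @param crgs A `crg_selection` or a character vector of CRG IDs.
#' @param reference_sample Sample ID to use as the reference.
#' @return A `correction_model`: list with `reference_sample`, `crg_ids`,
#'   `crg_medians` (per sample) and `coefficients` (per sample, positive).
#' @export
fit_correction <- function(matrix, crgs, reference_sample) {
  validate_expression_matrix(matrix)
  if (inherits(crgs, "crg_selection")) crgs <- crg_ids(crgs)
  crgs <- intersect(crgs, rownames(matrix))
  if (length(crgs) == 0) stop("No CRG present in the matrix.", call. = FALSE)
  if (!reference_sample %in% colnames(matrix)) {
    stop("Reference sample '", reference_sample, "' not in matrix.", call. = FALSE)
  }
  med <- apply(matrix[crgs, , drop = FALSE], 2, median)
  zero <- names(med)[med <= 0]
  if (length(zero) > 0) {
    stop("Zero CRG median in sample(s): ", paste(zero, collapse = ", "), call. = FALSE)
  }
  structure(list(
    reference_sample = reference_sample,
    crg_ids = crgs,
    crg_medians = med,
    coefficients = med[[reference_sample]] / med
  ), class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model> reference %s, %d CRGs, %d samples, coefficients in [%.3g, %.3g]\n",
              x$reference_sample, length(x$crg_ids), length(x$coefficients),
              min(x$coefficients), max(x$coefficients)))
  invisible(x)
}

#' Apply a fitted median-ratio correction
#'
#' Multiplies every value of sample `j` by `coefficient(j)`. Afterwards every
#' sample's CRG median equals the reference sample's CRG median.
#'
#' @param matrix Genes-by-samples matrix (linear scale).
#' @param model A `correction_model` from [fit_correction()].
#' @return The corrected matrix.
#' @export
apply_correction <- function(matrix, model) {
  validate_expression_matrix(matrix)
  missing <- setdiff(colnames(matrix), names(model$coefficients))
  if (length(missing) > 0) {
    stop("Correction model missing sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sweep(matrix, 2, model$coefficients[colnames(matrix)], `*`)
}

#' One-step housekeeping batch correction
#'
#' Convenience wrapper: select CRGs, pick the reference sample (seeded random
#' draw when not supplied — the choice is recorded in the returned model),
#' fit and apply.
#'
#' @inheritParams select_crgs
#' @param reference_sample Sample ID, or `NULL` to draw one at random.
#' @param seed Seed for the random reference draw.
#' @return List with `matrix` (corrected), `model`, `crg_selection`.
#' @export
correct_batch_effects <- function(matrix, metadata, housekeeping_ids, k = 100,
                                  reference_sample = NULL, seed = 1) {
  selection <- select_crgs(matrix, metadata, housekeeping_ids, k = k)
  if (is.null(reference_sample)) {
    set.seed(derive_seed(seed, "reference-sample"))
    reference_sample <- sample(colnames(matrix), 1)
  }
  model <- fit_correction(matrix, selection, reference_sample)
  list(matrix = apply_correction(matrix, model), model = model,
       crg_selection = selection)
}
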