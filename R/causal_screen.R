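#' Merge pathway graphs into a prior network
#'
#' Node and edge union of the differentially expressed pathways' graphs.
#' Duplicate `(source, target)` edges are collapsed keeping the first-seen
#' interaction type, and every contributing pathway is recorded in the edge's
#' provenance. Merged KEGG-style graphs may be cyclic; cyclicity is reported,
#' not "fixed".
#'
#' @param pathway_graphs Non-empty list of `pathway_graph` objects.
#' @return A `priori_network`: list with `nodes`, `edges` (tibble `source`,
#'   `target`, `interaction`, list-column `provenance`) and `is_cyclic`.
#' @export
merge_priori_network <- function(pathway_graphs) {
  if (length(pathway_graphs) == 0) {
    stop("Cannot merge an empty list of pathway graphs.", call. = FALSE)
  }
  stopifnot(all(vapply(pathway_graphs, inherits, logical(1), "pathway_graph")))
  all_edges <- dplyr::bind_rows(lapply(pathway_graphs, function(g) {
    mutate(g$edges, pathway_id = g$pathway_id)
  }))
  nodes <- unique(unlist(lapply(pathway_graphs, `[[`, "nodes")))
  if (nrow(all_edges) > 0) {
    key <- paste(all_edges$source, all_edges$target, sep = "\r")
    first <- !duplicated(key)
    prov <- split(all_edges$pathway_id, factor(key, levels = key[first]))
    edges <- all_edges[first, c("source", "target", "interaction")]
    edges$provenance <- unname(prov)
  } else {
    edges <- tibble(source = character(), target = character(),
                    interaction = character(), provenance = list())
  }
  g <- igraph::graph_from_data_frame(edges[, c("source", "target")], vertices = nodes)
  structure(list(nodes = nodes, edges = as_tibble(edges),
                 is_cyclic = !igraph::is_dag(g)),
            class = "priori_network")
}

#' @export
print.priori_network <- function(x, ...) {
  cat(sprintf("<priori_network> %d nodes, %d edges%s\n", length(x$nodes),
              nrow(x$edges), if (x$is_cyclic) " (cyclic)" else ""))
  invisible(x)
}

#' Backdoor adjustment set for a treatment gene
#'
#' Returns the network parents of the treatment gene intersected with the
#' measured genes — parents form a valid backdoor set when the outcome is not
#' a network ancestor of the treatment. Unmeasured parents are dropped with a
#' warning.
#'
#' @param network A `priori_network`.
#' @param treatment_gene Gene ID; must be a network node.
#' @param measured_genes Genes available in the expression matrix.
#' @return Character vector of adjustment genes (possibly empty).
#' @export
adjustment_set_for <- function(network, treatment_gene, measured_genes) {
  if (!treatment_gene %in% network$nodes) {
    stop("Treatment gene '", treatment_gene, "' is not in the prior network.",
         call. = FALSE)
  }
  parents <- unique(network$edges$source[network$edges$target == treatment_gene])
  dropped <- setdiff(parents, measured_genes)
  if (length(dropped) > 0) {
    warning("Unmeasured parent(s) of ", treatment_gene, " dropped from adjustment set: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  intersect(parents, measured_genes)
}

# design matrix + FWL residual machinery shared by estimate and permutation
cev_prepare <- function(matrix, metadata, treatment_gene, adjustment_set,
                        outcome = NULL) {
  validate_expression_matrix(matrix)
  if (is.null(outcome)) {
    grp <- groups_of(matrix, metadata)
    keep <- names(grp)[grp %in% c("CD", "UC")]
    if (length(keep) == 0) stop("No CD/UC samples for causal estimation.", call. = FALSE)
    outcome <- setNames(as.numeric(grp[keep] == "CD"), keep)
  } else {
    stopifnot(!is.null(names(outcome)))
    keep <- intersect(colnames(matrix), names(outcome))
  }
  genes <- c(treatment_gene, adjustment_set)
  absent <- setdiff(genes, rownames(matrix))
  if (length(absent) > 0) {
    stop("Gene(s) absent from matrix: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  if (treatment_gene %in% adjustment_set) {
    stop("Adjustment set must exclude the treatment gene.", call. = FALSE)
  }
  n <- length(keep)
  if (n <= length(adjustment_set) + 2) {
    stop(sprintf("Under-determined causal fit: n = %d samples for %d adjustment covariates.",
                 n, length(adjustment_set)), call. = FALSE)
  }
  y <- unname(outcome[keep])
  if (all(y == y[1])) y <- rep(0, n) # constant outcome: exact-zero residuals
  tvec <- log2p1(matrix[treatment_gene, keep])
  X <- cbind(`(intercept)` = rep(1, n))
  if (length(adjustment_set) > 0) {
    X <- cbind(X, t(log2p1(matrix[adjustment_set, keep, drop = FALSE])))
  }
  dq <- qr(cbind(X, treatment = tvec))
  if (dq$rank < ncol(X) + 1) {
    culprit <- colnames(cbind(X, treatment = tvec))[dq$pivot[-seq_len(dq$rank)]]
    stop("Collinear design for treatment '", treatment_gene, "': ",
         paste(culprit, collapse = ", "), call. = FALSE)
  }
  Q <- qr.Q(qr(X))
  rT <- tvec - drop(Q %*% crossprod(Q, tvec))
  rY <- y - drop(Q %*% crossprod(Q, y))
  list(Q = Q, rT = rT, rY = rY, tvec = tvec, y = y, n = n, samples = keep)
}

#' Backdoor-adjusted causal estimate value (CEV)
#'
#' Estimates the effect of a gene's expression on the CD-vs-UC subtype as the
#' coefficient of the treatment gene in a least-squares fit of the 0/1
#' outcome (CD = 1, UC = 0) on an intercept, the treatment and its backdoor
#' adjustment set, all expressions `log2(x + 1)`-transformed (a
#' linear-probability reading of "change in the outcome per unit change of
#' the treatment"). Control samples are excluded.
#'
#' @param matrix Corrected genes-by-samples matrix.
#' @param metadata Sample metadata.
#' @param treatment_gene Gene whose effect is estimated.
#' @param adjustment_set Covariate genes (e.g. from [adjustment_set_for()]).
#' @param outcome Optional named numeric outcome per sample (e.g. a
#'   continuous severity score); the default uses the CD = 1 / UC = 0 coding
#'   over the subtype samples.
#' @return List with `cev`, `n` (samples used), `adjustment_set`.
#' @export
estimate_cev <- function(matrix, metadata, treatment_gene, adjustment_set = character(0),
                         outcome = NULL) {
  prep <- cev_prepare(matrix, metadata, treatment_gene, adjustment_set, outcome)
  den <- sum(prep$rT^2)
  cev <- if (den > 0) sum(prep$rT * prep$rY) / den else 0
  list(cev = cev, n = prep$n, adjustment_set = adjustment_set)
}

#' Placebo-treatment permutation significance of a CEV
#'
#' Builds the null by permuting the treatment gene's expression vector across
#' samples, holding the outcome and the adjustment covariates fixed, and
#' refitting the backdoor regression each draw. The exceedance comparison is
#' two-sided on the *studentized* CEV (the coefficient divided by its OLS
#' standard error), with `p = (1 + #\{|t_perm| >= |t_obs|\}) / (1 + B)`.
#' Studentization matters: permuting the treatment destroys its correlation
#' with the adjustment covariates, so raw permuted coefficients have
#' systematically smaller sampling variance than the observed one whenever
#' treatment and covariates are correlated, making a raw-coefficient
#' comparison anti-conservative; the studentized statistic is pivotal under
#' permutation and keeps the test calibrated.
#'
#' @inheritParams estimate_cev
#' @param B Number of permutations (>= 99; default 1000).
#' @param seed Integer seed.
#' @return List with `cev`, `p_value`, `n`, `B`, `adjustment_set`.
#' @export
permutation_significance <- function(matrix, metadata, treatment_gene,
                                     adjustment_set = character(0), B = 1000, seed = 1,
                                     outcome = NULL) {
  stopifnot(B >= 99)
  prep <- cev_prepare(matrix, metadata, treatment_gene, adjustment_set, outcome)
  den <- sum(prep$rT^2)
  if (den == 0) {
    stop("Treatment gene '", treatment_gene, "' has zero residual variance.", call. = FALSE)
  }
  cev <- sum(prep$rT * prep$rY) / den
  n <- prep$n
  df <- n - length(adjustment_set) - 2
  ssy <- sum(prep$rY^2)
  # studentized coefficient: t = cev / se with se^2 = RSS / (df * ||rT||^2)
  studentize <- function(coefs, dens) {
    rss <- pmax(ssy - coefs^2 * dens, 0)
    ifelse(rss > 0 & dens > 0, coefs * sqrt(df * dens / rss),
           ifelse(coefs == 0, 0, Inf * sign(coefs)))
  }
  t_obs <- studentize(cev, den)
  set.seed(seed)
  perm_idx <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
  TP <- matrix(prep$tvec[perm_idx], nrow = n) # n x B permuted treatments
  RP <- TP - prep$Q %*% crossprod(prep$Q, TP)
  num <- drop(crossprod(RP, prep$rY))
  dens <- colSums(RP^2)
  cev_perm <- ifelse(dens > 0, num / dens, 0)
  t_perm <- studentize(cev_perm, dens)
  if (ssy == 0) { t_obs <- 0; t_perm <- rep(0, B) } # constant outcome
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + B)
  list(cev = cev, statistic = t_obs, p_value = p, n = n, B = B,
       adjustment_set = adjustment_set)
}

#' Screen candidate genes for causal effects on the subtype
#'
#' Runs backdoor estimation plus permutation significance for every candidate
#' gene that is a node of the prior network (candidates are typically the
#' DEGs found against control). Each gene gets its own permutation stream
#' derived from `(seed, gene)`.
#'
#' @param matrix Corrected genes-by-samples matrix.
#' @param metadata Sample metadata.
#' @param network A `priori_network`.
#' @param candidate_genes Genes to screen; silently restricted to network
#'   nodes present in the matrix.
#' @param B Permutations per gene (default 1000).
#' @param seed Integer master seed.
#' @return A `causal_result` tibble: `gene_id`, `cev`, `p_value`, `n`, `B`,
#'   `n_adjust`, list-column `adjustment_set`.
#' @export
screen_causal_effects <- function(matrix, metadata, network, candidate_genes,
                                  B = 1000, seed = 1) {
  cands <- intersect(intersect(candidate_genes, network$nodes), rownames(matrix))
  rows <- purrr::map(cands, function(g) {
    adj <- adjustment_set_for(network, g, rownames(matrix))
    res <- permutation_significance(matrix, metadata, g, adj, B = B,
                                    seed = derive_seed(seed, "causal", g))
    tibble(gene_id = g, cev = res$cev, p_value = res$p_value, n = res$n,
           B = B, n_adjust = length(adj), adjustment_set = list(adj))
  })
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else
    tibble(gene_id = character(), cev = numeric(), p_value = numeric(),
           n = integer(), B = integer(), n_adjust = integer(),
           adjustment_set = list())
  structure(out, class = c("causal_result", class(tibble())))
}

#' Call subtype-regulators
#'
#' A gene is a subtype-regulator iff its causal permutation p is below
#' `alpha` *and* it is differentially expressed between the subtypes: a
#' two-sided rank-sum (Wilcoxon) test of CD vs UC per candidate, BH-adjusted
#' across candidates.
#'
#' @param causal_results A `causal_result` tibble.
#' @param matrix Corrected genes-by-samples matrix.
#' @param metadata Sample metadata.
#' @param alpha Significance level for both gates (default 0.05).
#' @return A `regulator_calls` tibble: `gene_id`, `cev`, `causal_p`,
#'   `subtype_p`, `subtype_p_adjusted`, `is_regulator`.
#' @export
call_subtype_regulators <- function(causal_results, matrix, metadata, alpha = 0.05) {
  if (nrow(causal_results) == 0) {
    return(structure(
      tibble(gene_id = character(), cev = numeric(), causal_p = numeric(),
             subtype_p = numeric(), subtype_p_adjusted = numeric(),
             is_regulator = logical()),
      class = c("regulator_calls", class(tibble()))
    ))
  }
  grp <- groups_of(matrix, metadata)
  cd <- names(grp)[grp == "CD"]; uc <- names(grp)[grp == "UC"]
  subtype_p <- vapply(causal_results$gene_id, function(g) {
    suppressWarnings(wilcox.test(matrix[g, cd], matrix[g, uc])$p.value)
  }, numeric(1))
  out <- tibble(
    gene_id = causal_results$gene_id,
    cev = causal_results$cev,
    causal_p = causal_results$p_value,
    subtype_p = unname(subtype_p),
    subtype_p_adjusted = bh_adjust(unname(subtype_p)),
    is_regulator = causal_results$p_value < alpha & bh_adjust(unname(subtype_p)) < alpha
  )
  structure(out, class = c("regulator_calls", class(out)), alpha = alpha)
}
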