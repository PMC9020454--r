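#' One-sided hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of DEG overlap per gene set, with sets
#' intersected with the universe first and BH adjustment across tested sets.
#' The default flagging threshold (adjusted p < 1e-3) is the conventional
#' strict gate for pathway enrichment in this pipeline.
#'
#' @param deg_ids DEG identifiers (must be a subset of the universe).
#' @param universe_ids The gene universe (all measured genes).
#' @param gene_sets Gene-set tibble as from [read_gene_sets_gmt()].
#' @param alpha_adj Adjusted-p threshold for the `enriched` flag.
#' @return An `enrichment_table` tibble: `set_id`, `overlap` (k), `set_size`
#'   (K within universe), `n_degs` (n), `universe` (N), `p_value`,
#'   `p_adjusted`, `enriched`.
#' @export
hypergeometric_enrich <- function(deg_ids, universe_ids, gene_sets, alpha_adj = 1e-3) {
  universe_ids <- unique(universe_ids)
  if (length(universe_ids) == 0) stop("Empty gene universe.", call. = FALSE)
  deg_ids <- unique(deg_ids)
  stray <- setdiff(deg_ids, universe_ids)
  if (length(stray) > 0) {
    stop("DEG(s) outside the universe: ", paste(head(stray, 5), collapse = ", "),
         call. = FALSE)
  }
  N <- length(universe_ids); n <- length(deg_ids)
  empty <- tibble(set_id = character(), overlap = integer(), set_size = integer(),
                  n_degs = integer(), universe = integer(),
                  p_value = numeric(), p_adjusted = numeric(), enriched = logical())
  if (n == 0) {
    return(structure(empty, class = c("enrichment_table", class(empty)),
                     alpha_adj = alpha_adj))
  }
  rows <- purrr::map(seq_len(nrow(gene_sets)), function(i) {
    members <- intersect(gene_sets$genes[[i]], universe_ids)
    K <- length(members)
    if (K == 0) return(NULL) # set absent from the universe: skipped
    k <- length(intersect(members, deg_ids))
    tibble(set_id = gene_sets$set_id[i], overlap = k, set_size = K,
           n_degs = n, universe = N,
           p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- empty
  } else {
    out$p_adjusted <- bh_adjust(out$p_value)
    out$enriched <- out$p_adjusted < alpha_adj
  }
  structure(out, class = c("enrichment_table", class(out)), alpha_adj = alpha_adj)
}

#' Quantify a pathway as a per-sample scalar score
#'
#' Projects the pathway's expression submatrix onto one dimension: each
#' member gene is standardised across samples (zero mean, unit variance;
#' zero-variance genes are dropped with a warning), the samples are projected
#' onto the first principal axis of the standardised submatrix, and the sign
#' is fixed so the score correlates non-negatively with mean pathway
#' expression ("higher score = higher expression"). Scores have zero mean
#' over samples by construction.
#'
#' @param matrix Genes-by-samples matrix (corrected, linear scale).
#' @param gene_set Character vector of member gene IDs, or a single row of a
#'   gene-set tibble.
#' @param pathway_id Identifier attached to the profile.
#' @return A `qpa_profile`: list with `pathway_id`, `scores` (named
#'   per-sample), `loadings` (per retained gene), `var_explained`,
#'   `orientation` (+1/-1), `genes_used`.
#' @export
qpa_quantify <- function(matrix, gene_set, pathway_id = "pathway") {
  validate_expression_matrix(matrix)
  if (is.list(gene_set)) gene_set <- unlist(gene_set)
  genes <- intersect(gene_set, rownames(matrix))
  if (length(genes) == 0) {
    stop("No pathway gene present in the matrix for '", pathway_id, "'.", call. = FALSE)
  }
  sub <- matrix[genes, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("Dropping %d zero-variance gene(s) from pathway '%s'.",
                    sum(sds == 0), pathway_id), call. = FALSE)
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(sub) == 0) {
    stop("All pathway genes are zero-variance in '", pathway_id, "'.", call. = FALSE)
  }
  z <- (sub - rowMeans(sub)) / sds # genes x samples, standardised per gene
  sv <- svd(t(z)) # samples x genes
  scores <- sv$u[, 1] * sv$d[1]
  loadings <- sv$v[, 1]
  # orient so the score tracks mean pathway expression non-negatively
  mean_expr <- colMeans(z)
  s <- sum(scores * mean_expr)
  orientation <- if (s < 0) -1 else 1
  scores <- scores * orientation
  loadings <- loadings * orientation
  structure(list(
    pathway_id = pathway_id,
    scores = setNames(scores, colnames(matrix)),
    loadings = setNames(loadings, rownames(sub)),
    var_explained = sv$d[1]^2 / sum(sv$d^2),
    orientation = orientation,
    genes_used = rownames(sub)
  ), class = "qpa_profile")
}

#' @export
print.qpa_profile <- function(x, ...) {
  cat(sprintf("<qpa_profile> %s: %d genes, %d samples, %.1f%% variance on axis 1\n",
              x$pathway_id, length(x$genes_used), length(x$scores),
              100 * x$var_explained))
  invisible(x)
}

#' Compare pathway scores between two groups by permutation
#'
#' The comparison statistic is the absolute difference of group mean scores;
#' the null is built by shuffling the group labels within the two groups `B`
#' times (scores fixed), and the p-value uses the exceedance convention
#' `p = (1 + #\{Delta_perm >= Delta_obs\}) / (1 + B)`, so p is never 0 and
#' its floor `1/(B+1)` is attained only when the observed difference exceeds
#' every permuted one.
#'
#' @param profile A `qpa_profile`.
#' @param metadata Sample metadata.
#' @param group_a,group_b Groups to contrast (default CD vs UC).
#' @param B Number of permutations (>= 99; default 1000).
#' @param seed Integer seed.
#' @param alpha Significance level for the `is_dep` flag.
#' @return A `dep_record` one-row tibble: `pathway_id`, `delta`, `B`,
#'   `p_value`, `is_dep`.
#' @export
qpa_compare_groups <- function(profile, metadata, group_a = "CD", group_b = "UC",
                               B = 1000, seed = 1, alpha = 0.05) {
  stopifnot(inherits(profile, "qpa_profile"), B >= 99)
  md <- metadata[match(names(profile$scores), metadata$sample_id), , drop = FALSE]
  ia <- which(md$group == group_a); ib <- which(md$group == group_b)
  if (length(ia) == 0 || length(ib) == 0) {
    stop("Group without samples in the score profile: ",
         if (length(ia) == 0) group_a else group_b, call. = FALSE)
  }
  sc <- profile$scores[c(ia, ib)]
  na <- length(ia)
  delta_obs <- abs(mean(sc[seq_len(na)]) - mean(sc[-seq_len(na)]))
  set.seed(seed)
  total <- sum(sc); nn <- length(sc); nb <- nn - na
  exceed <- 0L
  for (b in seq_len(B)) {
    pa <- sum(sc[sample.int(nn, na)])
    d <- abs(pa / na - (total - pa) / nb)
    if (d >= delta_obs - 1e-12) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (1 + B)
  structure(
    tibble(pathway_id = profile$pathway_id, delta = delta_obs, B = B,
           p_value = p, is_dep = p < alpha),
    class = c("dep_record", "tbl_df", "tbl", "data.frame")
  )
}

#' Find differentially expressed pathways (DEPs)
#'
#' Runs [qpa_quantify()] and [qpa_compare_groups()] (CD vs UC) for every
#' candidate gene set — the union of sets enriched in either subtype-vs-
#' control comparison. Each pathway gets its own permutation stream derived
#' deterministically from `(seed, pathway_id)`, so adding or removing a
#' candidate never changes another pathway's p-value.
#'
#' @param matrix Corrected genes-by-samples matrix.
#' @param metadata Sample metadata.
#' @param candidate_sets Gene-set tibble (`set_id`, `genes`).
#' @param B Permutations per pathway (default 1000).
#' @param seed Integer master seed.
#' @param alpha DEP significance level (default 0.05).
#' @param group_a,group_b Groups contrasted (default CD vs UC).
#' @return A `dep_table` tibble, one row per candidate pathway.
#' @export
find_deps <- function(matrix, metadata, candidate_sets, B = 1000, seed = 1,
                      alpha = 0.05, group_a = "CD", group_b = "UC") {
  if (nrow(candidate_sets) == 0) {
    return(structure(
      tibble(pathway_id = character(), delta = numeric(), B = integer(),
             p_value = numeric(), is_dep = logical()),
      class = c("dep_table", "tbl_df", "tbl", "data.frame")
    ))
  }
  rows <- purrr::map(seq_len(nrow(candidate_sets)), function(i) {
    id <- candidate_sets$set_id[i]
    prof <- qpa_quantify(matrix, candidate_sets$genes[[i]], pathway_id = id)
    qpa_compare_groups(prof, metadata, group_a, group_b, B = B,
                       seed = derive_seed(seed, "qpa", id), alpha = alpha)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("dep_table", class(tibble())), alpha = alpha)
}
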