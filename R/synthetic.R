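#' Specify the planted causal cascade
#'
#' The generator embeds a three-gene motif `A -> B -> C` in which the upstream
#' regulator `A` and the mediator `B` carry nonzero outcome coefficients while
#' the downstream gene `C` does not: `C` is correlated with the subtype label
#' only through its parent `B`. This is the synthetic analogue of an
#' upstream cytokine cascade whose terminal gene tracks disease without
#' driving it.
#'
#' @param a,b,c Gene identifiers for the upstream regulator, the mediator and
#'   the non-causal downstream gene.
#' @param gamma Length-3 numeric: log-odds of CD (vs UC) per SD of each
#'   cascade gene's expression, in order (a, b, c). `gamma[3]` must be 0.
#' @param w_ab,w_bc Linear edge weights of `a -> b` and `b -> c`.
#' @return A `cascade_spec` list.
#' @export
cascade_spec <- function(a = "regA", b = "medB", c = "dsC",
                         gamma = c(1.5, 1.0, 0), w_ab = 0.8, w_bc = 0.8) {
  genes <- c(a, b, c)
  if (anyDuplicated(genes)) {
    stop("Cascade genes must be distinct (a cyclic cascade is not allowed).", call. = FALSE)
  }
  stopifnot(length(gamma) == 3, is.numeric(gamma))
  if (gamma[3] != 0) {
    stop("The downstream cascade gene must have outcome coefficient 0.", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, gamma = setNames(gamma, genes),
                 w_ab = w_ab, w_bc = w_bc),
            class = "cascade_spec")
}

#' Build a ground-truth generating model
#'
#' Constructs a linear-Gaussian structural model over `n_genes` genes:
#' a set of housekeeping genes (no incoming edges, no group shift), the
#' remaining genes partitioned into `n_pathways` gene sets each carrying a
#' random acyclic edge set, the cascade of [cascade_spec()] embedded in the
#' first pathway, an additive disease shift on the members of the first
#' `n_shifted_pathways` pathways (identical for CD and UC — subtype
#' separation arises only through the outcome model), and a logistic
#' CD-vs-UC outcome model on the cascade regulators.
#'
#' @param n_genes Total number of genes including housekeeping genes.
#' @param n_pathways Number of gene sets/pathway graphs.
#' @param cascade_spec A [cascade_spec()].
#' @param seed Integer seed; the truth is a pure function of the arguments.
#' @param n_housekeeping Number of housekeeping genes.
#' @param mu_range Range of baseline mean intensities (linear scale).
#' @param cv Per-gene coefficient of variation of pathway genes:
#'   `sigma_g = cv * mu_g`.
#' @param cv_housekeeping Coefficient of variation of housekeeping genes;
#'   much smaller than `cv`, reflecting the biological stability that makes
#'   them usable as correction references.
#' @param disease_effect_sd Disease shift on shifted-pathway genes, in units
#'   of the gene's noise SD.
#' @param edge_prob Probability of a random forward edge between two members
#'   of the same pathway.
#' @param weight_range Range of random edge weights.
#' @param n_shifted_pathways How many pathways receive the disease shift
#'   (0 for a global null).
#' @param batch_scale Multiplicative intensity ratio of the second batch to
#'   the first.
#' @param batch_jitter SD of per-sample log-normal jitter on batch factors.
#' @return A `synthetic_truth` object; see Details.
#' @details The object bundles: `genes` (tibble `gene_id`, `mu`, `sigma`,
#'   `housekeeping`, `pathway`), `edges` (tibble `source`, `target`,
#'   `weight`, `interaction`), `delta` (tibble `gene_id`, `CD`, `UC`,
#'   `control`), `gamma` (named, per SD), `regulators`
#'   (genes with nonzero `gamma`), `gene_sets` (GMT-style tibble),
#'   `pathway_graphs` (list of `pathway_graph`), and batch parameters.
#' @export
build_truth_network <- function(n_genes = 48, n_pathways = 6, cascade_spec = causalqpa::cascade_spec(),
                                seed = 1, n_housekeeping = 12,
                                mu_range = c(20, 40), cv = 0.5, cv_housekeeping = 0.05,
                                disease_effect_sd = 3, edge_prob = 0.15,
                                weight_range = c(0.2, 0.5),
                                n_shifted_pathways = 2,
                                batch_scale = 1.8, batch_jitter = 0.1) {
  stopifnot(inherits(cascade_spec, "cascade_spec"), n_pathways >= 1,
            n_shifted_pathways <= n_pathways, n_housekeeping >= 2)
  n_pathway_genes <- n_genes - n_housekeeping
  if (n_pathway_genes < 3 + (n_pathways - 1)) {
    stop("n_genes too small for the cascade plus housekeeping genes.", call. = FALSE)
  }
  set.seed(derive_seed(seed, "truth"))

  hk_ids <- sprintf("hk%02d", seq_len(n_housekeeping))
  other_n <- n_pathway_genes - 3
  other_ids <- if (other_n > 0) sprintf("g%03d", seq_len(other_n)) else character(0)
  casc <- c(cascade_spec$a, cascade_spec$b, cascade_spec$c)

  # pathway membership: cascade genes head pathway 1; remaining genes split
  # roughly evenly across pathways
  assign_pw <- sort(rep_len(seq_len(n_pathways), other_n))
  members <- split(other_ids, factor(assign_pw, levels = seq_len(n_pathways)))
  members[[1]] <- c(casc, members[[1]])
  pw_ids <- sprintf("pw%02d", seq_len(n_pathways))
  names(members) <- pw_ids

  gene_ids <- c(unlist(members, use.names = FALSE), hk_ids)
  pathway_of <- setNames(rep(NA_character_, length(gene_ids)), gene_ids)
  for (p in pw_ids) pathway_of[members[[p]]] <- p

  mu <- setNames(runif(length(gene_ids), mu_range[1], mu_range[2]), gene_ids)
  sigma <- ifelse(gene_ids %in% hk_ids, cv_housekeeping, cv) * mu

  # random forward edges within each pathway keep the graph acyclic; the
  # cascade edges are fixed
  edge_list <- list(tibble(
    source = c(cascade_spec$a, cascade_spec$b),
    target = c(cascade_spec$b, cascade_spec$c),
    weight = c(cascade_spec$w_ab, cascade_spec$w_bc),
    interaction = "activation"
  ))
  for (p in pw_ids) {
    mem <- members[[p]]
    if (length(mem) < 2) next
    pairs <- which(upper.tri(diag(length(mem))), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < edge_prob
    if (!any(keep)) next
    e <- tibble(
      source = mem[pairs[keep, 1]],
      target = mem[pairs[keep, 2]],
      weight = runif(sum(keep), weight_range[1], weight_range[2]),
      interaction = "activation"
    )
    edge_list <- c(edge_list, list(e))
  }
  edges <- dplyr::bind_rows(edge_list)
  edges <- edges[!duplicated(paste(edges$source, edges$target, sep = "\r")), , drop = FALSE]

  # disease shift: members of the first n_shifted_pathways pathways, CD == UC
  shifted <- unlist(members[seq_len(n_shifted_pathways)], use.names = FALSE)
  delta <- tibble(
    gene_id = gene_ids,
    CD = ifelse(gene_ids %in% shifted, disease_effect_sd * sigma[gene_ids], 0),
    UC = ifelse(gene_ids %in% shifted, disease_effect_sd * sigma[gene_ids], 0),
    control = 0
  )

  gamma <- setNames(numeric(length(gene_ids)), gene_ids)
  gamma[names(cascade_spec$gamma)] <- cascade_spec$gamma

  gene_sets <- tibble(
    set_id = pw_ids,
    description = sprintf("synthetic pathway %s", pw_ids),
    genes = unname(members)
  )
  pathway_graphs <- lapply(pw_ids, function(p) {
    e <- edges[edges$source %in% members[[p]] & edges$target %in% members[[p]], , drop = FALSE]
    new_pathway_graph(p, edges = e[, c("source", "target", "interaction")],
                      nodes = members[[p]])
  })
  names(pathway_graphs) <- pw_ids

  truth <- structure(list(
    genes = tibble(gene_id = gene_ids, mu = unname(mu), sigma = unname(sigma),
                   housekeeping = gene_ids %in% hk_ids,
                   pathway = unname(pathway_of)),
    edges = edges,
    delta = delta,
    gamma = gamma,
    regulators = names(gamma)[gamma != 0],
    cascade = list(a = cascade_spec$a, b = cascade_spec$b, c = cascade_spec$c),
    housekeeping = hk_ids,
    gene_sets = gene_sets,
    pathway_graphs = pathway_graphs,
    batch_scale = batch_scale,
    batch_jitter = batch_jitter,
    seed = seed,
    schema_version = "1.0"
  ), class = "synthetic_truth")
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  g <- igraph::graph_from_data_frame(truth$edges[, c("source", "target")],
                                     vertices = truth$genes$gene_id)
  if (!igraph::is_dag(g)) stop("Generating network must be acyclic.", call. = FALSE)
  hk_in <- truth$edges$target %in% truth$housekeeping
  if (any(hk_in)) stop("Housekeeping genes must have no incoming edges.", call. = FALSE)
  hk_delta <- truth$delta[truth$delta$gene_id %in% truth$housekeeping, c("CD", "UC", "control")]
  if (any(unlist(hk_delta) != 0)) stop("Housekeeping genes must have zero group shift.", call. = FALSE)
  if (any(truth$genes$sigma < 0)) stop("Negative noise SD in truth.", call. = FALSE)
  invisible(truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d genes (%d housekeeping), %d edges, %d pathways, regulators: %s\n",
    nrow(x$genes), length(x$housekeeping), nrow(x$edges),
    nrow(x$gene_sets),
    if (length(x$regulators)) paste(x$regulators, collapse = ", ") else "(none)"
  ))
  invisible(x)
}

# edge-weight matrix A with A[target, source] = w, genes in truth order
truth_weight_matrix <- function(truth) {
  ids <- truth$genes$gene_id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  A[cbind(truth$edges$target, truth$edges$source)] <- truth$edges$weight
  A
}

#' Model-implied covariance of the generating structural model
#'
#' Path-tracing covariance of the linear-Gaussian model,
#' `Sigma = (I - A)^-1 D (I - A)^-T` with `A` the weight matrix and `D` the
#' diagonal of noise variances. Group shifts do not enter the covariance.
#'
#' @param truth A `synthetic_truth`.
#' @return Gene-by-gene covariance matrix.
#' @export
truth_covariance <- function(truth) {
  A <- truth_weight_matrix(truth)
  n <- nrow(A)
  M <- solve(diag(n) - A)
  S <- M %*% diag(truth$genes$sigma^2, n) %*% t(M)
  dimnames(S) <- dimnames(A)
  S
}

# expected gene means under a given delta column, propagated through the
# network in one linear solve: m = mu + (I - A)^-1 delta
truth_means <- function(truth, delta) {
  A <- truth_weight_matrix(truth)
  mu <- setNames(truth$genes$mu, truth$genes$gene_id)
  mu + drop(solve(diag(nrow(A)) - A, delta[truth$genes$gene_id]))
}

# one cohort draw: genes x n matrix generated in topological order
generate_cohort <- function(truth, n, delta) {
  ids <- truth$genes$gene_id
  mu <- setNames(truth$genes$mu, ids)
  sigma <- setNames(truth$genes$sigma, ids)
  ord <- igraph::topo_sort(igraph::graph_from_data_frame(
    truth$edges[, c("source", "target")], vertices = ids))$name
  x <- matrix(0, length(ids), n, dimnames = list(ids, NULL))
  for (g in ord) {
    contrib <- 0
    pa <- truth$edges[truth$edges$target == g, , drop = FALSE]
    if (nrow(pa) > 0) {
      dev <- x[pa$source, , drop = FALSE] - mu[pa$source]
      contrib <- drop(crossprod(dev, pa$weight))
    }
    x[g, ] <- mu[g] + delta[g] + contrib + rnorm(n, 0, sigma[g])
  }
  x
}

#' Simulate an expression cohort from a ground truth
#'
#' Control samples are drawn with zero group shift. IBD samples are drawn
#' with the disease shift and their CD/UC label is then *drawn from* the
#' logistic outcome model applied to the (SD-standardised) regulator
#' expressions — so the regulators literally cause the subtype. Sampling
#' continues until `n_per_group` CD and UC samples are collected. Negative
#' intensities are truncated at 0. Batch labels alternate within each group
#' (balanced design) and per-sample multiplicative batch factors are drawn
#' but NOT applied; see [apply_batch_distortion()].
#'
#' @param truth A `synthetic_truth`.
#' @param n_per_group Samples per group (CD, UC, control); at least 3.
#' @param seed Integer seed.
#' @return A `synthetic_cohort` list: `matrix` (genes x samples, undistorted),
#'   `metadata` (tibble `sample_id`, `group`, `batch`), `batch_factors`
#'   (named, positive), `truth`.
#' @export
simulate_expression <- function(truth, n_per_group, seed) {
  stopifnot(inherits(truth, "synthetic_truth"), n_per_group >= 3)
  if (any(truth$genes$sigma < 0)) stop("Negative noise SD in truth.", call. = FALSE)
  set.seed(derive_seed(seed, "simulate"))
  ids <- truth$genes$gene_id
  delta0 <- setNames(numeric(length(ids)), ids)
  delta_ibd <- setNames((truth$delta$CD + truth$delta$UC) / 2, truth$delta$gene_id)[ids]

  ctrl <- generate_cohort(truth, n_per_group, delta0)

  # outcome model operates on SD-standardised deviations from the IBD-pool mean
  nu <- truth_means(truth, delta_ibd)
  sdv <- sqrt(pmax(diag(truth_covariance(truth)), 1e-12))
  reg <- truth$regulators
  cd <- list(); uc <- list(); n_cd <- 0; n_uc <- 0
  tries <- 0
  while ((n_cd < n_per_group || n_uc < n_per_group) && tries < 60) {
    tries <- tries + 1
    m <- generate_cohort(truth, max(2 * n_per_group, 8), delta_ibd)
    eta <- if (length(reg) > 0) {
      drop(crossprod((m[reg, , drop = FALSE] - nu[reg]) / sdv[reg], truth$gamma[reg]))
    } else rep(0, ncol(m))
    is_cd <- rbinom(ncol(m), 1, plogis(eta)) == 1
    if (any(is_cd)) cd <- c(cd, list(m[, is_cd, drop = FALSE]))
    if (any(!is_cd)) uc <- c(uc, list(m[, !is_cd, drop = FALSE]))
    n_cd <- n_cd + sum(is_cd); n_uc <- n_uc + sum(!is_cd)
  }
  if (n_cd < n_per_group || n_uc < n_per_group) {
    stop("Could not fill CD/UC groups; outcome model too unbalanced.", call. = FALSE)
  }
  cd <- do.call(cbind, cd)[, seq_len(n_per_group), drop = FALSE]
  uc <- do.call(cbind, uc)[, seq_len(n_per_group), drop = FALSE]

  x <- cbind(cd, uc, ctrl)
  x <- pmax(x, 0) # truncate rare negative intensities
  sample_ids <- c(sprintf("CD%03d", seq_len(n_per_group)),
                  sprintf("UC%03d", seq_len(n_per_group)),
                  sprintf("CT%03d", seq_len(n_per_group)))
  colnames(x) <- sample_ids
  metadata <- tibble(
    sample_id = sample_ids,
    group = rep(c("CD", "UC", "control"), each = n_per_group),
    batch = rep(c("b1", "b2"), length.out = 3 * n_per_group)
  )
  base <- c(b1 = 1, b2 = truth$batch_scale)
  factors <- setNames(
    base[metadata$batch] * exp(rnorm(nrow(metadata), 0, truth$batch_jitter)),
    metadata$sample_id
  )
  structure(list(matrix = x, metadata = metadata, batch_factors = factors,
                 truth = truth),
            class = "synthetic_cohort")
}

#' Apply per-sample multiplicative batch distortion
#'
#' Multiplies every sample column by its positive batch factor — exactly the
#' distortion family that median-ratio housekeeping correction removes.
#'
#' @param matrix Genes-by-samples matrix.
#' @param factors Positive numeric factors, named by sample or in column
#'   order.
#' @return The distorted matrix.
#' @export
apply_batch_distortion <- function(matrix, factors) {
  validate_expression_matrix(matrix)
  if (!is.null(names(factors))) {
    missing <- setdiff(colnames(matrix), names(factors))
    if (length(missing) > 0) {
      stop("No batch factor for sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
    }
    factors <- factors[colnames(matrix)]
  }
  if (length(factors) != ncol(matrix)) {
    stop("Need one batch factor per sample.", call. = FALSE)
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    stop("Batch factors must be positive and finite.", call. = FALSE)
  }
  sweep(matrix, 2, factors, `*`)
}

# serialisable representation of a truth object
truth_to_json <- function(truth, path) {
  obj <- list(
    schema_version = truth$schema_version,
    seed = truth$seed,
    genes = truth$genes,
    edges = truth$edges,
    delta = truth$delta,
    gamma = as.list(truth$gamma),
    regulators = truth$regulators,
    cascade = truth$cascade,
    housekeeping = truth$housekeeping,
    batch_scale = truth$batch_scale,
    batch_jitter = truth$batch_jitter
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a complete synthetic fixture bundle
#'
#' Generates a cohort under one of three presets and writes every file the
#' pipeline consumes: batch-distorted expression TSV, clean expression TSV,
#' metadata CSV, housekeeping-gene list, GMT gene sets, one SIF edge list per
#' pathway, and the ground-truth JSON.
#'
#' @param outdir Output directory (created if needed).
#' @param preset `"smoke"` (tiny), `"benchmark"` (n = 200/group, planted
#'   cascade) or `"null"` (no planted effects anywhere).
#' @param seed Integer seed; the bundle is byte-identical across reruns.
#' @return Named character vector of file paths, invisibly.
#' @export
emit_fixture_bundle <- function(outdir, preset = c("smoke", "benchmark", "null"), seed = 1) {
  preset <- match.arg(preset)
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("Cannot create output directory: ", outdir, call. = FALSE)
  }
  if (file.access(outdir, 2) != 0) stop("Output directory not writable: ", outdir, call. = FALSE)

  truth <- switch(preset,
    smoke = build_truth_network(n_genes = 24, n_pathways = 3, n_housekeeping = 6,
                                seed = derive_seed(seed, "smoke")),
    benchmark = build_truth_network(seed = derive_seed(seed, "benchmark")),
    null = build_truth_network(n_genes = 24, n_pathways = 3, n_housekeeping = 6,
                               cascade_spec = cascade_spec(gamma = c(0, 0, 0)),
                               n_shifted_pathways = 0,
                               seed = derive_seed(seed, "null"))
  )
  n_per_group <- switch(preset, smoke = 6, benchmark = 200, null = 6)
  cohort <- simulate_expression(truth, n_per_group, seed = derive_seed(seed, "cohort"))
  distorted <- apply_batch_distortion(cohort$matrix, cohort$batch_factors)

  paths <- c(
    expression = file.path(outdir, "expression.tsv"),
    expression_clean = file.path(outdir, "expression_clean.tsv"),
    metadata = file.path(outdir, "metadata.csv"),
    housekeeping = file.path(outdir, "housekeeping.txt"),
    gmt = file.path(outdir, "gene_sets.gmt"),
    truth = file.path(outdir, "truth.json")
  )
  write_expression_matrix(distorted, paths["expression"])
  write_expression_matrix(cohort$matrix, paths["expression_clean"])
  utils::write.table(cohort$metadata, paths["metadata"], sep = ",", quote = FALSE,
                     row.names = FALSE)
  writeLines(truth$housekeeping, paths["housekeeping"])
  write_gene_sets_gmt(truth$gene_sets, paths["gmt"])
  truth_to_json(truth, paths["truth"])
  sif_dir <- file.path(outdir, "pathways")
  dir.create(sif_dir, showWarnings = FALSE)
  for (p in names(truth$pathway_graphs)) {
    sif <- file.path(sif_dir, paste0(p, ".sif"))
    write_pathway_graph(truth$pathway_graphs[[p]], sif)
    paths[paste0("sif_", p)] <- sif
  }
  invisible(paths)
}
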