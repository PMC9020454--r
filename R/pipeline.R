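#' Build a pipeline configuration
#'
#' Bundles input paths and the tuning parameters of every stage. Defaults:
#' CRG panel size 100, fold-change gate 1 (log2), significance gates 0.05,
#' enrichment gate adjusted p < 1e-3, and 1000 permutations for both the QPA
#' and the causal permutation tests.
#'
#' @param expression Path to the expression TSV (genes x samples).
#' @param metadata Path to the metadata CSV.
#' @param housekeeping Path to the housekeeping-gene list (one ID per line).
#' @param gmt Path to the gene-set GMT.
#' @param pathway_dir Directory of SIF-style pathway edge lists, one file per
#'   pathway, named `<set_id>.sif`.
#' @param k_crg CRG selection size.
#' @param fc_threshold Absolute log2 fold-change DEG gate.
#' @param alpha_deg,alpha_dep,alpha_causal Stage significance levels.
#' @param alpha_adj_enrich Enrichment adjusted-p gate.
#' @param B_qpa,B_causal Permutation counts (>= 99).
#' @param seed Master seed; per-stage, per-unit streams are derived from it.
#' @param reference_sample Reference sample for batch correction, or `NULL`
#'   for a seeded random draw.
#' @param gate_on_kw Gate post hoc DEG tests on the Kruskal-Wallis omnibus.
#' @param mc_draws Monte-Carlo draws for the Dunnett null.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, metadata, housekeeping, gmt, pathway_dir,
                            k_crg = 100, fc_threshold = 1,
                            alpha_deg = 0.05, alpha_dep = 0.05, alpha_causal = 0.05,
                            alpha_adj_enrich = 1e-3, B_qpa = 1000, B_causal = 1000,
                            seed = 1, reference_sample = NULL, gate_on_kw = TRUE,
                            mc_draws = 10000) {
  alphas <- c(alpha_deg = alpha_deg, alpha_dep = alpha_dep,
              alpha_causal = alpha_causal, alpha_adj_enrich = alpha_adj_enrich)
  if (any(alphas <= 0 | alphas >= 1)) {
    stop("All significance levels must lie in (0, 1).", call. = FALSE)
  }
  if (B_qpa < 99 || B_causal < 99) stop("Permutation counts must be >= 99.", call. = FALSE)
  structure(list(
    expression = expression, metadata = metadata, housekeeping = housekeeping,
    gmt = gmt, pathway_dir = pathway_dir,
    k_crg = k_crg, fc_threshold = fc_threshold,
    alpha_deg = alpha_deg, alpha_dep = alpha_dep, alpha_causal = alpha_causal,
    alpha_adj_enrich = alpha_adj_enrich, B_qpa = B_qpa, B_causal = B_causal,
    seed = seed, reference_sample = reference_sample, gate_on_kw = gate_on_kw,
    mc_draws = mc_draws
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path Path to a JSON file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}

pipeline_stage_error <- function(stage, parent) {
  stop(errorCondition(
    sprintf("[stage:%s] %s", stage, conditionMessage(parent)),
    class = c("causalqpa_pipeline_error", "error"),
    stage = stage
  ))
}

#' Run the full inference chain
#'
#' Executes batch correction, DEG analysis, enrichment, QPA/DEP calling,
#' prior-network merging, the causal screen, subtype-regulator calling and
#' the downstream regulator regressions, in order. Every stage's output is
#' returned and (when `outdir` is given) written as a CSV/TSV with fixed
#' column order, together with the merged network SIF and a JSON run
#' manifest recording the configuration, derived seeds, the reference
#' sample, and the cyclicity of the merged network. Given a seed, the run is
#' deterministic.
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory, or `NULL` to keep results in memory only.
#' @return A `pipeline_result` list: `corrected`, `crg_selection`,
#'   `correction_model`, `degs`, `enrichment` (per subtype), `deps`,
#'   `network`, `causal`, `regulators`, `downstream`, `manifest`.
#' @export
run_full_pipeline <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  status <- list()
  run_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) {
      status[[stage]] <<- "failed"
      if (!is.null(outdir)) {
        manifest <- list(incomplete = TRUE, failed_stage = stage,
                         error = conditionMessage(e), stages = status)
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
      pipeline_stage_error(stage, e)
    })
    status[[stage]] <<- "ok"
    res
  }
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  inputs <- run_stage("read_inputs", {
    sif_files <- sort(list.files(config$pathway_dir, pattern = "\\.sif$",
                                 full.names = TRUE))
    list(
      matrix = read_expression_matrix(config$expression),
      metadata = read_metadata(config$metadata),
      housekeeping = readLines(config$housekeeping),
      gene_sets = read_gene_sets_gmt(config$gmt),
      graphs = setNames(
        lapply(sif_files, function(f) {
          read_pathway_graph(f, sub("\\.sif$", "", basename(f)))
        }),
        sub("\\.sif$", "", basename(sif_files))
      )
    )
  })

  corrected <- run_stage("correct", {
    correct_batch_effects(inputs$matrix, inputs$metadata, inputs$housekeeping,
                          k = config$k_crg,
                          reference_sample = config$reference_sample,
                          seed = derive_seed(config$seed, "reference"))
  })

  degs <- run_stage("deg", {
    run_deg_analysis(corrected$matrix, inputs$metadata,
                     fc_threshold = config$fc_threshold, alpha = config$alpha_deg,
                     gate_on_kw = config$gate_on_kw, mc_draws = config$mc_draws,
                     seed = derive_seed(config$seed, "deg"))
  })

  enrichment <- run_stage("enrich", {
    universe <- rownames(corrected$matrix)
    list(
      CD = hypergeometric_enrich(deg_ids(degs, "CD_vs_control"), universe,
                                 inputs$gene_sets, config$alpha_adj_enrich),
      UC = hypergeometric_enrich(deg_ids(degs, "UC_vs_control"), universe,
                                 inputs$gene_sets, config$alpha_adj_enrich)
    )
  })

  deps <- run_stage("qpa", {
    enriched_ids <- union(
      enrichment$CD$set_id[enrichment$CD$enriched],
      enrichment$UC$set_id[enrichment$UC$enriched]
    )
    candidates <- inputs$gene_sets[inputs$gene_sets$set_id %in% enriched_ids, , drop = FALSE]
    find_deps(corrected$matrix, inputs$metadata, candidates,
              B = config$B_qpa, seed = derive_seed(config$seed, "qpa"),
              alpha = config$alpha_dep)
  })

  network <- run_stage("merge", {
    dep_ids <- deps$pathway_id[deps$is_dep]
    graphs <- inputs$graphs[intersect(names(inputs$graphs), dep_ids)]
    if (length(graphs) == 0) NULL else merge_priori_network(graphs)
  })

  causal <- run_stage("causal", {
    if (is.null(network)) {
      screen_causal_effects(corrected$matrix, inputs$metadata,
                            structure(list(nodes = character(),
                                           edges = tibble(source = character(),
                                                          target = character()),
                                           is_cyclic = FALSE),
                                      class = "priori_network"),
                            character(0), B = config$B_causal, seed = config$seed)
    } else {
      screen_causal_effects(corrected$matrix, inputs$metadata, network,
                            candidate_genes = deg_ids(degs),
                            B = config$B_causal,
                            seed = derive_seed(config$seed, "causal"))
    }
  })

  regulators <- run_stage("regulators", {
    call_subtype_regulators(causal, corrected$matrix, inputs$metadata,
                            alpha = config$alpha_causal)
  })

  downstream <- run_stage("downstream", {
    regs <- regulators$gene_id[regulators$is_regulator]
    if (length(regs) < 2) {
      tibble(gene_x = character(), gene_y = character(), scope = character(),
             rho = numeric(), rho_p = numeric(), slope = numeric(),
             intercept = numeric(), r_squared = numeric(), n = integer())
    } else {
      pairs <- utils::combn(sort(regs), 2)
      pairs <- pairs[, seq_len(min(ncol(pairs), 10)), drop = FALSE]
      dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
        mutate(regress_gene_pair(corrected$matrix, inputs$metadata,
                                 pairs[1, j], pairs[2, j]),
               gene_x = pairs[1, j], gene_y = pairs[2, j], .before = 1)
      }))
    }
  })

  manifest <- list(
    package = "causalqpa",
    version = as.character(utils::packageVersion("causalqpa")),
    incomplete = FALSE,
    config = config[setdiff(names(config), "reference_sample")],
    seed = config$seed,
    derived_seeds = list(
      reference = derive_seed(config$seed, "reference"),
      deg = derive_seed(config$seed, "deg"),
      qpa = derive_seed(config$seed, "qpa"),
      causal = derive_seed(config$seed, "causal")
    ),
    reference_sample = corrected$model$reference_sample,
    network_cyclic = if (is.null(network)) NA else network$is_cyclic,
    n_deps = sum(deps$is_dep),
    n_regulators = sum(regulators$is_regulator),
    stages = status
  )

  result <- structure(list(
    corrected = corrected$matrix,
    crg_selection = corrected$crg_selection,
    correction_model = corrected$model,
    degs = degs,
    enrichment = enrichment,
    deps = deps,
    network = network,
    causal = causal,
    regulators = regulators,
    downstream = downstream,
    manifest = manifest
  ), class = "pipeline_result")

  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

write_csv_fixed <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ";")
    }
  }
  utils::write.table(df, path, sep = ",", quote = TRUE, row.names = FALSE)
  invisible(path)
}

write_pipeline_outputs <- function(result, outdir) {
  write_expression_matrix(result$corrected, file.path(outdir, "corrected.tsv"))
  write_csv_fixed(result$crg_selection, file.path(outdir, "crg_report.csv"))
  write_csv_fixed(result$degs, file.path(outdir, "degs.csv"))
  write_csv_fixed(result$enrichment$CD, file.path(outdir, "enrichment_CD.csv"))
  write_csv_fixed(result$enrichment$UC, file.path(outdir, "enrichment_UC.csv"))
  write_csv_fixed(result$deps, file.path(outdir, "deps.csv"))
  if (!is.null(result$network)) {
    net <- result$network
    utils::write.table(
      data.frame(net$edges$source, net$edges$interaction, net$edges$target),
      file.path(outdir, "network.sif"),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  write_csv_fixed(result$causal, file.path(outdir, "causal_results.csv"))
  write_csv_fixed(result$regulators, file.path(outdir, "regulators.csv"))
  write_csv_fixed(result$downstream, file.path(outdir, "downstream.csv"))
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  samples: %d, genes: %d\n", ncol(x$corrected), nrow(x$corrected)))
  cat(sprintf("  DEGs (vs control, either subtype): %d\n", length(deg_ids(x$degs))))
  cat(sprintf("  DEPs: %d of %d candidates\n", sum(x$deps$is_dep), nrow(x$deps)))
  if (!is.null(x$network)) {
    cat(sprintf("  prior network: %d nodes, %d edges%s\n", length(x$network$nodes),
                nrow(x$network$edges), if (x$network$is_cyclic) " (cyclic)" else ""))
  }
  cat(sprintf("  subtype-regulators: %s\n",
              paste(x$regulators$gene_id[x$regulators$is_regulator], collapse = ", ")))
  invisible(x)
}
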