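#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a correction model
#'
#' One row per sample with its CRG median and correcting coefficient.
#'
#' @param x A `correction_model`.
#' @param ... Unused.
#' @return A tibble `sample_id`, `crg_median`, `coefficient`, `is_reference`.
#' @method tidy correction_model
#' @export
tidy.correction_model <- function(x, ...) {
  tibble(
    sample_id = names(x$coefficients),
    crg_median = unname(x$crg_medians),
    coefficient = unname(x$coefficients),
    is_reference = names(x$coefficients) == x$reference_sample
  )
}

#' @describeIn tidy.correction_model One-row model summary.
#' @method glance correction_model
#' @export
glance.correction_model <- function(x, ...) {
  tibble(
    reference_sample = x$reference_sample,
    n_crgs = length(x$crg_ids),
    n_samples = length(x$coefficients),
    coefficient_min = min(x$coefficients),
    coefficient_max = max(x$coefficients)
  )
}

#' Tidy a prior network
#'
#' @param x A `priori_network`.
#' @param ... Unused.
#' @return The edge tibble with provenance collapsed to a `;`-joined string.
#' @method tidy priori_network
#' @export
tidy.priori_network <- function(x, ...) {
  mutate(x$edges,
         provenance = vapply(x$edges$provenance, paste, character(1), collapse = ";"))
}

#' @describeIn tidy.priori_network One-row network summary.
#' @method glance priori_network
#' @export
glance.priori_network <- function(x, ...) {
  tibble(n_nodes = length(x$nodes), n_edges = nrow(x$edges), cyclic = x$is_cyclic)
}

#' Tidy a QPA profile
#'
#' @param x A `qpa_profile`.
#' @param ... Unused.
#' @return A tibble `sample_id`, `score`.
#' @method tidy qpa_profile
#' @export
tidy.qpa_profile <- function(x, ...) {
  tibble(sample_id = names(x$scores), score = unname(x$scores))
}

#' @describeIn tidy.qpa_profile One-row profile summary.
#' @method glance qpa_profile
#' @export
glance.qpa_profile <- function(x, ...) {
  tibble(pathway_id = x$pathway_id, n_genes = length(x$genes_used),
         n_samples = length(x$scores), var_explained = x$var_explained,
         orientation = x$orientation)
}

#' Tidy a pipeline result
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return The regulator-call tibble (the pipeline's terminal output).
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) as_tibble(x$regulators)

#' @describeIn tidy.pipeline_result One-row run summary.
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x$corrected),
    n_samples = ncol(x$corrected),
    n_degs = length(deg_ids(x$degs)),
    n_dep_candidates = nrow(x$deps),
    n_deps = sum(x$deps$is_dep),
    n_network_nodes = if (is.null(x$network)) 0L else length(x$network$nodes),
    n_network_edges = if (is.null(x$network)) 0L else nrow(x$network$edges),
    network_cyclic = if (is.null(x$network)) NA else x$network$is_cyclic,
    n_causal_tested = nrow(x$causal),
    n_regulators = sum(x$regulators$is_regulator)
  )
}
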