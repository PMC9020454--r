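# Small in-code fixtures shared across test files.

make_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = length(genes) %||% nrow(values))
  if (!is.null(genes)) rownames(m) <- genes
  if (!is.null(samples)) colnames(m) <- samples
  m
}

# random valid expression matrix
random_matrix <- function(n_genes = 8, n_samples = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(round(runif(n_genes * n_samples, 1, 100), 4), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# balanced three-group metadata for a sample vector
make_metadata <- function(sample_ids, groups = NULL) {
  n <- length(sample_ids)
  tibble::tibble(
    sample_id = sample_ids,
    group = groups %||% rep_len(c("CD", "UC", "control"), n),
    batch = rep_len(c("b1", "b2"), n)
  )
}

# matrix with prescribed per-group values for a single gene of interest,
# plus filler genes so expression-matrix invariants hold
group_value_matrix <- function(cd, uc, control, filler_seed = 1) {
  vals <- c(cd, uc, control)
  ids <- c(sprintf("CD%02d", seq_along(cd)), sprintf("UC%02d", seq_along(uc)),
           sprintf("CT%02d", seq_along(control)))
  set.seed(filler_seed)
  m <- rbind(target = vals, filler = runif(length(vals), 1, 10))
  colnames(m) <- ids
  md <- tibble::tibble(
    sample_id = ids,
    group = c(rep("CD", length(cd)), rep("UC", length(uc)),
              rep("control", length(control))),
    batch = "b1"
  )
  list(matrix = m, metadata = md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
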