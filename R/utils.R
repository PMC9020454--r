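#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate arrange filter select left_join group_by summarise ungroup
#' @importFrom stats median kruskal.test p.adjust phyper oneway.test cor.test
#'   rnorm rchisq rbinom runif plogis wilcox.test lm coef quantile var sd setNames
#' @importFrom utils head
NULL

# Canonical group vocabulary used throughout: CD and UC are the two IBD
# subtypes; "control" the non-IBD reference group.
GROUP_LEVELS <- c("CD", "UC", "control")

#' Canonicalise group labels
#'
#' Matches labels against the controlled vocabulary `CD`, `UC`, `control`
#' case-insensitively and returns the canonical spelling.
#'
#' @param x Character vector of group labels.
#' @return Character vector with canonical labels.
#' @keywords internal
canonicalize_group <- function(x) {
  idx <- match(tolower(x), tolower(GROUP_LEVELS))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop(
      "Unknown group label(s): ", paste(bad, collapse = ", "),
      ". Allowed values: ", paste(GROUP_LEVELS, collapse = ", "),
      call. = FALSE
    )
  }
  GROUP_LEVELS[idx]
}

#' Derive a reproducible child seed from a master seed and a label
#'
#' Hashes the label into a 31-bit integer and mixes it with the master seed so
#' that every (stage, unit) pair gets an independent, stable random stream.
#' Adding or removing a unit therefore never shifts the randomness of others.
#'
#' @param seed Integer master seed.
#' @param ... Character or integer labels identifying the stage/unit.
#' @return A single integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "qpa", "hsa04621")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (label in list(...)) {
    for (ch in utf8ToInt(paste0("/", as.character(label)))) {
      h <- (h * 131 + ch) %% m
    }
  }
  as.integer(h)
}

#' log2(x + 1) transform
#'
#' The package's explicit log transform: expression values are carried on
#' linear scale (MAS5-like intensities) and log-transformed only where a
#' statistical procedure calls for it.
#'
#' @param x Numeric vector or matrix of nonnegative values.
#' @return `log2(x + 1)`, same shape as `x`.
#' @export
log2p1 <- function(x) log2(x + 1)

#' Validate an expression matrix
#'
#' Checks the invariants of the package's expression container: a numeric
#' genes-by-samples matrix, no missing entries, all values nonnegative, at
#' least 2 genes and 3 samples, unique row and column names.
#'
#' @param x Numeric matrix, genes in rows, samples in columns.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("Expression data must be a numeric matrix (genes x samples).", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("Expression matrix must have gene row names and sample column names.", call. = FALSE)
  }
  if (anyNA(x)) stop("Expression matrix contains missing values.", call. = FALSE)
  if (any(x < 0)) stop("Expression matrix contains negative values.", call. = FALSE)
  if (nrow(x) < 2) stop("Expression matrix needs at least 2 genes.", call. = FALSE)
  if (ncol(x) < 3) stop("Expression matrix needs at least 3 samples.", call. = FALSE)
  if (anyDuplicated(rownames(x))) stop("Duplicate gene IDs in expression matrix.", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("Duplicate sample IDs in expression matrix.", call. = FALSE)
  invisible(x)
}

# Check that metadata covers every sample of the matrix exactly once and
# return it ordered to match the matrix columns.
align_metadata <- function(matrix, metadata) {
  stopifnot(is.data.frame(metadata), all(c("sample_id", "group") %in% names(metadata)))
  if (anyDuplicated(metadata$sample_id)) {
    stop("Duplicated sample_id in metadata.", call. = FALSE)
  }
  missing <- setdiff(colnames(matrix), metadata$sample_id)
  if (length(missing) > 0) {
    stop("Metadata missing sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  metadata[match(colnames(matrix), metadata$sample_id), , drop = FALSE]
}

# groups_of: named vector sample -> group for the matrix columns
groups_of <- function(matrix, metadata) {
  md <- align_metadata(matrix, metadata)
  setNames(md$group, md$sample_id)
}
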