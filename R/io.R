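#' Read a genes-by-samples expression matrix
#'
#' Parses a tab-separated table whose first column holds gene identifiers and
#' whose header row holds sample identifiers. Values must be nonnegative
#' linear-scale intensities (MAS5-like); any missing, negative or non-numeric
#' cell is an error naming the offending row and column. Duplicate gene rows
#' are collapsed by their mean with a warning; duplicate sample IDs are an
#' error.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix (genes x samples) passing
#'   [validate_expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("Expression table needs a gene column plus >= 1 sample.", call. = FALSE)
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("Duplicate sample ID(s) in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "Invalid expression value '%s' at gene '%s', sample '%s' (must be a nonnegative number).",
      vals[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]
    ), call. = FALSE)
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    warning("Collapsing duplicated gene row(s) by mean: ",
            paste(dups, collapse = ", "), call. = FALSE)
    num <- rowsum(num, group = gene_ids, reorder = FALSE) /
      as.vector(table(factor(gene_ids, levels = unique(gene_ids))))
  }
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix as TSV
#'
#' Writes with 17 significant digits so that a write-then-read round trip
#' reproduces every double-precision value bit-for-bit.
#'
#' @param matrix Numeric genes-by-samples matrix.
#' @param path Output path.
#' @param id_column Name for the gene-ID column (first column).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path, id_column = "gene_id") {
  validate_expression_matrix(matrix)
  chr <- matrix(sprintf("%.17g", matrix), nrow(matrix), dimnames = dimnames(matrix))
  df <- data.frame(chr, check.names = FALSE)
  df <- cbind(setNames(data.frame(rownames(matrix)), id_column), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a CSV or TSV with columns `sample_id`, `group`, `batch`. Group labels
#' are validated case-insensitively against `CD`, `UC`, `control` and stored
#' canonically.
#'
#' @param path Path to a CSV (default) or TSV file; the delimiter is chosen by
#'   file extension.
#' @return A tibble with columns `sample_id`, `group`, `batch`.
#' @export
read_metadata <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "batch")
  if (!all(need %in% names(df))) {
    stop("Metadata must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("Duplicated sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  tibble(
    sample_id = as.character(df$sample_id),
    group = canonicalize_group(df$group),
    batch = as.character(df$batch)
  )
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `set_id<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a line are deduplicated and empty member fields skipped.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_id`, `description` and list-column
#'   `genes`.
#' @export
read_gene_sets_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(set_id = character(), description = character(), genes = list()))
  }
  parsed <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need at least 3 (id, description, members).",
                   i, length(fields)), call. = FALSE)
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop(sprintf("GMT line %d (set '%s') has no non-empty members.", i, fields[1]),
           call. = FALSE)
    }
    list(set_id = fields[1], description = fields[2], genes = members)
  })
  ids <- vapply(parsed, `[[`, character(1), "set_id")
  if (anyDuplicated(ids)) {
    stop("Duplicated set_id in GMT: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  tibble(
    set_id = ids,
    description = vapply(parsed, `[[`, character(1), "description"),
    genes = lapply(parsed, `[[`, "genes")
  )
}

#' Write a gene-set collection as GMT
#'
#' @param gene_sets Tibble as returned by [read_gene_sets_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(gene_sets, path) {
  lines <- vapply(seq_len(nrow(gene_sets)), function(i) {
    paste(c(gene_sets$set_id[i], gene_sets$description[i], gene_sets$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# interaction-token vocabulary for SIF-style edge lists
.interaction_map <- c(
  activation = "activation", activate = "activation", activates = "activation",
  "->" = "activation",
  inhibition = "inhibition", inhibit = "inhibition", inhibits = "inhibition",
  "-|" = "inhibition"
)

normalize_interaction <- function(x) {
  out <- unname(.interaction_map[tolower(x)])
  out[is.na(out)] <- "unspecified"
  out
}

#' Read a directed pathway graph from a SIF-style edge list
#'
#' Each line is `source<TAB>interaction<TAB>target` (whitespace also
#' accepted). Interaction tokens map onto `activation`, `inhibition` or
#' `unspecified`. Self-loops are dropped with a warning; duplicate
#' `(source, target)` edges are collapsed keeping the first interaction type.
#'
#' @param path Path to the edge-list file.
#' @param pathway_id Identifier to attach to the graph.
#' @return A `pathway_graph` object: list with `pathway_id`, `nodes`
#'   (character) and `edges` (tibble `source`, `target`, `interaction`).
#' @export
read_pathway_graph <- function(path, pathway_id) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  fields <- strsplit(trimws(lines[keep]), "[\t ]+")
  n_fields <- lengths(fields)
  if (any(n_fields != 3)) {
    bad <- which(keep)[which(n_fields != 3)[1]]
    stop(sprintf("Malformed edge line %d in '%s': need 'source interaction target'.",
                 bad, path), call. = FALSE)
  }
  src <- vapply(fields, `[[`, character(1), 1)
  rel <- vapply(fields, `[[`, character(1), 2)
  tgt <- vapply(fields, `[[`, character(1), 3)
  new_pathway_graph(pathway_id,
                    edges = tibble(source = src,
                                   target = tgt,
                                   interaction = normalize_interaction(rel)),
                    nodes = unique(c(src, tgt)))
}

#' Construct a pathway graph object
#'
#' @param pathway_id Identifier.
#' @param edges Tibble with columns `source`, `target`, `interaction`.
#' @param nodes Character vector of node IDs; defaults to the edge endpoints.
#' @return A `pathway_graph` object.
#' @export
new_pathway_graph <- function(pathway_id, edges, nodes = NULL) {
  stopifnot(all(c("source", "target", "interaction") %in% names(edges)))
  nodes <- unique(c(nodes, edges$source, edges$target))
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning(sprintf("Dropping %d self-loop(s) in pathway '%s'.", sum(loops), pathway_id),
            call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  dup <- duplicated(paste(edges$source, edges$target, sep = "\r"))
  edges <- edges[!dup, , drop = FALSE]
  structure(
    list(pathway_id = pathway_id, nodes = nodes, edges = as_tibble(edges)),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s: %d nodes, %d edges\n",
              x$pathway_id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Write a pathway graph as a SIF-style edge list
#'
#' @param graph A `pathway_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pathway_graph <- function(graph, path) {
  utils::write.table(
    data.frame(graph$edges$source, graph$edges$interaction, graph$edges$target),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
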