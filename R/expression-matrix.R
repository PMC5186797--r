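#' Log2 expression matrices
#'
#' Expression data are carried as plain numeric matrices with genes (or
#' probesets) in rows and samples in columns, on the log2 scale throughout.
#' `log_expr()` validates such a matrix and tags it with the measurement
#' platform; all downstream functions accept the tagged or the bare matrix.
#'
#' @param values numeric matrix, genes x samples, log2 scale, finite.
#' @param platform `"array"` or `"rnaseq"`.
#' @return the matrix with class `log_expr` and a `platform` attribute.
#' @examples
#' m <- matrix(rnorm(6, 8), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' log_expr(m, "array")
#' @export
log_expr <- function(values, platform = c("array", "rnaseq")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrices need gene rownames and sample colnames.")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    abort("duplicate gene or sample identifiers are not allowed.")
  }
  if (nrow(values) == 0L) abort("at least one gene is required.")
  if (!all(is.finite(values))) abort("all expression values must be finite.")
  structure(values, class = c("log_expr", class(matrix())),
            platform = platform)
}

#' @export
print.log_expr <- function(x, ...) {
  cat(sprintf("<log_expr> %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "platform") %||% "untagged"))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 5L)), drop = FALSE],
                    5L))
  invisible(x)
}

#' Convert an expression matrix to a long tibble
#'
#' @param x a `log_expr` (or bare genes x samples matrix).
#' @param ... unused.
#' @return a tibble with columns `gene`, `sample`, `expression`.
#' @export
tidy.log_expr <- function(x, ...) {
  tibble(
    gene = rep(rownames(x), times = ncol(x)),
    sample = rep(colnames(x), each = nrow(x)),
    expression = as.vector(unclass(x))
  )
}

as_expr_matrix <- function(x, arg = "x") {
  if (inherits(x, "log_expr")) return(unclass(x))
  if (is.matrix(x) && is.numeric(x)) return(x)
  abort(sprintf("`%s` must be a numeric genes x samples matrix.", arg))
}

#' Summarize probeset-level expression to gene level
#'
#' Collapses a probeset x sample log2 matrix to a gene x sample matrix by
#' taking, per sample, the arithmetic mean of the log values of all
#' probesets mapped to each gene. Probesets without a mapping are dropped.
#'
#' @param probe_matrix probesets x samples log2 matrix (rownames are
#'   probeset ids).
#' @param probe_gene_map a data frame with columns `probeset` and `gene`,
#'   or a named character vector `probeset -> gene`.
#' @return a `log_expr` matrix keyed by gene, same platform tag as the
#'   input (default `"array"` for untagged input).
#' @export
summarize_to_gene_level <- function(probe_matrix, probe_gene_map) {
  platform <- attr(probe_matrix, "platform") %||% "array"
  m <- as_expr_matrix(probe_matrix, "probe_matrix")
  if (is.data.frame(probe_gene_map)) {
    map <- setNames(as.character(probe_gene_map$gene),
                    as.character(probe_gene_map$probeset))
  } else {
    map <- probe_gene_map
  }
  keep <- rownames(m) %in% names(map)
  if (!any(keep)) {
    abort("no probeset in the matrix is covered by the probe-gene map.")
  }
  m <- m[keep, , drop = FALSE]
  genes <- unname(map[rownames(m)])
  sums <- rowsum(m, group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  out <- out[order(rownames(out)), , drop = FALSE]
  log_expr(out, platform)
}

#' Average replicate columns of an expression matrix
#'
#' Replicate samples of the same biological unit (e.g. repeated arrays of
#' one cell line) are collapsed to the mean log expression per unit.
#'
#' @param mat genes x samples log2 matrix.
#' @param replicate_map data frame with columns `sample` and `unit`, or a
#'   named character vector `sample -> unit`.
#' @return `log_expr` with one column per unit.
#' @export
average_replicates <- function(mat, replicate_map) {
  platform <- attr(mat, "platform") %||% "array"
  m <- as_expr_matrix(mat, "mat")
  if (is.data.frame(replicate_map)) {
    map <- setNames(as.character(replicate_map$unit),
                    as.character(replicate_map$sample))
  } else {
    map <- replicate_map
  }
  keep <- colnames(m) %in% names(map)
  if (!any(keep)) abort("no sample of the matrix appears in the map.")
  m <- m[, keep, drop = FALSE]
  units <- unname(map[colnames(m)])
  out <- t(rowsum(t(m), group = units) / as.vector(table(units)))
  out <- out[, order(colnames(out)), drop = FALSE]
  log_expr(out, platform)
}

#' Read / write tab-separated expression matrices
#'
#' The on-disk format is a TSV with the gene identifier in the first
#' column (header `gene`) and one column per sample; values are log2
#' expression. Round-trips preserve gene and sample order.
#'
#' @param path file path.
#' @param platform platform tag attached on read.
#' @return `read_expression_matrix()` returns a `log_expr`;
#'   `write_expression_matrix()` returns `path` invisibly.
#' @export
read_expression_matrix <- function(path, platform = c("array", "rnaseq")) {
  platform <- match.arg(platform)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) abort(sprintf("empty expression file: %s", path))
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    abort(sprintf("%s: expected a gene column plus >=1 sample column.", path))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("%s: non-numeric expression values.", path))
  rownames(m) <- as.character(df[[1]])
  log_expr(m, platform)
}

#' @rdname read_expression_matrix
#' @param mat genes x samples matrix to write.
#' @export
write_expression_matrix <- function(mat, path) {
  m <- as_expr_matrix(mat, "mat")
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
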