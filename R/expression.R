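#' Read a cluster-level marker table (FindAllMarkers convention)
#'
#' Loads a long-format table of per-cluster marker statistics as emitted
#' by Seurat's `FindAllMarkers` (columns `p_val`, `avg_log2FC`, `pct.1`,
#' `pct.2`, `p_val_adj`, `cluster`, `gene`), applies the adjusted-p-value
#' screen, and normalizes gene symbols. Rows whose adjusted p-value is at
#' or above the threshold are dropped; if the table has no adjusted
#' p-value column the filter is skipped with a warning. Negative values
#' in the chosen statistic column are clipped to zero (the count of
#' clipped rows is kept in the `n_clipped` attribute).
#'
#' @param path CSV or TSV file (delimiter inferred from the extension,
#'   overridable via `delim`).
#' @param value_column column holding the per-gene-per-cluster magnitude
#'   fed into the expression matrix; default `avg_log2FC` (the alias
#'   `avg_logFC` is accepted), `pct.1` or a user column may be chosen.
#' @param p_adj_threshold adjusted-p-value screen; rows with
#'   `p_val_adj >= p_adj_threshold` are removed. Default 0.05.
#' @param case_fold upper-case gene symbols? Default `TRUE`.
#' @param on_duplicate what to do with duplicated (gene, cluster) pairs
#'   after filtering: `"error"` (default) or `"max"` (keep the largest
#'   value).
#' @param delim optional delimiter override.
#' @return a data.frame of class `marker_table` with columns `gene`,
#'   `cluster`, `value` plus any auxiliary input columns; attributes
#'   `value_column` and `n_clipped`.
#' @export
read_marker_table <- function(path, value_column = "avg_log2FC",
                              p_adj_threshold = 0.05, case_fold = TRUE,
                              on_duplicate = c("error", "max"),
                              delim = NULL) {
  on_duplicate <- match.arg(on_duplicate)
  df <- read_table_auto(path, delim = delim)
  ctx <- basename(path)
  idx <- match_header(names(df),
    list(gene = "gene", cluster = "cluster"),
    context = ctx
  )

  vcol <- value_column
  if (!vcol %in% names(df)) {
    if (identical(value_column, "avg_log2FC") && "avg_logFC" %in% names(df)) {
      vcol <- "avg_logFC"
    } else {
      stop(sprintf(
        "%s: value column '%s' not found; available columns: %s",
        ctx, value_column, paste(names(df), collapse = ", ")
      ), call. = FALSE)
    }
  }

  out <- df
  out$gene <- normalize_symbols(df[[idx["gene"]]], case_fold = case_fold)
  out$cluster <- trimws(as.character(df[[idx["cluster"]]]))
  out$value <- suppressWarnings(as.numeric(df[[vcol]]))
  if (anyNA(out$value) && nrow(out) > 0) {
    stop(sprintf("%s: non-numeric entries in value column '%s'", ctx, vcol),
      call. = FALSE
    )
  }

  padj_col <- intersect(c("p_val_adj", "p_adjusted", "p_adj"), names(df))[1]
  if (!is.na(padj_col)) {
    padj <- suppressWarnings(as.numeric(df[[padj_col]]))
    keep <- is.na(padj) | padj < p_adj_threshold
    out <- out[keep, , drop = FALSE]
  } else if (nrow(out) > 0) {
    warning(sprintf(
      "%s: no adjusted p-value column; significance filter skipped", ctx
    ), call. = FALSE)
  }

  n_clipped <- sum(out$value < 0)
  if (n_clipped > 0) {
    warning(sprintf("%d negative values clipped to 0", n_clipped),
      call. = FALSE
    )
    out$value[out$value < 0] <- 0
  }

  key <- paste(out$gene, out$cluster, sep = "\r")
  if (anyDuplicated(key)) {
    if (on_duplicate == "error") {
      dup <- out[duplicated(key), , drop = FALSE][1, ]
      stop(sprintf(
        "%s: duplicated (gene, cluster) pair: (%s, %s)",
        ctx, dup$gene, dup$cluster
      ), call. = FALSE)
    }
    out <- out[order(key, -out$value), , drop = FALSE]
    out <- out[!duplicated(paste(out$gene, out$cluster, sep = "\r")), ,
      drop = FALSE
    ]
    out <- out[order(as.integer(rownames(out))), , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(out,
    class = c("marker_table", "data.frame"),
    value_column = vcol, n_clipped = n_clipped
  )
}

#' Build the gene-by-cluster expression matrix
#'
#' Arranges the marker-table values into a dense matrix A with marker
#' genes as rows and cell clusters as columns. Pairs absent from the
#' table get 0 (upstream differential expression only reports detected
#' markers, so absence is treated as no evidence). Row and column orders
#' follow first appearance in the table.
#'
#' @param table a `marker_table` (or data.frame with `gene`, `cluster`,
#'   `value`).
#' @return an object of class `expression_matrix`: list with `genes`,
#'   `clusters`, `A` (values) and `E` (proportions; `NULL` until
#'   [normalize_expression()] is called).
#' @export
build_expression_matrix <- function(table) {
  table <- as.data.frame(table)
  if (nrow(table) == 0) stop("marker table is empty", call. = FALSE)
  stopifnot(all(c("gene", "cluster", "value") %in% names(table)))
  genes <- unique(table$gene)
  clusters <- unique(table$cluster)
  a <- matrix(0,
    nrow = length(genes), ncol = length(clusters),
    dimnames = list(genes, clusters)
  )
  a[cbind(match(table$gene, genes), match(table$cluster, clusters))] <-
    table$value
  structure(
    list(genes = genes, clusters = clusters, A = a, E = NULL),
    class = "expression_matrix"
  )
}

#' Convert expression values to proportions
#'
#' With the default `axis = "gene"`, each entry is divided by its gene's
#' total across clusters, so every nonzero gene row of E sums to 1 and
#' entries are comparable between genes within a cluster. Rows that are
#' all zero stay all zero (no NaN). `axis = "cluster"` instead divides by
#' the cluster (column) totals, provided for sensitivity checks.
#'
#' @param matrix an `expression_matrix`.
#' @param axis `"gene"` (row-wise, default) or `"cluster"` (column-wise).
#' @return the `expression_matrix` with `E` populated; `A` is unchanged.
#' @export
normalize_expression <- function(matrix, axis = c("gene", "cluster")) {
  stopifnot(inherits(matrix, "expression_matrix"))
  axis <- match.arg(axis)
  a <- matrix$A
  if (axis == "gene") {
    tot <- rowSums(a)
    tot[tot == 0] <- 1
    e <- a / tot
  } else {
    tot <- colSums(a)
    tot[tot == 0] <- 1
    e <- sweep(a, 2, tot, "/")
  }
  matrix$E <- e
  matrix
}

#' Write an expression or proportion matrix as TSV
#'
#' Genes as rows, clusters as columns, with a leading `gene` column.
#'
#' @param matrix an `expression_matrix`.
#' @param path output path.
#' @param what `"A"` (values) or `"E"` (proportions).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path, what = c("A", "E")) {
  stopifnot(inherits(matrix, "expression_matrix"))
  what <- match.arg(what)
  m <- matrix[[what]]
  if (is.null(m)) stop("proportions not computed yet", call. = FALSE)
  df <- data.frame(gene = rownames(m), m,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  write_tsv_plain(df, path)
  invisible(path)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d genes x %d clusters (%s)\n",
    length(x$genes), length(x$clusters),
    if (is.null(x$E)) "values only" else "values + proportions"
  ))
  invisible(x)
}
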