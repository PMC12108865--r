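#' Score clusters against dictionary cell types
#'
#' The similarity of cluster j to cell type m is the sum, over genes
#' present both among the cluster's markers and in the type's dictionary
#' entry, of the gene's expression proportion in the cluster times its
#' dictionary weight for the type. Genes found in only one of the two
#' inputs contribute nothing, so disjoint gene sets give a score of 0.
#'
#' @param matrix an `expression_matrix` with proportions computed
#'   ([normalize_expression()]).
#' @param dictionary a `marker_dictionary` with weights computed.
#' @return a dense numeric matrix, clusters as rows and every dictionary
#'   cell type as a column.
#' @export
compute_similarity <- function(matrix, dictionary) {
  stopifnot(
    inherits(matrix, "expression_matrix"),
    inherits(dictionary, "marker_dictionary")
  )
  if (is.null(matrix$E)) {
    stop("expression proportions missing; run normalize_expression() first",
      call. = FALSE
    )
  }
  w <- dictionary$weights
  s <- base::matrix(0,
    nrow = length(matrix$clusters), ncol = ncol(w),
    dimnames = list(matrix$clusters, colnames(w))
  )
  shared <- intersect(rownames(matrix$E), rownames(w))
  if (length(shared) == 0) {
    warning("no gene symbols shared between marker table and dictionary; all similarity scores are zero",
      call. = FALSE
    )
    return(s)
  }
  s[] <- t(matrix$E[shared, , drop = FALSE]) %*% w[shared, , drop = FALSE]
  s
}

#' Threshold statistics for one cluster's similarity scores
#'
#' From a cluster's row of the similarity matrix this derives the top
#' score, the second-highest score (multiset semantics: after removing
#' one occurrence of the maximum, the largest remaining value, so a tied
#' maximum yields `s_secmax == s_max`), and the median over the full row
#' (maximum included). The primary criterion is
#' `lambda1 = s_max - s_median`. A secondary criterion
#' `lambda2 = s_secmax - s_median` is reported only when the trigger
#' fires: by default when `s_max - s_secmax > epsilon` (the `"median"`
#' trigger variant fires when `s_max - s_median > epsilon` instead).
#'
#' @param scores numeric vector (one row of the similarity matrix),
#'   optionally named by cell type.
#' @param epsilon positive trigger tolerance; default 0.00001.
#' @param lambda2_trigger `"secmax"` (default) or `"median"`.
#' @return a list with `s_max`, `s_secmax` (`NA` for a length-1 row),
#'   `s_median`, `lambda1`, `lambda2` (`NA` when not triggered) and
#'   `has_lambda2`.
#' @export
derive_thresholds <- function(scores, epsilon = 1e-5,
                              lambda2_trigger = c("secmax", "median")) {
  lambda2_trigger <- match.arg(lambda2_trigger)
  scores <- as.numeric(scores)
  if (length(scores) == 0) stop("empty score row", call. = FALSE)
  stopifnot(is.numeric(epsilon), epsilon > 0)
  s_max <- max(scores)
  s_median <- stats::median(scores)
  if (length(scores) == 1) {
    return(list(
      s_max = s_max, s_secmax = NA_real_, s_median = s_median,
      lambda1 = 0, lambda2 = NA_real_, has_lambda2 = FALSE
    ))
  }
  rest <- scores[-which.max(scores)]
  s_secmax <- max(rest)
  lambda1 <- s_max - s_median
  gap <- switch(lambda2_trigger,
    secmax = s_max - s_secmax,
    median = s_max - s_median
  )
  has_l2 <- gap > epsilon
  list(
    s_max = s_max, s_secmax = s_secmax, s_median = s_median,
    lambda1 = lambda1,
    lambda2 = if (has_l2) s_secmax - s_median else NA_real_,
    has_lambda2 = has_l2
  )
}

#' Assign one or two cell-type labels per cluster
#'
#' Each cluster's primary label is the cell type with the highest
#' similarity score (ties broken lexicographically). A zero or negative
#' `lambda1` is considered meaningless, and the cluster is labelled
#' `"Unannotated"`. When the secondary criterion is triggered and
#' `lambda2 > 0`, the cell type attaining the second-highest score is
#' attached as a secondary label.
#'
#' @param similarity cluster x cell-type numeric matrix from
#'   [compute_similarity()].
#' @param epsilon secondary-trigger tolerance; default 0.00001.
#' @param lambda2_trigger `"secmax"` (default) or `"median"`; see
#'   [derive_thresholds()].
#' @return a data.frame with one row per cluster: `cluster`,
#'   `primary_type`, `secondary_type` (`NA` when absent), `lambda1`,
#'   `lambda2`, `s_max`, `s_secmax`, `s_median`. The number of
#'   lexicographic tie-breaks applied is kept in the `n_ties` attribute.
#' @export
assign_labels <- function(similarity, epsilon = 1e-5,
                          lambda2_trigger = c("secmax", "median")) {
  lambda2_trigger <- match.arg(lambda2_trigger)
  if (is.null(dim(similarity)) || nrow(similarity) == 0 ||
    ncol(similarity) == 0) {
    stop("similarity matrix is empty", call. = FALSE)
  }
  clusters <- rownames(similarity) %||% as.character(seq_len(nrow(similarity)))
  types <- colnames(similarity)
  n_ties <- 0L
  rows <- lapply(seq_len(nrow(similarity)), function(i) {
    row <- similarity[i, ]
    th <- derive_thresholds(row, epsilon, lambda2_trigger)
    top_idx <- which(row == th$s_max)
    if (length(top_idx) > 1) {
      n_ties <<- n_ties + 1L
      top_idx <- top_idx[order(types[top_idx])][1]
    }
    primary <- if (th$lambda1 <= 0) "Unannotated" else types[top_idx]
    secondary <- NA_character_
    if (th$has_lambda2 && !is.na(th$lambda2) && th$lambda2 > 0 &&
      primary != "Unannotated") {
      rest <- row[-top_idx]
      rest_types <- types[-top_idx]
      sec_idx <- which(rest == th$s_secmax)
      sec_type <- rest_types[sec_idx][order(rest_types[sec_idx])][1]
      if (!identical(sec_type, primary)) secondary <- sec_type
    }
    data.frame(
      cluster = clusters[i], primary_type = primary,
      secondary_type = secondary, lambda1 = th$lambda1,
      lambda2 = if (th$has_lambda2) th$lambda2 else NA_real_,
      s_max = th$s_max, s_secmax = th$s_secmax, s_median = th$s_median,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, n_ties = n_ties)
}

#' Annotate clusters from a marker table and a dictionary file
#'
#' End-to-end pipeline: read the marker table, apply the adjusted-p
#' screen, build the gene-by-cluster matrix, convert to proportions,
#' score against the dictionary and assign labels. Deterministic for
#' fixed inputs and config.
#'
#' @param marker_table_path path to the FindAllMarkers-style CSV/TSV.
#' @param dictionary_path path to the five-column dictionary TSV.
#' @param config optional list overriding defaults: `epsilon` (0.00001),
#'   `value_column` ("avg_log2FC"), `p_adj_threshold` (0.05),
#'   `normalize_axis` ("gene" or "cluster"), `lambda2_trigger` ("secmax"
#'   or "median"), `case_fold` (TRUE). Unknown keys are rejected.
#' @return a list with `annotation` (data.frame from [assign_labels()]),
#'   `similarity` (cluster x cell-type matrix), `expression`
#'   (`expression_matrix`) and `dictionary`.
#' @export
annotate <- function(marker_table_path, dictionary_path, config = list()) {
  config <- resolve_config(config)
  dict <- with_stage("dictionary", read_dictionary(
    dictionary_path,
    case_fold = config$case_fold
  ))
  tab <- with_stage("marker_table", read_marker_table(
    marker_table_path,
    value_column = config$value_column,
    p_adj_threshold = config$p_adj_threshold,
    case_fold = config$case_fold
  ))
  em <- with_stage("expression", {
    normalize_expression(build_expression_matrix(tab),
      axis = config$normalize_axis
    )
  })
  sim <- with_stage("similarity", compute_similarity(em, dict))
  ann <- with_stage("assignment", assign_labels(
    sim,
    epsilon = config$epsilon,
    lambda2_trigger = config$lambda2_trigger
  ))
  list(annotation = ann, similarity = sim, expression = em, dictionary = dict)
}

# defaults for the annotate() pipeline; unknown keys are rejected so a
# typo in a config file cannot silently fall back to a default
.default_config <- list(
  epsilon = 1e-5,
  value_column = "avg_log2FC",
  p_adj_threshold = 0.05,
  normalize_axis = "gene",
  lambda2_trigger = "secmax",
  case_fold = TRUE
)

resolve_config <- function(config) {
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(.default_config))
  if (length(unknown)) {
    stop(sprintf(
      "unknown config keys: %s (known: %s)",
      paste(unknown, collapse = ", "),
      paste(names(.default_config), collapse = ", ")
    ), call. = FALSE)
  }
  out <- utils::modifyList(.default_config, config)
  out$epsilon <- as.numeric(out$epsilon)
  out$p_adj_threshold <- as.numeric(out$p_adj_threshold)
  out$case_fold <- isTRUE(out$case_fold) || identical(out$case_fold, "TRUE") ||
    identical(out$case_fold, "true")
  out$normalize_axis <- match.arg(out$normalize_axis, c("gene", "cluster"))
  out$lambda2_trigger <- match.arg(out$lambda2_trigger, c("secmax", "median"))
  out
}

# re-raise stage errors with the failing stage named
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Write an annotation table as TSV
#'
#' One row per cluster with columns `cluster`, `primary_type`,
#' `secondary_type` (empty when absent), `lambda1`, `lambda2`, `s_max`,
#' `s_secmax`, `s_median`.
#'
#' @param annotation data.frame from [assign_labels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv_plain(as.data.frame(annotation), path)
  invisible(path)
}

#' Write a similarity matrix as TSV (cell types as rows)
#'
#' @param similarity cluster x cell-type matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(similarity, path) {
  m <- t(similarity)
  df <- data.frame(cell_type = rownames(m), m,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  write_tsv_plain(df, path)
  invisible(path)
}
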