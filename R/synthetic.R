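#' Specification for a synthetic benchmark
#'
#' Describes a planted-truth benchmark: a voting dictionary over
#' `n_cell_types` cell types, a cluster-level marker table in which each
#' cluster expresses the marker genes of its assigned type, and a panel
#' of imperfect annotators. All randomness is governed by the explicit
#' `seed`; there is no hidden global state.
#'
#' @param n_cell_types number of cell types (>= 2).
#' @param n_clusters number of clusters (>= 1).
#' @param genes_per_type marker genes per cell type (default 10, the
#'   dictionary's per-type retention depth).
#' @param n_sources number of literature sources voting (default 6).
#' @param marker_overlap fraction in \[0, 1) of each type's genes shared
#'   with the adjacent type (default 0: disjoint marker sets).
#' @param noise_sd standard deviation, on the log scale, of the
#'   multiplicative log-normal noise applied to expression values
#'   (default 0.3, a moderate fold-change jitter).
#' @param dropout probability in \[0, 1) that a true marker row is
#'   omitted from the marker table (default 0.1).
#' @param seed integer seed.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cell_types, n_clusters, genes_per_type = 10,
                           n_sources = 6, marker_overlap = 0,
                           noise_sd = 0.3, dropout = 0.1, seed = 1L) {
  stopifnot(
    n_cell_types >= 2, n_clusters >= 1, genes_per_type >= 1,
    n_sources >= 1,
    marker_overlap >= 0, marker_overlap < 1,
    noise_sd >= 0, dropout >= 0, dropout < 1
  )
  structure(
    list(
      n_cell_types = as.integer(n_cell_types),
      n_clusters = as.integer(n_clusters),
      genes_per_type = as.integer(genes_per_type),
      n_sources = as.integer(n_sources),
      marker_overlap = marker_overlap,
      noise_sd = noise_sd,
      dropout = dropout,
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Preset synthetic benchmark specifications
#'
#' `"paper_scale"` mimics the published dictionary's scale — 75 cell
#' types of 10 genes each from 6 sources, scored over 29 clusters, with
#' mild marker sharing between related types — to exercise realistic
#' sparsity. `"small"` is a fast noise-free benchmark for smoke tests.
#'
#' @param name `"paper_scale"` or `"small"`.
#' @param seed integer seed.
#' @return a [synthetic_spec()].
#' @export
synthetic_preset <- function(name = c("paper_scale", "small"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    paper_scale = synthetic_spec(
      n_cell_types = 75, n_clusters = 29, genes_per_type = 10,
      n_sources = 6, marker_overlap = 0.1, noise_sd = 0.3, dropout = 0.1,
      seed = seed
    ),
    small = synthetic_spec(
      n_cell_types = 6, n_clusters = 8, genes_per_type = 10,
      n_sources = 6, marker_overlap = 0, noise_sd = 0, dropout = 0,
      seed = seed
    )
  )
}

# Vote counts are skewed toward single votes, like real curation where
# only a handful of canonical markers are cited by most sources.
sample_votes <- function(n, n_sources) {
  p <- 0.55^(seq_len(n_sources))
  sample.int(n_sources, n, replace = TRUE, prob = p / sum(p))
}

#' Generate a synthetic voting dictionary with planted truth
#'
#' Each cell type receives `genes_per_type` marker genes; adjacent types
#' share `ceiling(marker_overlap * genes_per_type)` genes. Vote counts
#' are drawn from 1..`n_sources` with a profile skewed toward few votes.
#' An optional explicit `vote_profile` (recycled per type) makes vote
#' totals deterministic.
#'
#' @param spec a `synthetic_spec`.
#' @param vote_profile optional integer vector of length
#'   `genes_per_type` used verbatim for every type.
#' @return list with `dictionary` (a [marker_dictionary()]) and `truth`
#'   (named list: cell type -> character vector of its marker genes).
#' @export
make_dictionary <- function(spec, vote_profile = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gpt <- spec$genes_per_type
  k <- ceiling(spec$marker_overlap * gpt)
  if (k >= gpt) {
    stop("marker_overlap so high that adjacent types would share all genes",
      call. = FALSE
    )
  }
  if (!is.null(vote_profile)) {
    stopifnot(length(vote_profile) == gpt, all(vote_profile >= 1))
  }
  set.seed(spec$seed)
  types <- sprintf("Type_%02d", seq_len(spec$n_cell_types))
  truth <- vector("list", spec$n_cell_types)
  names(truth) <- types
  next_gene <- 1L
  new_genes <- function(n) {
    g <- sprintf("GENE%05d", seq(next_gene, length.out = n))
    next_gene <<- next_gene + n
    g
  }
  for (i in seq_along(types)) {
    if (i == 1L || k == 0L) {
      truth[[i]] <- new_genes(gpt)
    } else {
      shared <- utils::tail(truth[[i - 1L]], k)
      truth[[i]] <- c(shared, new_genes(gpt - k))
    }
  }
  rec <- do.call(rbind, lapply(types, function(t) {
    votes <- if (is.null(vote_profile)) {
      sample_votes(gpt, spec$n_sources)
    } else {
      as.integer(vote_profile)
    }
    data.frame(
      cell_type = t, gene = truth[[t]], votes = votes,
      stringsAsFactors = FALSE
    )
  }))
  list(dictionary = marker_dictionary(rec), truth = truth)
}

#' Generate a cluster-level marker table with planted labels
#'
#' Each cluster's rows are the marker genes of its assigned cell type,
#' with values proportional to the dictionary weights, perturbed by
#' multiplicative log-normal noise (`noise_sd` on the log scale) and
#' thinned by `dropout` (the top-weight gene of each cluster is always
#' kept so every cluster remains observable). Output follows the
#' FindAllMarkers column convention, with adjusted p-values drawn below
#' the default 0.05 screen.
#'
#' @param spec a `synthetic_spec`.
#' @param dictionary the [marker_dictionary()] from [make_dictionary()].
#' @param assignment named character vector mapping every cluster to its
#'   planted cell type.
#' @return a data.frame in FindAllMarkers convention (`p_val`,
#'   `avg_log2FC`, `pct.1`, `pct.2`, `p_val_adj`, `cluster`, `gene`).
#' @export
make_marker_table <- function(spec, dictionary, assignment) {
  stopifnot(
    inherits(spec, "synthetic_spec"),
    inherits(dictionary, "marker_dictionary")
  )
  if (is.null(names(assignment)) || anyNA(assignment)) {
    stop("assignment must be a named cluster -> cell type vector",
      call. = FALSE
    )
  }
  missing_types <- setdiff(assignment, dictionary$cell_types)
  if (length(missing_types)) {
    stop(sprintf(
      "assignment references unknown cell types: %s",
      paste(missing_types, collapse = ", ")
    ), call. = FALSE)
  }
  set.seed(spec$seed + 1L)
  rec <- dictionary$records
  rows <- lapply(names(assignment), function(cl) {
    type <- assignment[[cl]]
    d <- rec[rec$cell_type == type, , drop = FALSE]
    d <- d[order(-d$percent, d$gene), , drop = FALSE]
    n <- nrow(d)
    # log2FC-scale magnitude proportional to the dictionary weight
    value <- 4 * d$percent * n * exp(stats::rnorm(n, 0, spec$noise_sd))
    keep <- stats::runif(n) >= spec$dropout
    keep[1] <- TRUE
    padj <- stats::runif(n, 0, 0.04)
    data.frame(
      p_val = padj / 10,
      avg_log2FC = value,
      pct.1 = round(stats::runif(n, 0.5, 0.95), 3),
      pct.2 = round(stats::runif(n, 0.01, 0.2), 3),
      p_val_adj = padj,
      cluster = cl,
      gene = d$gene,
      stringsAsFactors = FALSE
    )[keep, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a panel of imperfect annotators
#'
#' Each annotator reproduces the planted label of every cluster with
#' probability `1 - error_rate` and otherwise reports a uniformly chosen
#' wrong cell type, so its expected accuracy against the truth is
#' `1 - error_rate`.
#'
#' @param spec a `synthetic_spec`.
#' @param assignment named cluster -> cell type truth vector.
#' @param error_rates numeric vector of per-annotator error rates in
#'   \[0, 1\]; names (default A1, A2, ...) become annotator names.
#' @return list of [label_table()]s, one per annotator.
#' @export
make_annotator_panel <- function(spec, assignment, error_rates) {
  stopifnot(
    inherits(spec, "synthetic_spec"),
    all(error_rates >= 0), all(error_rates <= 1)
  )
  types <- sprintf("Type_%02d", seq_len(spec$n_cell_types))
  if (is.null(names(error_rates))) {
    names(error_rates) <- paste0("A", seq_along(error_rates))
  }
  set.seed(spec$seed + 2L)
  lapply(names(error_rates), function(a) {
    e <- error_rates[[a]]
    lab <- vapply(names(assignment), function(cl) {
      truth <- assignment[[cl]]
      if (stats::runif(1) < e) {
        sample(setdiff(types, truth), 1)
      } else {
        truth
      }
    }, character(1))
    label_table(names(assignment), lab, name = a)
  })
}

#' Generate a full benchmark and write it to disk
#'
#' Writes `dictionary.tsv`, `markers.csv`, `truth.tsv` and one
#' `annotator_<name>.tsv` per annotator into `out_dir`. Cluster-to-type
#' assignment cycles through the cell types.
#'
#' @param spec a `synthetic_spec`.
#' @param out_dir output directory (created if needed).
#' @param error_rates per-annotator error rates; default six annotators
#'   at error 0.1.
#' @return invisibly, a list with the file paths and the `assignment`.
#' @export
simulate_benchmark <- function(spec, out_dir,
                               error_rates = stats::setNames(
                                 rep(0.1, 6), paste0("A", 1:6)
                               )) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- make_dictionary(spec)
  clusters <- as.character(seq_len(spec$n_clusters) - 1L)
  assignment <- stats::setNames(
    rep(names(md$truth), length.out = spec$n_clusters), clusters
  )
  markers <- make_marker_table(spec, md$dictionary, assignment)
  panel <- make_annotator_panel(spec, assignment, error_rates)

  dict_path <- file.path(out_dir, "dictionary.tsv")
  markers_path <- file.path(out_dir, "markers.csv")
  truth_path <- file.path(out_dir, "truth.tsv")
  write_dictionary(md$dictionary, dict_path)
  utils::write.csv(markers, markers_path, row.names = FALSE, quote = FALSE)
  write_tsv_plain(
    data.frame(
      cluster = names(assignment), cell_type = unname(assignment),
      stringsAsFactors = FALSE
    ),
    truth_path
  )
  annot_paths <- vapply(panel, function(t) {
    p <- file.path(
      out_dir, paste0("annotator_", attr(t, "annotator"), ".tsv")
    )
    write_label_table(t, p)
    p
  }, character(1))
  invisible(list(
    dictionary = dict_path, markers = markers_path, truth = truth_path,
    annotators = annot_paths, assignment = assignment
  ))
}
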