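# Shared fixtures and independent oracles.

# the ten published basal-resting dictionary rows (example dictionary)
basal_resting_records <- function() {
  data.frame(
    cell_type = "Basal resting",
    gene = c(
      "TP63", "KRT5", "KRT15", "FXYD3", "KRT14", "KRT17",
      "EPCAM", "ELF3", "IGFBP2", "SERPINF1"
    ),
    votes = c(4L, 4L, 3L, 2L, 2L, 2L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

basal_resting_path <- function() {
  system.file("extdata", "basal_resting_dictionary.tsv", package = "fpcam")
}

# brute-force similarity oracle: explicit triple loop over clusters,
# types and the full gene cross product; independent of the matrix code
brute_similarity <- function(em, dict) {
  rec <- dict$records
  types <- dict$cell_types
  s <- matrix(0,
    nrow = length(em$clusters), ncol = length(types),
    dimnames = list(em$clusters, types)
  )
  for (j in seq_along(em$clusters)) {
    for (m in seq_along(types)) {
      d <- rec[rec$cell_type == types[m], , drop = FALSE]
      acc <- 0
      for (r in seq_len(nrow(d))) {
        g <- d$gene[r]
        if (g %in% rownames(em$E)) {
          acc <- acc + em$E[g, j] * d$percent[r]
        }
      }
      s[j, m] <- acc
    }
  }
  s
}

# exhaustive majority oracle: full count table
exhaustive_majority <- function(votes) {
  counts <- table(votes)
  top <- names(counts)[counts == max(counts)]
  strict <- max(counts) > length(votes) / 2
  list(winner = sort(top)[1], strict = strict)
}

# random small expression matrix + dictionary pair for property tests
random_fixture <- function(n_genes, n_clusters, n_types) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  clusters <- paste0("c", seq_len(n_clusters))
  tab <- expand.grid(
    gene = genes, cluster = clusters,
    stringsAsFactors = FALSE
  )
  tab$value <- round(stats::runif(nrow(tab)) *
    stats::rbinom(nrow(tab), 1, 0.6), 4)
  tab <- tab[tab$value > 0, , drop = FALSE]
  if (nrow(tab) == 0) tab <- data.frame(
    gene = genes[1], cluster = clusters[1], value = 1
  )
  em <- normalize_expression(build_expression_matrix(tab))
  rec <- do.call(rbind, lapply(seq_len(n_types), function(m) {
    k <- sample(3:min(8, n_genes), 1)
    data.frame(
      cell_type = paste0("T", m),
      gene = sample(genes, k),
      votes = sample(1:6, k, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  list(em = em, dict = marker_dictionary(rec), table = tab)
}

write_tmp <- function(lines, ext = ".tsv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
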