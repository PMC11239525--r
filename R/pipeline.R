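#' Standard RNA-side processing
#'
#' QC filter, log-normalization, variable-gene selection, PCA embedding and
#' high-resolution Louvain clustering in one call.
#'
#' @param counts RNA [count_matrix()].
#' @param mito_gene_ids Mitochondrial gene ids for the QC filter.
#' @param n_var Number of variable genes kept for downstream matching
#'   (default 1,000).
#' @param n_pcs Principal components (default 20).
#' @param resolution Louvain resolution (default 1; the RNA side is the
#'   annotation clustering, coarser than the chromatin high-resolution
#'   clusterings it is matched against).
#' @param knn_k,seed Clustering parameters.
#' @return List with `qc`, `lognorm`, `var_genes`, `embedding`, `clusters`.
#' @export
process_rna <- function(counts, mito_gene_ids = character(), n_var = 1000L,
                        n_pcs = 20L, resolution = 1, knn_k = 20L, seed = 1L) {
  qc <- filter_cells_rna(counts, mito_gene_ids)
  kept <- subset_cells(counts, qc$cell_id[qc$retained])
  lognorm <- lognormalize_rna(kept)
  v <- apply(as.matrix(lognorm), 2, stats::var)
  var_genes <- colnames(lognorm)[order(v, decreasing = TRUE)][
    seq_len(min(n_var, ncol(lognorm)))]
  embedding <- pca_embed(lognorm, features = var_genes[seq_len(min(500L, n_var))],
                         n_pcs = n_pcs, seed = seed)
  clusters <- cluster_highres(embedding, resolution = resolution,
                              knn_k = knn_k, seed = seed)
  list(qc = qc, lognorm = lognorm, var_genes = var_genes,
       embedding = embedding, clusters = clusters)
}

#' Standard chromatin-side processing for one histone mark
#'
#' QC filter, TF-IDF/LSI embedding, high-resolution clustering, gene
#' activity scoring, binarization and per-cluster detection rates.
#'
#' @param counts Chromatin [count_matrix()].
#' @param peaks Peak interval tibble matching the matrix columns.
#' @param genes Gene-model tibble for gene activity.
#' @param n_components,keep_from LSI components (defaults 30, 2).
#' @param resolution Louvain resolution (default 2).
#' @param knn_k,seed Clustering parameters.
#' @return List with `qc`, `counts` (filtered), `embedding`, `clusters`,
#'   `activity`, `binary`, `rates`, `n_fragments`.
#' @export
process_chromatin <- function(counts, peaks, genes, n_components = 30L,
                              keep_from = 2L, resolution = 2, knn_k = 20L,
                              seed = 1L) {
  qc <- filter_cells_chromatin(counts)
  kept <- subset_cells(counts, qc$cell_id[qc$retained])
  embedding <- tfidf_lsi(kept, n_components = n_components,
                         keep_from = keep_from, seed = seed)
  clusters <- cluster_highres(embedding, resolution = resolution,
                              knn_k = knn_k, seed = seed)
  activity <- gene_activity(kept, genes, peaks = peaks)
  binary <- binarize(kept)
  rates <- detection_rates(binary, clusters)
  list(qc = qc, counts = kept, embedding = embedding, clusters = clusters,
       activity = activity, binary = binary, rates = rates,
       n_fragments = Matrix::rowSums(kept$values))
}

#' Match a processed chromatin modality to processed RNA and transfer labels
#'
#' Computes cluster-level profiles over the shared variable genes,
#' correlation-distance costs (negated for H3K27me3), runs the
#' min-cost-max-flow matching with fallback resolution, and transfers the
#' supplied RNA cluster annotations.
#'
#' @param rna Result of [process_rna()].
#' @param chrom Result of [process_chromatin()].
#' @param rna_annotations Mapping of RNA cluster id to state name (named
#'   vector or tibble `cluster`, `state`).
#' @param sign `+1` for activating marks, `-1` for H3K27me3; by default
#'   inferred from the chromatin modality.
#' @param features Profile features (default: RNA variable genes present in
#'   the activity matrix).
#' @param ... Passed to [mcmf_match()].
#' @return List with `match` (`epi_match`), `labels` (tibble
#'   `chrom_cluster`, `rna_cluster`, `state`, `pair_type`), `cell_states`
#'   (per-cell transferred state).
#' @export
match_chromatin_to_rna <- function(rna, chrom, rna_annotations, sign = NULL,
                                   features = NULL, ...) {
  if (is.null(sign)) {
    sign <- if (chrom$counts$modality == "H3K27me3") -1 else 1
  }
  if (is.null(features)) {
    features <- intersect(rna$var_genes, colnames(chrom$activity))
  }
  rna_prof <- cluster_profiles(as.matrix(rna$lognorm), rna$clusters, features)
  chrom_prof <- cluster_profiles(as.matrix(chrom$activity), chrom$clusters,
                                 features)
  cost <- matching_cost(rna_prof, chrom_prof, sign = sign)
  m <- resolve_unmatched(mcmf_match(cost, ...))
  labels <- transfer_labels(m, rna_annotations)
  cells <- chrom$clusters
  cells$state <- labels$state[match(as.character(cells$cluster),
                                    labels$chrom_cluster)]
  list(match = m, labels = labels, cell_states = cells)
}

#' Majority label per cluster
#'
#' Convenience for annotating clusters from a per-cell reference label
#' (e.g. manual annotations, or the generating state in simulations).
#'
#' @param clusters Tibble `cell_id`, `cluster`.
#' @param reference Tibble `cell_id`, `label` (second column used).
#' @return Tibble `cluster`, `state` (majority label).
#' @export
majority_annotation <- function(clusters, reference) {
  names(reference)[2] <- "label"
  clusters |>
    dplyr::left_join(reference, by = "cell_id") |>
    dplyr::count(.data$cluster, .data$label) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("cluster", state = "label")
}
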