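#' QC filter for RNA cells
#'
#' A cell is retained iff UMIs > 2,000, UMIs < 1.5e5, detected genes > 1,000
#' and mitochondrial fraction < 0.2 (all strict inequalities).
#'
#' @param counts An RNA [count_matrix()].
#' @param mito_gene_ids Character set of mitochondrial gene ids; if empty, the
#'   mitochondrial fraction is 0 for every cell (with a warning).
#' @return QC tibble with columns `cell_id`, `n_umi`, `n_genes`, `frac_mito`,
#'   `retained`.
#' @export
filter_cells_rna <- function(counts, mito_gene_ids = character()) {
  stopifnot(inherits(counts, "count_matrix"))
  if (counts$modality != "RNA") stop("filter_cells_rna expects RNA counts")
  m <- counts$values
  n_umi <- Matrix::rowSums(m)
  n_genes <- Matrix::rowSums(m > 0)
  mito <- intersect(mito_gene_ids, counts$feature_ids)
  if (!length(mito)) {
    warning("no mitochondrial genes found; mitochondrial fraction set to 0")
    frac_mito <- rep(0, nrow(m))
  } else {
    frac_mito <- Matrix::rowSums(m[, mito, drop = FALSE]) / pmax(n_umi, 1)
  }
  qc <- tibble::tibble(
    cell_id = counts$cell_ids,
    n_umi = unname(as.numeric(n_umi)),
    n_genes = unname(as.numeric(n_genes)),
    frac_mito = unname(frac_mito),
    retained = unname(n_umi > 2000 & n_umi < 1.5e5 & n_genes > 1000 &
                        frac_mito < 0.2)
  )
  epi_log("RNA QC: %d/%d cells retained", sum(qc$retained), nrow(qc))
  qc
}

#' QC filter for chromatin (scCUT&Tag) cells
#'
#' Cells with fewer than 200 fragments (H3K27ac, H3K4me3) or fewer than 100
#' fragments (H3K27me3) are removed; cells exactly at the boundary are kept.
#'
#' @param counts A chromatin [count_matrix()].
#' @return Tibble with `cell_id`, `n_fragments`, `retained`.
#' @export
filter_cells_chromatin <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  min_frag <- switch(counts$modality,
                     H3K27ac = 200, H3K4me3 = 200, H3K27me3 = 100,
                     stop("unknown chromatin modality: ", counts$modality))
  n_frag <- Matrix::rowSums(counts$values)
  qc <- tibble::tibble(
    cell_id = counts$cell_ids,
    n_fragments = unname(as.numeric(n_frag)),
    retained = unname(n_frag >= min_frag)
  )
  epi_log("%s QC: %d/%d cells retained", counts$modality,
          sum(qc$retained), nrow(qc))
  qc
}

#' Subset a count matrix to a set of cells
#'
#' @param counts A [count_matrix()].
#' @param cell_ids Cells to keep (order preserved as given).
#' @return A [count_matrix()].
#' @export
subset_cells <- function(counts, cell_ids) {
  stopifnot(all(cell_ids %in% counts$cell_ids))
  count_matrix(counts$values[cell_ids, , drop = FALSE], cell_ids,
               counts$feature_ids, modality = counts$modality)
}

#' Log-normalize counts
#'
#' `log(1 + scale_factor * count / cell_total)` with the conventional scale
#' factor of 10,000. Cells with zero totals must be filtered beforehand.
#'
#' @param counts A [count_matrix()] or a cells-by-features sparse matrix.
#' @param scale_factor Scaling constant (default 1e4).
#' @return Sparse cells-by-features matrix of log-normalized values.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  m <- if (inherits(counts, "count_matrix")) counts$values else counts
  totals <- Matrix::rowSums(m)
  if (any(totals == 0)) {
    stop("cells with zero total counts must be filtered before normalization")
  }
  out <- Matrix::Diagonal(x = scale_factor / totals) %*% m
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  methods::as(out, "CsparseMatrix")
}

#' @rdname lognormalize
#' @export
lognormalize_rna <- function(counts, scale_factor = 1e4) {
  if (inherits(counts, "count_matrix") && counts$modality != "RNA") {
    stop("lognormalize_rna expects RNA counts")
  }
  lognormalize(counts, scale_factor)
}

#' TF-IDF transform and latent semantic indexing of a peak matrix
#'
#' Term frequency is count over cell total; inverse document frequency is
#' `log(1 + n_cells / (1 + peak occurrence count))`. A truncated SVD of the
#' transformed matrix yields the LSI embedding; by convention the first
#' component (which tracks depth) is dropped, so components
#' `keep_from..n_components` are returned.
#'
#' @param counts Chromatin [count_matrix()] (cells with zero totals must be
#'   filtered first).
#' @param n_components Last SVD component to retain (default 30).
#' @param keep_from First SVD component to retain (default 2).
#' @param seed Seed for the iterative SVD.
#' @return Numeric matrix (cells x retained components) with an attribute
#'   `d` holding the singular values; class `epi_embedding`.
#' @export
tfidf_lsi <- function(counts, n_components = 30L, keep_from = 2L, seed = 1L) {
  m <- if (inherits(counts, "count_matrix")) counts$values else counts
  stopifnot(n_components >= keep_from, keep_from >= 2)
  if (sum(m) == 0) stop("all-zero matrix")
  totals <- Matrix::rowSums(m)
  if (any(totals == 0)) stop("cells with zero totals must be filtered first")
  tf <- Matrix::Diagonal(x = 1 / totals) %*% m
  occ <- Matrix::colSums(m > 0)
  idf <- log(1 + nrow(m) / (1 + occ))
  x <- tf %*% Matrix::Diagonal(x = idf)
  x <- methods::as(x, "CsparseMatrix")
  k <- min(n_components, min(dim(x)) - 1L)
  sv <- withr::with_seed(as.integer(seed), irlba::irlba(x, nv = k))
  emb <- sv$u[, keep_from:k, drop = FALSE] %*% diag(sv$d[keep_from:k],
                                                    nrow = k - keep_from + 1L)
  rownames(emb) <- rownames(m)
  colnames(emb) <- paste0("LSI_", keep_from:k)
  structure(emb, d = sv$d, method = "tfidf_lsi", class = c("epi_embedding", "matrix", "array"))
}

# strand-aware gene window: gene body plus `upstream` bp of promoter
.gene_windows <- function(genes, upstream = 2000L) {
  start <- ifelse(genes$strand == "+", pmax(0L, genes$start - upstream), genes$start)
  end <- ifelse(genes$strand == "+", genes$end, genes$end + upstream)
  tibble::tibble(chrom = genes$chrom, start = as.integer(start),
                 end = as.integer(end), gene_id = genes$gene_id)
}

#' Gene activity scores from fragments or peak counts
#'
#' Sums fragment counts over each gene's body extended 2 kb upstream of the
#' TSS (strand-aware), then log-normalizes with a scale factor of 10,000.
#' Accepts either a fragments tibble (`chrom`, `start`, `end`, `barcode`,
#' `count`) or a peak-level [count_matrix()] plus its peak intervals, in
#' which case a peak's counts contribute to every gene window it overlaps.
#'
#' @param x Fragment tibble or chromatin [count_matrix()].
#' @param genes Gene-model tibble (see [gene_models()]).
#' @param peaks Peak interval tibble (required when `x` is a count matrix);
#'   rows must match the matrix columns.
#' @param upstream Promoter extension in bp (default 2,000).
#' @param cell_ids For the fragments path, the universe of cells (defaults to
#'   the barcodes present).
#' @return Sparse cells-by-genes matrix of log-normalized gene activities.
#' @export
gene_activity <- function(x, genes, peaks = NULL, upstream = 2000L,
                          cell_ids = NULL) {
  windows <- .gene_windows(genes, upstream)
  if (inherits(x, "count_matrix")) {
    stopifnot(!is.null(peaks), nrow(peaks) == ncol(x$values))
    hits <- intersect_intervals(peaks, windows, slop = 0L)
    if (!nrow(hits)) stop("no peaks overlap any gene window")
    # peak -> gene indicator, then counts %*% indicator
    ind <- Matrix::sparseMatrix(i = hits$i, j = hits$j, x = 1,
                                dims = c(nrow(peaks), nrow(genes)))
    raw <- x$values %*% ind
    dimnames(raw) <- list(x$cell_ids, genes$gene_id)
  } else {
    frag <- x
    if (is.null(cell_ids)) cell_ids <- sort(unique(frag$barcode))
    missing_chrom <- setdiff(windows$chrom, unique(frag$chrom))
    if (length(missing_chrom)) {
      warning("skipping genes on chromosomes absent from fragments: ",
              paste(missing_chrom, collapse = ", "))
    }
    hits <- intersect_intervals(frag, windows, slop = 0L)
    raw <- Matrix::sparseMatrix(
      i = match(frag$barcode[hits$i], cell_ids),
      j = hits$j,
      x = frag$count[hits$i],
      dims = c(length(cell_ids), nrow(genes)),
      dimnames = list(cell_ids, genes$gene_id)
    )
  }
  raw <- methods::as(raw, "CsparseMatrix")
  keep <- Matrix::rowSums(raw) > 0
  if (!all(keep)) {
    warning(sum(!keep), " cells with no gene-window signal dropped")
    raw <- raw[keep, , drop = FALSE]
  }
  lognormalize(raw)
}

#' @keywords internal
#' Shared-nearest-neighbor graph with Jaccard weights (Euclidean kNN)
.snn_graph <- function(embedding, knn_k = 20L) {
  n <- nrow(embedding)
  if (n <= knn_k) stop("fewer cells than knn_k")
  nn <- RANN::nn2(embedding, k = knn_k + 1L)$nn.idx
  neighbor_sets <- lapply(seq_len(n), function(i) nn[i, ])
  # candidate edges: i -- each kNN j
  ii <- rep(seq_len(n), each = knn_k)
  jj <- as.vector(t(nn[, -1, drop = FALSE]))
  jac <- vapply(seq_along(ii), function(e) {
    a <- neighbor_sets[[ii[e]]]; b <- neighbor_sets[[jj[e]]]
    length(intersect(a, b)) / length(union(a, b))
  }, 1)
  keep <- jac > 1 / 15  # prune as in standard SNN construction
  g <- igraph::graph_from_data_frame(
    data.frame(from = pmin(ii, jj)[keep], to = pmax(ii, jj)[keep],
               weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  igraph::simplify(g, edge.attr.comb = "max")
}

#' High-resolution clustering of an embedding
#'
#' Louvain community detection on a Jaccard-weighted shared-nearest-neighbor
#' graph built from Euclidean k-nearest neighbors in the embedding.
#'
#' @param embedding Cells-by-components matrix (e.g. from [tfidf_lsi()]).
#' @param resolution Louvain resolution (> 0); higher gives more clusters.
#' @param knn_k Neighbors for the kNN graph (default 20).
#' @param seed Seed for the (randomized) Louvain optimizer.
#' @param min_cells Clusters smaller than this are merged into the nearest
#'   cluster by centroid distance (default 10); detection rates on
#'   near-singleton clusters are meaningless downstream.
#' @return Tibble with `cell_id` and `cluster` (dense integer ids from 0).
#' @export
cluster_highres <- function(embedding, resolution = 1, knn_k = 20L, seed = 1L,
                            min_cells = 10L) {
  stopifnot(resolution > 0)
  g <- .snn_graph(embedding, knn_k)
  com <- withr::with_seed(as.integer(seed),
                          igraph::cluster_louvain(g, resolution = resolution))
  labels <- as.integer(igraph::membership(com))
  # merge undersized clusters into their nearest (centroid) neighbor
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_cells & sizes < nrow(embedding)]
    if (!length(small) || length(sizes) <= 1) break
    cent <- rowsum(embedding, labels) / as.vector(sizes)
    for (cl in small) {
      d <- sqrt(rowSums((cent - matrix(cent[cl, ], nrow(cent), ncol(cent),
                                       byrow = TRUE))^2))
      d[rownames(cent) == cl] <- Inf
      d[rownames(cent) %in% small] <- d[rownames(cent) %in% small] + 1e6
      labels[labels == as.integer(cl)] <- as.integer(rownames(cent)[which.min(d)])
    }
  }
  # dense 0-based ids, ordered by first appearance for determinism
  dense <- as.integer(factor(labels, levels = unique(labels))) - 1L
  ids <- rownames(embedding)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(embedding)))
  epi_log("cluster_highres: %d clusters at resolution %.2f (seed %d)",
          length(unique(dense)), resolution, seed)
  tibble::tibble(cell_id = ids, cluster = dense)
}

#' PCA embedding of a log-normalized expression matrix
#'
#' Standard RNA-side embedding: z-scales the selected features and takes the
#' top principal components by truncated SVD.
#'
#' @param lognorm Cells-by-genes matrix of log-normalized expression.
#' @param features Features to use (default: the 500 most variable genes).
#' @param n_pcs Principal components retained (default 20).
#' @param seed Seed for the iterative SVD.
#' @return Cells-by-PCs matrix of class `epi_embedding`.
#' @export
pca_embed <- function(lognorm, features = NULL, n_pcs = 20L, seed = 1L) {
  if (is.null(features)) {
    v <- apply(lognorm, 2, stats::var)
    features <- colnames(lognorm)[order(v, decreasing = TRUE)][
      seq_len(min(500L, ncol(lognorm)))]
  }
  x <- scale(as.matrix(lognorm[, features, drop = FALSE]))
  x[is.na(x)] <- 0
  k <- min(n_pcs, min(dim(x)) - 1L)
  pc <- withr::with_seed(as.integer(seed),
                         irlba::prcomp_irlba(x, n = k, center = FALSE,
                                             scale. = FALSE))$x
  rownames(pc) <- rownames(lognorm)
  colnames(pc) <- paste0("PC_", seq_len(k))
  structure(pc, method = "pca", class = c("epi_embedding", "matrix", "array"))
}
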