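# shared fixtures, built once per test run and cached in this environment
.fixtures <- new.env(parent = emptyenv())

# the default simulated dataset (the study conditions); ~5 s to build
default_dataset <- function() {
  if (is.null(.fixtures$ds)) .fixtures$ds <- simulate_dataset(seed = 7)
  .fixtures$ds
}

# random intervals on a small genome
random_intervals <- function(n, seed = 1) {
  withr::with_seed(seed, {
    start <- sample.int(1e5, n)
    tibble::tibble(
      chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
      start = start,
      end = start + sample.int(500, n)
    )
  })
}

# brute-force interval intersection oracle
brute_intersect <- function(a, b, slop) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      a1 <- max(0, a$start[i] - slop); a2 <- a$end[i] + slop
      b1 <- max(0, b$start[j] - slop); b2 <- b$end[j] + slop
      if (a1 < b2 && b1 < a2) out[[length(out) + 1]] <- c(i = i, j = j)
    }
  }
  if (!length(out)) return(tibble::tibble(i = integer(), j = integer()))
  tibble::as_tibble(do.call(rbind, out))
}

# brute-force kNN by full distance matrix
brute_knn <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

# naive memoized DTW (symmetric1) from a local cost matrix
naive_dtw <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  D <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      prev <- c(if (i > 1) D[i - 1, j], if (j > 1) D[i, j - 1],
                if (i > 1 && j > 1) D[i - 1, j - 1])
      D[i, j] <- cost[i, j] + if (length(prev)) min(prev) else 0
    }
  }
  D[n, m]
}

# run the full cross-modality matching on the default dataset and return
# per-mark cluster tables with transferred and true majority states
run_matching_on_dataset <- function(ds, marks = c("H3K27ac", "H3K4me3", "H3K27me3")) {
  if (!is.null(.fixtures$matching)) return(.fixtures$matching)
  truth <- ds$truth$cells
  # synthetic genes carry no mitochondrial ids; the empty-set warning is
  # expected here
  rna <- suppressWarnings(process_rna(ds$counts$RNA))
  ann <- majority_annotation(rna$clusters,
                             truth[truth$modality == "RNA", c("cell_id", "state")])
  ann_vec <- stats::setNames(ann$state, as.character(ann$cluster))
  out <- list(rna = rna, marks = list())
  for (mark in marks) {
    chrom <- process_chromatin(ds$counts[[mark]], ds$peaks[[mark]], ds$genes)
    mm <- match_chromatin_to_rna(rna, chrom, ann_vec)
    maj <- majority_annotation(chrom$clusters,
                               truth[truth$modality == mark, c("cell_id", "state")])
    cmp <- dplyr::inner_join(
      mm$labels,
      dplyr::mutate(maj, chrom_cluster = as.character(cluster)),
      by = "chrom_cluster", suffix = c("_pred", "_true"))
    out$marks[[mark]] <- list(chrom = chrom, match = mm, comparison = cmp)
  }
  .fixtures$matching <- out
  out
}

# a tiny RNA matrix exercising every QC boundary from the filtering rules
qc_fixture <- function() {
  # cells: umi/genes/mito engineered per case
  genes <- c(paste0("g", 1:1500), "MT-1")
  build_cell <- function(umi, n_genes, mito) {
    x <- numeric(length(genes))
    x[seq_len(n_genes)] <- 1
    x[seq_len(n_genes)][1] <- umi - n_genes + 1 - mito
    x[length(genes)] <- mito
    x
  }
  cells <- list(
    pass = build_cell(2001, 1001, 0),
    umi_low = build_cell(2000, 1001, 0),
    umi_high = build_cell(1.5e5, 1001, 0),
    genes_low = build_cell(2500, 1000, 0),
    mito_high = build_cell(3000, 1001, 600)  # fraction exactly 0.2
  )
  m <- do.call(rbind, cells)
  count_matrix(Matrix::Matrix(m, sparse = TRUE), names(cells), genes, "RNA")
}


# stage-specific detection rates, mirroring per-timepoint-group clustering:
# cells of one timepoint group are clustered separately and rates are
# computed over those clusters only
stage_rates <- function(chrom, meta, group = "Mid", resolution = 0.5, seed = 1) {
  ids <- intersect(rownames(chrom$embedding),
                   meta$cell_id[meta$timepoint_group == group])
  # coarse clustering with a size floor: detection-rate maxima over many
  # tiny clusters would be pure noise
  cl <- cluster_highres(chrom$embedding[ids, , drop = FALSE],
                        resolution = resolution, seed = seed, min_cells = 50L)
  rates <- detection_rates(chrom$binary[ids, , drop = FALSE], cl)
  list(rates = rates, clusters = rownames(rates))
}
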