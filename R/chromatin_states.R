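#' Binarize a chromatin count matrix
#'
#' @param counts [count_matrix()] or sparse matrix.
#' @return Sparse 0/1 matrix of the same shape.
#' @export
binarize <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$values else counts
  out <- m
  out@x <- as.double(out@x > 0)
  Matrix::drop0(out)
}

# log2 fold change of detection rates with pseudocount
.detection_lfc <- function(rate_a, rate_b, pseudocount = 0.01) {
  log2((rate_a + pseudocount) / (rate_b + pseudocount))
}

# binomial logit GLM LRT for one peak: full = [1, covars, groups], null = [1, covars]
.binom_lrt <- function(y, X_full, X_null) {
  fit_f <- suppressWarnings(stats::glm.fit(X_full, y, family = stats::binomial()))
  fit_n <- suppressWarnings(stats::glm.fit(X_null, y, family = stats::binomial()))
  df <- ncol(X_full) - ncol(X_null)
  stat <- max(fit_n$deviance - fit_f$deviance, 0)
  list(p = stats::pchisq(stat, df, lower.tail = FALSE),
       coef = fit_f$coefficients)
}

#' Differential peak detection between groups (binomial GLM + LRT)
#'
#' For every peak, fits a binomial logit GLM of binarized detection on the
#' per-cell fragment total plus the group factor, and a null model without
#' the group; the likelihood-ratio chi-square with `levels - 1` degrees of
#' freedom gives one p-value per peak, corrected by Benjamini-Hochberg over
#' all peaks tested. Per-group effects are deviation-coded coefficients
#' (sum-to-zero contrasts), and each group also gets the log2 fold change of
#' its detection rate versus all other cells (pseudocount 0.01).
#'
#' Peaks detected in no cell or in every cell are reported with `p = 1` and
#' flagged `degenerate` rather than dropped.
#'
#' @param Y Binary cells-by-peaks matrix (see [binarize()]).
#' @param group Factor-like group label per cell (>= 2 levels).
#' @param n_fragments Positive per-cell fragment totals.
#' @param pseudocount Pseudocount on detection rates (default 0.01).
#' @return Tibble with one row per peak x group: `peak_id`, `group`,
#'   `effect`, `detection_lfc`, `p`, `fdr`, `degenerate`.
#' @export
differential_peaks <- function(Y, group, n_fragments, pseudocount = 0.01) {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2, all(n_fragments > 0),
            length(group) == nrow(Y), length(n_fragments) == nrow(Y))
  lv <- levels(group)
  nf <- log(n_fragments)
  nf <- if (stats::sd(nf) > 0) (nf - mean(nf)) / stats::sd(nf) else rep(0, length(nf))
  G <- stats::model.matrix(~g, data = data.frame(g = group),
                           contrasts.arg = list(g = "contr.sum"))
  X_full <- cbind(1, nf, G[, -1, drop = FALSE])
  X_null <- cbind(1, nf)
  n_peaks <- ncol(Y)
  peak_ids <- colnames(Y) %||% as.character(seq_len(n_peaks))
  Y <- methods::as(Y, "CsparseMatrix")
  det <- Matrix::colSums(Y)
  p_vec <- rep(1, n_peaks)
  eff <- matrix(0, n_peaks, nlevels(group))
  degenerate <- det == 0 | det == nrow(Y)
  for (k in which(!degenerate)) {
    y <- Y[, k]
    fit <- .binom_lrt(as.numeric(y), X_full, X_null)
    p_vec[k] <- fit$p
    dev_coefs <- fit$coef[-(1:2)]
    eff[k, ] <- c(dev_coefs, -sum(dev_coefs))  # contr.sum: last level implied
  }
  fdr <- stats::p.adjust(p_vec, method = "BH")
  rates <- t(rowsum(as.matrix(Y), group) / as.vector(table(group)))
  n_by_g <- as.vector(table(group))
  tot_det <- Matrix::colSums(Y)
  out <- purrr::map_dfr(seq_along(lv), function(gi) {
    rest_rate <- (tot_det - rates[, gi] * n_by_g[gi]) / (nrow(Y) - n_by_g[gi])
    tibble::tibble(
      peak_id = peak_ids, group = lv[gi],
      effect = eff[, gi],
      detection_rate = rates[, gi],
      detection_lfc = .detection_lfc(rates[, gi], rest_rate, pseudocount),
      p = p_vec, fdr = fdr, degenerate = degenerate
    )
  })
  epi_log("differential_peaks: %d peaks, %d groups, %d degenerate",
          n_peaks, nlevels(group), sum(degenerate))
  out
}

#' Per-cluster detection rates
#'
#' @param Y Binary cells-by-peaks matrix.
#' @param clusters Tibble `cell_id`, `cluster` or a vector aligned with rows.
#' @return Clusters-by-peaks matrix of detection rates.
#' @export
detection_rates <- function(Y, clusters) {
  grp <- if (is.data.frame(clusters)) {
    clusters$cluster[match(rownames(Y), clusters$cell_id)]
  } else clusters
  grp <- factor(grp)
  sums <- rowsum(as.matrix(Y), grp)
  rates <- sums / as.vector(table(grp))
  rownames(rates) <- levels(grp)
  rates
}

# pairs of (a-table row, b-table row) whose diff calls oppose in some group;
# returns per-pair the qualifying groups and signs
.opposite_effects <- function(diff_a, diff_b, peak_a, peak_b,
                              fdr_threshold = 0.05, lfc_threshold = 0.25) {
  da <- diff_a[diff_a$peak_id == peak_a & !diff_a$degenerate &
                 diff_a$fdr < fdr_threshold &
                 abs(diff_a$detection_lfc) > lfc_threshold, ]
  db <- diff_b[diff_b$peak_id == peak_b & !diff_b$degenerate &
                 diff_b$fdr < fdr_threshold &
                 abs(diff_b$detection_lfc) > lfc_threshold, ]
  if (!nrow(da) || !nrow(db)) return(NULL)
  j <- dplyr::inner_join(da, db, by = "group", suffix = c("_a", "_b"))
  j <- j[sign(j$effect_a) == -sign(j$effect_b) & j$effect_a != 0, ]
  if (!nrow(j)) return(NULL)
  j
}

#' Call bivalent regions (H3K4me3 + H3K27me3)
#'
#' Candidate pairs are K4me3/K27me3 peaks overlapping after +/-2 kb
#' extension. A pair is called bivalent when (a) both marks are detected at
#' rate > `min_det` in at least one neuroepithelium-stage cluster and (b)
#' the pair shows regional differential enrichment with opposite effect
#' signs (both FDR < 0.05 and |log2 detection fold change| > 0.25). Each
#' call is classified per qualifying branch: `activated` (K4me3 up, K27me3
#' down), `repressed` (the reverse).
#'
#' @param k4_peaks,me3_peaks Peak interval tibbles with `peak_id`.
#' @param k4_rates,me3_rates Cluster-by-peak detection-rate matrices.
#' @param k4_diff,me3_diff [differential_peaks()] tables over regional groups.
#' @param stage_clusters Neuroepithelium-stage cluster ids of the H3K4me3
#'   clustering (cluster ids are modality-specific).
#' @param me3_stage_clusters Neuroepithelium-stage cluster ids of the
#'   H3K27me3 clustering (defaults to `stage_clusters` when both matrices
#'   share a cluster universe).
#' @param slop Extension in bp (default 2,000).
#' @param min_det Neuroepithelium detection threshold (default 0.05).
#' @param fdr_threshold,lfc_threshold Differential thresholds (0.05, 0.25).
#' @return Tibble with one row per called pair x qualifying branch:
#'   `k4_peak_id`, `me3_peak_id`, `chrom`, `start`, `end` (merged interval),
#'   `branch`, `class`.
#' @export
call_bivalent <- function(k4_peaks, me3_peaks, k4_rates, me3_rates,
                          k4_diff, me3_diff, stage_clusters,
                          me3_stage_clusters = stage_clusters,
                          slop = 2000L, min_det = 0.05,
                          fdr_threshold = 0.05, lfc_threshold = 0.25) {
  if (!length(stage_clusters) || !length(me3_stage_clusters)) {
    stop("stage_clusters is empty")
  }
  stage_clusters <- as.character(stage_clusters)
  me3_stage_clusters <- as.character(me3_stage_clusters)
  stopifnot(all(stage_clusters %in% rownames(k4_rates)),
            all(me3_stage_clusters %in% rownames(me3_rates)))
  pairs <- intersect_intervals(k4_peaks, me3_peaks, slop = slop)
  if (!nrow(pairs)) return(tibble::tibble())
  k4_ne <- apply(k4_rates[stage_clusters, , drop = FALSE], 2, max)
  me3_ne <- apply(me3_rates[me3_stage_clusters, , drop = FALSE], 2, max)
  pairs <- pairs[k4_ne[k4_peaks$peak_id[pairs$i]] > min_det &
                   me3_ne[me3_peaks$peak_id[pairs$j]] > min_det, ]
  out <- purrr::pmap_dfr(pairs, function(i, j) {
    opp <- .opposite_effects(k4_diff, me3_diff,
                             k4_peaks$peak_id[i], me3_peaks$peak_id[j],
                             fdr_threshold, lfc_threshold)
    if (is.null(opp)) return(tibble::tibble())
    tibble::tibble(
      k4_peak_id = k4_peaks$peak_id[i],
      me3_peak_id = me3_peaks$peak_id[j],
      chrom = k4_peaks$chrom[i],
      start = min(k4_peaks$start[i], me3_peaks$start[j]),
      end = max(k4_peaks$end[i], me3_peaks$end[j]),
      branch = opp$group,
      class = ifelse(opp$effect_a > 0, "activated", "repressed")
    )
  })
  epi_log("call_bivalent: %d candidate pairs, %d called",
          nrow(pairs), length(unique(out$k4_peak_id)))
  out
}

#' Call switching regions (H3K27me3 <-> H3K27ac)
#'
#' Candidate pairs are overlapping K27me3/K27ac peaks where exactly one of
#' the two marks exceeds `min_det` detection in some neuroepithelium-stage
#' cluster. The branch of activation is the branch where the other mark
#' becomes differentially enriched while the neuroepithelium mark is
#' depleted. Calls where the neuroepithelium mark is H3K27me3 (repression
#' resolving to activation) carry `direction = "activating"`; the converse
#' carries `direction = "deactivating"`.
#'
#' @inheritParams call_bivalent
#' @param ac_peaks,ac_rates,ac_diff H3K27ac inputs.
#' @param stage_clusters Neuroepithelium-stage cluster ids of the H3K27me3
#'   clustering.
#' @param ac_stage_clusters Neuroepithelium-stage cluster ids of the H3K27ac
#'   clustering (defaults to `stage_clusters`).
#' @return Tibble with `me3_peak_id`, `ac_peak_id`, merged interval columns,
#'   `branch`, `direction`.
#' @export
call_switching <- function(me3_peaks, ac_peaks, me3_rates, ac_rates,
                           me3_diff, ac_diff, stage_clusters,
                           ac_stage_clusters = stage_clusters,
                           slop = 2000L, min_det = 0.05,
                           fdr_threshold = 0.05, lfc_threshold = 0.25) {
  if (!length(stage_clusters) || !length(ac_stage_clusters)) {
    stop("stage_clusters is empty")
  }
  stage_clusters <- as.character(stage_clusters)
  ac_stage_clusters <- as.character(ac_stage_clusters)
  pairs <- intersect_intervals(me3_peaks, ac_peaks, slop = slop)
  if (!nrow(pairs)) return(tibble::tibble())
  me3_ne <- apply(me3_rates[stage_clusters, , drop = FALSE], 2, max)
  ac_ne <- apply(ac_rates[ac_stage_clusters, , drop = FALSE], 2, max)
  det_me3 <- me3_ne[me3_peaks$peak_id[pairs$i]] > min_det
  det_ac <- ac_ne[ac_peaks$peak_id[pairs$j]] > min_det
  pairs <- pairs[xor(det_me3, det_ac), ]
  det_me3 <- det_me3[xor(det_me3, det_ac)]
  out <- purrr::pmap_dfr(cbind(pairs, ne_is_me3 = det_me3),
                         function(i, j, ne_is_me3) {
    # gaining mark must be enriched in a branch where the NE mark is depleted
    if (ne_is_me3) {
      opp <- .opposite_effects(ac_diff, me3_diff,
                               ac_peaks$peak_id[j], me3_peaks$peak_id[i],
                               fdr_threshold, lfc_threshold)
    } else {
      opp <- .opposite_effects(me3_diff, ac_diff,
                               me3_peaks$peak_id[i], ac_peaks$peak_id[j],
                               fdr_threshold, lfc_threshold)
    }
    if (is.null(opp)) return(tibble::tibble())
    opp <- opp[opp$effect_a > 0, ]  # the gaining mark goes up in that branch
    if (!nrow(opp)) return(tibble::tibble())
    tibble::tibble(
      me3_peak_id = me3_peaks$peak_id[i],
      ac_peak_id = ac_peaks$peak_id[j],
      chrom = me3_peaks$chrom[i],
      start = min(me3_peaks$start[i], ac_peaks$start[j]),
      end = max(me3_peaks$end[i], ac_peaks$end[j]),
      branch = opp$group,
      direction = if (ne_is_me3) "activating" else "deactivating"
    )
  })
  epi_log("call_switching: %d candidate pairs, %d called",
          nrow(pairs), length(unique(out$me3_peak_id)))
  out
}

#' Classify peaks as promoter, distal or other
#'
#' Promoter: within 2 kb of any TSS. Distal: farther than 3 kb from every
#' gene body. Other: in between.
#'
#' @param peaks Peak interval tibble.
#' @param genes Gene-model tibble with `tss`.
#' @param promoter_dist,distal_dist Thresholds in bp (2,000 and 3,000).
#' @return The peak tibble with a `locus_class` column.
#' @export
classify_locus <- function(peaks, genes, promoter_dist = 2000L,
                           distal_dist = 3000L) {
  gp <- .as_granges(peaks)
  tss <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$tss + 1L, genes$tss + 1L))
  bodies <- .as_granges(genes)
  d_tss <- rep(Inf, nrow(peaks))
  hit_tss <- GenomicRanges::distanceToNearest(gp, tss)
  d_tss[S4Vectors::queryHits(hit_tss)] <- S4Vectors::mcols(hit_tss)$distance
  d_body <- rep(Inf, nrow(peaks))
  hit_body <- GenomicRanges::distanceToNearest(gp, bodies)
  d_body[S4Vectors::queryHits(hit_body)] <- S4Vectors::mcols(hit_body)$distance
  peaks$locus_class <- dplyr::case_when(
    d_tss <= promoter_dist ~ "promoter",
    d_body > distal_dist ~ "distal",
    TRUE ~ "other"
  )
  peaks
}

#' Build the regulatory-region embedding across modalities
#'
#' Per modality, keeps peaks detected (rate > `det_rate`) in more than
#' `min_clusters` high-resolution clusters and at rate > `min_rate` in at
#' least one cluster; merges surviving peaks across modalities into regions
#' by interval union; represents each region by the concatenated per-cluster
#' detection rates of its member peaks in all modalities; z-scales per
#' region, regresses out the number of detected clusters, and runs PCA plus
#' Louvain clustering. The region class records which marks contributed.
#'
#' @param rates Named list (per modality) of cluster-by-peak rate matrices
#'   sharing the cluster universe.
#' @param peaks Named list of peak interval tibbles matching `rates` columns.
#' @param min_clusters Detection breadth threshold (default 50).
#' @param min_rate Maximum-rate threshold (default 0.10).
#' @param det_rate Per-cluster detection definition (default 0.05).
#' @param n_pcs Principal components (default 20).
#' @param resolution Louvain resolution (default 1).
#' @param knn_k kNN for region clustering (default 20).
#' @param seed Seed.
#' @return List of class `epi_region_map`: `regions` tibble (`region_id`,
#'   interval, `class`, `cluster`), `matrix` (regions x cluster-modality),
#'   `embedding` (regions x PCs).
#' @export
region_embedding_build <- function(rates, peaks, min_clusters = 50L,
                                   min_rate = 0.10, det_rate = 0.05,
                                   n_pcs = 20L, resolution = 1,
                                   knn_k = 20L, seed = 1L) {
  mods <- names(rates)
  stopifnot(!is.null(mods), identical(mods, names(peaks)))
  surviving <- lapply(mods, function(mod) {
    r <- rates[[mod]]
    breadth <- colSums(r > det_rate)
    peak_keep <- breadth > min_clusters & apply(r, 2, max) > min_rate
    p <- peaks[[mod]][match(colnames(r)[peak_keep], peaks[[mod]]$peak_id), ]
    p$modality <- mod
    p
  })
  all_peaks <- dplyr::bind_rows(surviving)
  if (!nrow(all_peaks)) stop("no regions survive filtering")
  merged <- GenomicRanges::reduce(.as_granges(all_peaks))
  region_ids <- peak_id(as.character(GenomicRanges::seqnames(merged)),
                        GenomicRanges::start(merged) - 1L,
                        GenomicRanges::end(merged))
  hits <- GenomicRanges::findOverlaps(.as_granges(all_peaks), merged)
  all_peaks$region <- region_ids[S4Vectors::subjectHits(hits)]
  n_regions <- length(region_ids)
  blocks <- lapply(mods, function(mod) {
    r <- rates[[mod]]
    block <- matrix(0, n_regions, nrow(r),
                    dimnames = list(region_ids, paste0(mod, ":", rownames(r))))
    pm <- all_peaks[all_peaks$modality == mod, ]
    for (k in seq_len(nrow(pm))) {
      ri <- pm$region[k]
      block[ri, ] <- pmax(block[ri, ], r[, pm$peak_id[k]])
    }
    block
  })
  M <- do.call(cbind, blocks)
  classes <- vapply(region_ids, function(ri) {
    paste(sort(unique(all_peaks$modality[all_peaks$region == ri])),
          collapse = "+")
  }, "")
  # z-scale per region, then regress out detection breadth
  Z <- t(scale(t(M)))
  Z[is.na(Z)] <- 0
  n_detected <- rowSums(M > det_rate)
  Zr <- apply(Z, 2, function(col) stats::residuals(stats::lm(col ~ n_detected)))
  k <- min(n_pcs, min(dim(Zr)) - 1L)
  pcs <- if (min(dim(Zr)) < 5 * k) {
    stats::prcomp(Zr, center = TRUE, scale. = FALSE)$x[, seq_len(k), drop = FALSE]
  } else {
    withr::with_seed(as.integer(seed),
                     irlba::prcomp_irlba(Zr, n = k, center = TRUE,
                                         scale. = FALSE))$x
  }
  rownames(pcs) <- region_ids
  cl <- cluster_highres(pcs, resolution = resolution,
                        knn_k = min(knn_k, n_regions - 1L), seed = seed)
  iv <- parse_peak_id(region_ids)
  regions <- tibble::tibble(
    region_id = region_ids, chrom = iv$chrom, start = iv$start, end = iv$end,
    class = unname(classes),
    cluster = cl$cluster[match(region_ids, cl$cell_id)]
  )
  structure(list(regions = regions, matrix = M, embedding = pcs,
                 member_peaks = all_peaks), class = "epi_region_map")
}

#' Four-way regulatory census of genes
#'
#' Classes each gene by whether activity (active marks or expression) and
#' H3K27me3 are detected above threshold in at least one cluster anywhere in
#' the timecourse: `active_and_repressed`, `always_active`,
#' `always_repressed`, `inactive_unmarked`.
#'
#' @param active_detection Named list of gene-by-cluster detection matrices
#'   (or max-rate vectors) for active marks / expression.
#' @param repressive_detection Same for H3K27me3.
#' @param threshold Detection threshold (default 0.05).
#' @return Tibble `gene_id`, `active_anywhere`, `repressed_anywhere`,
#'   `class`.
#' @export
gene_regulatory_census <- function(active_detection, repressive_detection,
                                   threshold = 0.05) {
  max_of <- function(x) {
    if (is.matrix(x)) apply(x, 1, max) else x
  }
  act <- do.call(pmax, lapply(active_detection, max_of))
  rep_ <- do.call(pmax, lapply(repressive_detection, max_of))
  stopifnot(length(act) == length(rep_))
  genes <- names(act) %||% as.character(seq_along(act))
  active <- act > threshold
  repressed <- rep_ > threshold
  tibble::tibble(
    gene_id = genes,
    active_anywhere = active,
    repressed_anywhere = repressed,
    class = dplyr::case_when(
      active & repressed ~ "active_and_repressed",
      active & !repressed ~ "always_active",
      !active & repressed ~ "always_repressed",
      TRUE ~ "inactive_unmarked"
    )
  )
}

#' Bulk perturbation log2 fold changes per peak
#'
#' Per treated sample, `log2((treated + c) / (control + c))` against its
#' paired control (column `pair` in the design) or against the mean of all
#' control samples at the same concentration; fold changes are then averaged
#' per concentration.
#'
#' @param intensity Peaks-by-samples intensity matrix (non-negative).
#' @param design Tibble with `sample`, `condition` (`"treated"` /
#'   `"control"`), `concentration`, and optionally `pair`.
#' @param pseudocount Added to both sides (default 0.01).
#' @return Tibble `peak_id`, `concentration`, `lfc`.
#' @export
bulk_peak_lfc <- function(intensity, design, pseudocount = 0.01) {
  stopifnot(all(design$sample %in% colnames(intensity)))
  controls <- design[design$condition == "control", ]
  if (!nrow(controls)) stop("no control sample in design")
  treated <- design[design$condition == "treated", ]
  per_sample <- purrr::pmap_dfr(treated, function(...) {
    row <- list(...)
    ctrl <- if (!is.null(row$pair) && !is.na(row$pair)) {
      intensity[, controls$sample[match(row$pair, controls$pair)], drop = FALSE]
    } else {
      same_conc <- controls[is.na(controls$concentration) |
                              controls$concentration == row$concentration, ]
      if (!nrow(same_conc)) same_conc <- controls
      intensity[, same_conc$sample, drop = FALSE]
    }
    ctrl_mean <- rowMeans(as.matrix(ctrl))
    tibble::tibble(
      peak_id = rownames(intensity) %||% as.character(seq_len(nrow(intensity))),
      concentration = row$concentration,
      lfc = log2((intensity[, row$sample] + pseudocount) /
                   (ctrl_mean + pseudocount))
    )
  })
  dplyr::summarise(dplyr::group_by(per_sample, .data$peak_id, .data$concentration),
                   lfc = mean(.data$lfc), .groups = "drop")
}
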