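#' Even subsampling across modalities within timepoint groups
#'
#' Per timepoint group, every modality is subsampled to the smallest cell
#' count across modalities, but never below 100: modalities with at least
#' 100 cells keep at least 100, modalities with fewer keep all their cells.
#'
#' @param cells Tibble with `cell_id`, `modality`, `timepoint_group`.
#' @param seed Seed for the subsampling.
#' @param floor_n Minimum kept per modality when available (default 100).
#' @return The input tibble restricted to the retained cells.
#' @export
subsample_even <- function(cells, seed = 1L, floor_n = 100L) {
  withr::with_seed(as.integer(seed), {
    out <- cells |>
      dplyr::group_by(.data$timepoint_group) |>
      dplyr::group_modify(function(df, key) {
        counts <- table(df$modality)
        target <- max(min(counts), floor_n)
        df |>
          dplyr::group_by(.data$modality) |>
          dplyr::group_modify(function(d, k) {
            keep <- min(nrow(d), target)
            d[sample(nrow(d), keep), ]
          }) |>
          dplyr::ungroup()
      }) |>
      dplyr::ungroup()
    out
  })
}

#' Stratify cells into equal-occupancy pseudotime bins
#'
#' Cells are sorted by pseudotime (ties broken by cell id) and cut into `B`
#' contiguous blocks whose sizes differ by at most one cell.
#'
#' @param pt Tibble `cell_id`, `pseudotime`.
#' @param B Number of bins (10, 20 or 50 in typical use).
#' @return Tibble `cell_id`, `pseudotime`, `bin` (1..B).
#' @export
bin_pseudotime <- function(pt, B) {
  n <- nrow(pt)
  stopifnot(B >= 1, B <= n)
  ord <- order(pt$pseudotime, pt$cell_id)
  base <- n %/% B
  extra <- n %% B
  sizes <- rep(base, B) + c(rep(1L, extra), rep(0L, B - extra))
  bins <- rep(seq_len(B), times = sizes)
  out <- pt[ord, ]
  out$bin <- bins
  dplyr::arrange(out, .data$cell_id)
}

#' Per-bin summaries of a feature matrix
#'
#' @param mat Cells-by-features matrix (binary detection or log-normalized
#'   values); rownames are cell ids.
#' @param bins Tibble from [bin_pseudotime()].
#' @param stat `"mean"` (values) or `"detection"` (fraction nonzero).
#' @return Features-by-bins matrix.
#' @export
bin_profile <- function(mat, bins, stat = c("mean", "detection")) {
  stat <- match.arg(stat)
  common <- intersect(rownames(mat), bins$cell_id)
  m <- mat[common, , drop = FALSE]
  b <- factor(bins$bin[match(common, bins$cell_id)],
              levels = sort(unique(bins$bin)))
  if (stat == "detection") m <- (m > 0) * 1
  sums <- rowsum(as.matrix(m), b)
  t(sums / as.vector(table(b)))
}

#' Chromatin-state track over pseudotime bins
#'
#' Restricts to regions where all three marks exceed `min_det` detection in
#' some bin, computes a per-mark threshold as the median detection over
#' those regions and all bins, flags a mark "on" in a bin when its rate
#' exceeds the mark's threshold, and assigns a combination label per bin.
#' By default the biologically contradictory K27me3+K27ac combination is
#' labeled `"conflict"`; the mapping is configurable via `label_map` (names
#' are `+`-joined sorted mark subsets).
#'
#' @param detection Named list with elements `H3K4me3`, `H3K27me3`,
#'   `H3K27ac`: region-by-bin detection-rate matrices over a shared region
#'   universe.
#' @param min_det Eligibility threshold (default 0.05).
#' @param label_map Optional named character vector overriding labels for
#'   mark combinations.
#' @return List of class `epi_state_track`: `labels` (region-by-bin
#'   character matrix), `thresholds`, `eligible` region ids.
#' @export
chromatin_state_track <- function(detection, min_det = 0.05,
                                  label_map = NULL) {
  marks <- c("H3K4me3", "H3K27me3", "H3K27ac")
  stopifnot(all(marks %in% names(detection)))
  regions <- rownames(detection[[1]])
  stopifnot(all(vapply(detection[marks],
                       function(m) identical(rownames(m), regions), TRUE)))
  eligible <- Reduce(`&`, lapply(detection[marks],
                                 function(m) apply(m, 1, max) > min_det))
  if (!any(eligible)) stop("no eligible regions (all below the detection threshold)")
  thresholds <- vapply(detection[marks],
                       function(m) stats::median(m[eligible, ]), 1)
  defaults <- c("none" = "none",
                "H3K27me3" = "K27me3_only", "H3K4me3" = "K4me3_only",
                "H3K27ac" = "K27ac_only",
                "H3K27me3+H3K4me3" = "bivalent",
                "H3K27ac+H3K4me3" = "co_active",
                "H3K27ac+H3K27me3" = "conflict",
                "H3K27ac+H3K27me3+H3K4me3" = "other_combination")
  if (!is.null(label_map)) defaults[names(label_map)] <- label_map
  on <- lapply(marks, function(mk) {
    detection[[mk]][eligible, , drop = FALSE] > thresholds[[mk]]
  })
  names(on) <- marks
  nb <- ncol(detection[[1]])
  elig_ids <- regions[eligible]
  labels <- matrix("none", nrow = length(elig_ids), ncol = nb,
                   dimnames = list(elig_ids, colnames(detection[[1]])))
  for (b in seq_len(nb)) {
    combo <- paste0(ifelse(on$H3K27ac[, b], "H3K27ac+", ""),
                    ifelse(on$H3K27me3[, b], "H3K27me3+", ""),
                    ifelse(on$H3K4me3[, b], "H3K4me3+", ""))
    combo <- sub("\\+$", "", combo)
    combo[combo == ""] <- "none"
    labels[, b] <- unname(defaults[combo])
  }
  structure(list(labels = labels, thresholds = thresholds,
                 eligible = elig_ids), class = "epi_state_track")
}

#' Smooth binned profiles with a cubic-spline GAM
#'
#' Each feature's per-bin means are fit with `mgcv::gam(y ~ s(bin, bs =
#' "cr"))`, smoothing parameter by generalized cross-validation; fitted
#' values are returned at every bin. Constant profiles are returned
#' unchanged.
#'
#' @param binned Features-by-bins matrix.
#' @param k Spline basis dimension (default `min(10, B - 2)`).
#' @return Smoothed matrix of the same shape.
#' @export
smooth_profile <- function(binned, k = NULL) {
  B <- ncol(binned)
  stopifnot(B >= 8)
  if (is.null(k)) k <- min(10L, B - 2L)
  x <- seq_len(B)
  out <- binned
  for (f in seq_len(nrow(binned))) {
    y <- binned[f, ]
    if (stats::sd(y) == 0) next
    fit <- mgcv::gam(y ~ s(x, bs = "cr", k = k), method = "GCV.Cp")
    out[f, ] <- stats::fitted(fit)
  }
  out
}

#' Dynamic time warping distance between multimodal profiles
#'
#' Profiles are modality-by-bin matrices; the local cost between bins is the
#' Euclidean distance between the stacked per-bin modality vectors, and the
#' alignment uses the symmetric step pattern (diagonal, horizontal and
#' vertical moves, unit weights) with no warping window.
#'
#' @param a,b Modality-by-bin matrices (or numeric vectors for a single
#'   modality) with identical modality sets and bin counts.
#' @return Non-negative DTW distance.
#' @export
dtw_distance <- function(a, b) {
  if (is.vector(a)) a <- matrix(a, nrow = 1)
  if (is.vector(b)) b <- matrix(b, nrow = 1)
  if (!identical(dim(a), dim(b))) stop("profiles must share modalities and bin count")
  # cost[i, j] = Euclidean distance between bin i of a and bin j of b;
  # computed by explicit differences so identical bins give an exact zero
  B <- ncol(a)
  cost <- matrix(0, B, B)
  for (j in seq_len(B)) {
    cost[, j] <- sqrt(colSums((a - b[, j])^2))
  }
  .dtw_from_cost(cost)
}

#' Pairwise DTW distance matrix for a list of profiles
#'
#' @param profiles Named list of modality-by-bin matrices.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
dtw_distance_matrix <- function(profiles) {
  n <- length(profiles)
  D <- matrix(0, n, n, dimnames = list(names(profiles), names(profiles)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- dtw_distance(profiles[[i]], profiles[[j]])
    }
  }
  D
}

#' Cluster features by DTW distance (k-medoids)
#'
#' Partitions a precomputed DTW distance matrix with k-medoids (PAM), the
#' distance-native analogue of k-means.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param k Number of clusters (< number of features).
#' @param seed Seed (PAM with `pamonce` is deterministic; the seed guards
#'   the build phase for large inputs).
#' @return Tibble `feature`, `cluster` (1..k), `is_medoid`.
#' @export
cluster_profiles_dtw <- function(D, k, seed = 1L) {
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of features")
  stopifnot(isTRUE(all.equal(D, t(D), tolerance = 1e-8)),
            all(abs(diag(D)) < 1e-12))
  fit <- withr::with_seed(as.integer(seed),
                          cluster::pam(stats::as.dist(D), k = k, diss = TRUE))
  feats <- rownames(D) %||% as.character(seq_len(n))
  tibble::tibble(
    feature = feats,
    cluster = as.integer(fit$clustering),
    is_medoid = feats %in% (rownames(D)[fit$id.med] %||% as.character(fit$id.med))
  )
}

# two-group binomial LRT on binary detection, optional depth covariate;
# without covariate this is the closed-form G-test on the 2x2 table
.detection_test <- function(y, in_bin, n_fragments = NULL) {
  if (is.null(n_fragments)) {
    n1 <- sum(in_bin); n0 <- sum(!in_bin)
    k1 <- sum(y[in_bin]); k0 <- sum(y[!in_bin])
    ll <- function(k, n) {
      if (k == 0 || k == n) return(0)
      p <- k / n
      k * log(p) + (n - k) * log(1 - p)
    }
    stat <- 2 * (ll(k1, n1) + ll(k0, n0) - ll(k1 + k0, n1 + n0))
    stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
  } else {
    X_full <- cbind(1, scale(log(n_fragments))[, 1], as.numeric(in_bin))
    X_null <- X_full[, 1:2]
    .binom_lrt(y, X_full, X_null)$p
  }
}

#' First pseudotime bin of significant divergence from baseline
#'
#' For every feature, each bin after the baseline is tested against the
#' baseline bin with the binomial differential-detection test;
#' Benjamini-Hochberg correction is applied over all (feature, bin) tests in
#' the call. The first divergent bin is the smallest bin with FDR <
#' `fdr_threshold` and log2 detection fold change > `lfc_threshold`
#' (`direction = "increase"`) or < `-lfc_threshold` for repressive marks
#' (`direction = "decrease"`).
#'
#' @param Y Binary cells-by-features detection matrix.
#' @param bins Per-cell bin index (1..B), aligned with rows of `Y`.
#' @param baseline_bin Baseline bin (default 1).
#' @param fdr_threshold,lfc_threshold Divergence thresholds (0.05, 0.25).
#' @param direction Qualifying direction of change.
#' @param n_fragments Optional per-cell depth covariate for the GLM form of
#'   the test.
#' @param pseudocount Pseudocount on rates (default 0.01).
#' @return Tibble `feature`, `first_divergent_bin` (NA when no bin
#'   qualifies), plus the per-test table as attribute `tests`.
#' @export
first_divergent_bin <- function(Y, bins, baseline_bin = 1L,
                                fdr_threshold = 0.05, lfc_threshold = 0.25,
                                direction = c("increase", "decrease"),
                                n_fragments = NULL, pseudocount = 0.01) {
  direction <- match.arg(direction)
  stopifnot(length(bins) == nrow(Y))
  if (!any(bins == baseline_bin)) stop("baseline bin is empty")
  other_bins <- sort(setdiff(unique(bins), baseline_bin))
  if (!length(other_bins)) stop("need at least 2 bins")
  feats <- colnames(Y) %||% as.character(seq_len(ncol(Y)))
  Y <- as.matrix(Y)
  base_idx <- bins == baseline_bin
  tests <- purrr::map_dfr(other_bins, function(b) {
    idx <- bins == b | base_idx
    in_bin <- bins[idx] == b
    nf <- if (is.null(n_fragments)) NULL else n_fragments[idx]
    ps <- vapply(seq_along(feats), function(g) {
      y <- Y[idx, g]
      if (all(y == 0) || all(y == 1)) return(1)
      .detection_test(y, in_bin, nf)
    }, 1)
    rate_b <- colMeans(Y[bins == b, , drop = FALSE])
    rate_0 <- colMeans(Y[base_idx, , drop = FALSE])
    tibble::tibble(feature = feats, bin = b, p = ps,
                   lfc = .detection_lfc(rate_b, rate_0, pseudocount))
  })
  tests$fdr <- stats::p.adjust(tests$p, method = "BH")
  qualifies <- tests$fdr < fdr_threshold &
    (if (direction == "increase") tests$lfc > lfc_threshold
     else tests$lfc < -lfc_threshold)
  first <- tests[qualifies, ] |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(first_divergent_bin = min(.data$bin), .groups = "drop")
  out <- tibble::tibble(feature = feats) |>
    dplyr::left_join(first, by = "feature")
  attr(out, "tests") <- tests
  out
}

#' Pseudotime lag between RNA and chromatin divergence
#'
#' `lag = RNA bin - chromatin bin`; positive lags mean the chromatin change
#' precedes RNA expression (epigenetic priming). Undefined when either
#' modality has no divergent bin.
#'
#' @param rna First-divergent-bin tibble for RNA (from
#'   [first_divergent_bin()]).
#' @param chrom Named list of first-divergent-bin tibbles per chromatin
#'   modality.
#' @return Tibble `feature`, `modality`, `rna_bin`, `chrom_bin`, `lag`.
#' @export
pseudotime_lag <- function(rna, chrom) {
  stopifnot(is.list(chrom), !is.null(names(chrom)))
  purrr::imap_dfr(chrom, function(tbl, mod) {
    j <- dplyr::inner_join(
      dplyr::rename(rna, rna_bin = "first_divergent_bin"),
      dplyr::rename(tbl, chrom_bin = "first_divergent_bin"),
      by = "feature")
    j$modality <- mod
    j$lag <- j$rna_bin - j$chrom_bin
    j[, c("feature", "modality", "rna_bin", "chrom_bin", "lag")]
  })
}

#' Annotate network edges with per-bin epigenomic states
#'
#' For each (factor, target, region) edge of a provided regulatory network,
#' reports which chromatin marks exceed the detection threshold at the
#' edge's region in every pseudotime bin.
#'
#' @param edges Tibble with `factor`, `target`, `region_id`.
#' @param detection Named list of region-by-bin detection-rate matrices per
#'   mark.
#' @param threshold Detection threshold (default 0.05).
#' @return Tibble `factor`, `target`, `region_id`, `bin`, `state`
#'   (`+`-joined detected marks or `"none"`). Edges with unresolvable
#'   regions are skipped with a warning.
#' @export
annotate_network_edges <- function(edges, detection, threshold = 0.05) {
  marks <- names(detection)
  regions <- rownames(detection[[1]])
  unresolved <- !(edges$region_id %in% regions)
  if (any(unresolved)) {
    warning("skipping ", sum(unresolved), " edge(s) with unresolvable regions")
    edges <- edges[!unresolved, ]
  }
  nb <- ncol(detection[[1]])
  purrr::pmap_dfr(edges, function(...) {
    e <- list(...)
    state <- vapply(seq_len(nb), function(b) {
      present <- marks[vapply(marks, function(mk) {
        detection[[mk]][e$region_id, b] > threshold
      }, TRUE)]
      if (!length(present)) "none" else paste(sort(present), collapse = "+")
    }, "")
    tibble::tibble(factor = e$factor, target = e$target,
                   region_id = e$region_id, bin = seq_len(nb), state = state)
  })
}
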