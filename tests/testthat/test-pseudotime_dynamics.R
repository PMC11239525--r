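test_that("even subsampling follows the min-across-modalities rule with floor 100", {
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:950),
    modality = c(rep("RNA", 500), rep("H3K27ac", 300), rep("H3K27me3", 150)),
    timepoint_group = "Mid")
  out <- subsample_even(cells, seed = 1)
  expect_equal(unname(table(out$modality)["RNA"]), 150L, ignore_attr = TRUE)
  expect_equal(unname(table(out$modality)["H3K27ac"]), 150L, ignore_attr = TRUE)
  expect_equal(unname(table(out$modality)["H3K27me3"]), 150L, ignore_attr = TRUE)

  # a modality below 100 keeps everything; the others keep 100
  cells2 <- tibble::tibble(
    cell_id = paste0("d", 1:780),
    modality = c(rep("RNA", 400), rep("H3K27ac", 300), rep("H3K27me3", 80)),
    timepoint_group = "Late")
  out2 <- subsample_even(cells2, seed = 1)
  tab <- table(out2$modality)
  expect_equal(unname(tab["H3K27me3"]), 80L, ignore_attr = TRUE)
  expect_equal(unname(tab["RNA"]), 100L, ignore_attr = TRUE)
  expect_equal(unname(tab["H3K27ac"]), 100L, ignore_attr = TRUE)

  # deterministic given the seed
  expect_identical(subsample_even(cells, seed = 5)$cell_id,
                   subsample_even(cells, seed = 5)$cell_id)
})

test_that("pseudotime bins are contiguous, equal within one cell, and monotone", {
  pt <- tibble::tibble(cell_id = sprintf("c%03d", 1:100),
                       pseudotime = withr::with_seed(50, runif(100)))
  b <- bin_pseudotime(pt, 50)
  expect_equal(unname(table(b$bin)), rep(2L, 50), ignore_attr = TRUE)
  # monotone in pseudotime
  ord <- order(b$pseudotime)
  expect_true(all(diff(b$bin[ord]) >= 0))
  # union of bins is the input
  expect_setequal(b$cell_id, pt$cell_id)

  pt2 <- tibble::tibble(cell_id = sprintf("d%03d", 1:101),
                        pseudotime = withr::with_seed(51, runif(101)))
  b2 <- bin_pseudotime(pt2, 50)
  expect_setequal(unique(unname(table(b2$bin))), c(2L, 3L))
})

test_that("binned profiles average values and detection correctly", {
  m <- matrix(c(1, 3, 0, 2,
                0, 0, 4, 4), 4, 2,
              dimnames = list(paste0("c", 1:4), c("f1", "f2")))
  bins <- tibble::tibble(cell_id = paste0("c", 1:4), pseudotime = 1:4 / 4,
                         bin = c(1, 1, 2, 2))
  bp <- bin_profile(m, bins, stat = "mean")
  expect_equal(bp["f1", ], c(`1` = 2, `2` = 1))
  bd <- bin_profile(m, bins, stat = "detection")
  expect_equal(bd["f1", ], c(`1` = 1, `2` = 0.5))
})

test_that("the chromatin-state track applies median thresholds and combination labels", {
  regions <- c(paste0("e", 1:4), "r5")
  bins <- paste0("bin", 1:6)
  mk <- function(vals) matrix(rep(vals, each = 6), 5, 6, byrow = TRUE,
                              dimnames = list(regions, bins))
  # e1..e4 are eligible (every mark above 5% in some bin); r5 is not.
  # Per mark, two regions sit high (.6) and two low (.1), so the median
  # threshold over eligible regions x bins is .35 and "on" means .6.
  k4 <- mk(c(0.6, 0.1, 0.6, 0.1, 0.3))
  me3 <- mk(c(0.6, 0.6, 0.1, 0.1, 0.3))
  ac <- mk(c(0.1, 0.6, 0.6, 0.1, 0.02))
  tr <- chromatin_state_track(list(H3K4me3 = k4, H3K27me3 = me3, H3K27ac = ac))
  expect_setequal(tr$eligible, paste0("e", 1:4))
  expect_equal(unname(tr$thresholds),
               rep(0.35, 3), tolerance = 1e-12)
  expect_equal(unname(tr$labels["e1", 1]), "bivalent")
  expect_equal(unname(tr$labels["e2", 1]), "conflict")
  expect_equal(unname(tr$labels["e3", 1]), "co_active")
  expect_equal(unname(tr$labels["e4", 1]), "none")
  # label map override for the contested repressive+active combination
  tr2 <- chromatin_state_track(list(H3K4me3 = k4, H3K27me3 = me3, H3K27ac = ac),
                               label_map = c("H3K27ac+H3K27me3" = "active_promoter"))
  expect_equal(unname(tr2$labels["e2", 1]), "active_promoter")
  # brute-force recomputation of all labels
  thr <- tr$thresholds
  for (r in tr$eligible) {
    on <- c(k4[r, 1] > thr["H3K4me3"], me3[r, 1] > thr["H3K27me3"],
            ac[r, 1] > thr["H3K27ac"])
    marks <- sort(c("H3K4me3", "H3K27me3", "H3K27ac")[on])
    want <- if (!length(marks)) "none"
      else if (identical(marks, c("H3K27me3", "H3K4me3"))) "bivalent"
      else if (identical(marks, c("H3K27ac", "H3K27me3"))) "conflict"
      else if (identical(marks, c("H3K27ac", "H3K4me3"))) "co_active"
      else paste(marks, collapse = "+")
    expect_equal(unname(tr$labels[r, 1]), want)
  }
  expect_error(chromatin_state_track(list(H3K4me3 = k4 * 0, H3K27me3 = me3 * 0,
                                          H3K27ac = ac * 0)), "eligible")
})

test_that("spline smoothing preserves constants and linear trends, removes noise", {
  B <- 20
  const <- matrix(3, 1, B)
  expect_equal(smooth_profile(const), const)
  lin <- matrix(seq(0, 1, length.out = B), 1)
  expect_equal(smooth_profile(lin), lin, tolerance = 1e-6)
  withr::with_seed(52, {
    signal <- sin(seq(0, pi, length.out = B))
    noisy <- matrix(rep(signal, 30), 30, B, byrow = TRUE) +
      matrix(rnorm(30 * B, sd = 0.3), 30, B)
  })
  sm <- smooth_profile(noisy)
  resid_sm <- sweep(sm, 2, signal)
  resid_in <- sweep(noisy, 2, signal)
  expect_lt(mean(resid_sm^2), mean(resid_in^2))
  expect_error(smooth_profile(matrix(1:6, 1)), "B >= 8")
})

test_that("DTW distance matches its defining recursion", {
  withr::with_seed(53, {
    for (rep in 1:20) {
      a <- matrix(rnorm(4 * 50), 4)
      b <- matrix(rnorm(4 * 50), 4)
      cost <- matrix(0, 50, 50)
      for (j in 1:50) cost[, j] <- sqrt(colSums((a - b[, j])^2))
      expect_equal(dtw_distance(a, b), naive_dtw(cost), tolerance = 1e-12)
    }
  })
  a <- matrix(rnorm(4 * 30), 4)
  expect_identical(dtw_distance(a, a), 0)
  # single-bin series: plain Euclidean distance of the stacked vectors
  u <- matrix(c(1, 2, 3), 3, 1); v <- matrix(c(2, 2, 5), 3, 1)
  expect_equal(dtw_distance(u, v), sqrt(sum((u - v)^2)))
  expect_error(dtw_distance(matrix(0, 2, 5), matrix(0, 2, 6)), "share")
})

test_that("DTW distance matrices are symmetric and cluster planted groups exactly", {
  withr::with_seed(54, {
    up <- lapply(1:6, function(i) matrix(seq(0, 1, length.out = 30) +
                                           rnorm(30, sd = 0.02), 1))
    down <- lapply(1:6, function(i) matrix(seq(1, 0, length.out = 30) +
                                             rnorm(30, sd = 0.02), 1))
  })
  profs <- c(up, down)
  names(profs) <- paste0("g", 1:12)
  D <- dtw_distance_matrix(profs)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  cl <- cluster_profiles_dtw(D, k = 2, seed = 1)
  expect_equal(length(unique(cl$cluster[1:6])), 1L)
  expect_equal(length(unique(cl$cluster[7:12])), 1L)
  expect_false(cl$cluster[1] == cl$cluster[7])
  # permutation invariance up to relabeling
  perm <- withr::with_seed(55, sample(12))
  cl2 <- cluster_profiles_dtw(D[perm, perm], k = 2, seed = 1)
  joined <- dplyr::inner_join(cl, cl2, by = "feature")
  expect_equal(sum(table(joined$cluster.x, joined$cluster.y) > 0), 2L)
  expect_error(cluster_profiles_dtw(D, k = 12), "smaller")
})

test_that("first divergent bin finds a step and ignores flat profiles", {
  withr::with_seed(56, {
    bins <- rep(1:10, each = 200)
    step <- rbinom(2000, 1, ifelse(bins >= 5, 0.8, 0.05))
    flat <- rbinom(2000, 1, 0.3)
    Y <- cbind(step = step, flat = flat)
    rownames(Y) <- paste0("c", 1:2000)
  })
  fd <- first_divergent_bin(Y, bins)
  expect_equal(fd$first_divergent_bin[fd$feature == "step"], 5)
  expect_true(is.na(fd$first_divergent_bin[fd$feature == "flat"]))

  # tightening the fold-change threshold can never give an earlier bin
  fd_tight <- first_divergent_bin(Y, bins, lfc_threshold = 2)
  both <- !is.na(fd$first_divergent_bin) & !is.na(fd_tight$first_divergent_bin)
  expect_true(all(fd_tight$first_divergent_bin[both] >=
                    fd$first_divergent_bin[both]))

  # decreasing direction for repressive marks
  withr::with_seed(57, {
    drop_ <- rbinom(2000, 1, ifelse(bins >= 6, 0.05, 0.6))
  })
  fd_dec <- first_divergent_bin(cbind(drop_ = drop_), bins,
                                direction = "decrease")
  expect_equal(fd_dec$first_divergent_bin, 6)
  expect_error(first_divergent_bin(Y, bins, baseline_bin = 99), "empty")
})

test_that("pseudotime lags subtract chromatin from RNA divergence bins", {
  rna <- tibble::tibble(feature = c("g1", "g2", "g3"),
                        first_divergent_bin = c(6L, 4L, NA))
  chrom <- tibble::tibble(feature = c("g1", "g2", "g3"),
                          first_divergent_bin = c(3L, 4L, 5L))
  lags <- pseudotime_lag(rna, list(H3K27ac = chrom))
  expect_equal(lags$lag, c(3L, 0L, NA))
  expect_equal(unique(lags$modality), "H3K27ac")
})

test_that("network edges are annotated with per-bin mark states", {
  det <- list(
    H3K27me3 = matrix(c(0.3, 0.02), 1, 2, dimnames = list("r1", NULL)),
    H3K27ac = matrix(c(0.02, 0.3), 1, 2, dimnames = list("r1", NULL)),
    H3K4me3 = matrix(c(0.02, 0.02), 1, 2, dimnames = list("r1", NULL)))
  edges <- tibble::tibble(factor = "TF1", target = "G1", region_id = "r1")
  ann <- annotate_network_edges(edges, det)
  expect_equal(ann$state, c("H3K27me3", "H3K27ac"))  # repressed -> active
  edges2 <- dplyr::bind_rows(edges,
                             tibble::tibble(factor = "TF2", target = "G2",
                                            region_id = "missing"))
  expect_warning(ann2 <- annotate_network_edges(edges2, det), "unresolvable")
  expect_equal(nrow(ann2), 2L)
  # all-below-threshold regions are "none"
  det_lo <- lapply(det, function(m) m * 0 + 0.01)
  expect_equal(unique(annotate_network_edges(edges, det_lo)$state), "none")
})
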