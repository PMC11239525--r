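test_that("binarize thresholds counts at zero and column sums count detections", {
  m <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 1, 2), x = c(3, 1, 7),
                            dims = c(3, 2))
  b <- binarize(m)
  expect_equal(as.vector(b[1, 1]), 1)
  expect_equal(as.vector(b[1, 2]), 0)
  expect_equal(unname(Matrix::colSums(b)), c(2, 1))
})

test_that("differential peaks recover an overwhelming group effect", {
  withr::with_seed(40, {
    n <- 400
    grp <- rep(c("A", "B"), each = n / 2)
    nf <- exp(rnorm(n, log(500), 0.2))
    strong <- rbinom(n, 1, ifelse(grp == "A", 0.9, 0.0))
    flat <- rbinom(n, 1, 0.3)
    Y <- Matrix::Matrix(cbind(strong = strong, flat = flat), sparse = TRUE)
    rownames(Y) <- paste0("c", 1:n)
  })
  res <- differential_peaks(Y, grp, nf)
  strong_a <- res[res$peak_id == "strong" & res$group == "A", ]
  expect_lt(strong_a$fdr, 1e-6)
  expect_gt(strong_a$effect, 0)
  expect_gt(strong_a$detection_lfc, 1)
  # the flat peak is not significant
  expect_gt(min(res$p[res$peak_id == "flat"]), 0.01)
})

test_that("degenerate peaks are reported with p = 1, not dropped", {
  Y <- Matrix::Matrix(cbind(allzero = rep(0, 40), allone = rep(1, 40),
                            ok = rep(c(0, 1), 20)), sparse = TRUE)
  res <- differential_peaks(Y, rep(c("A", "B"), each = 20), rep(100, 40))
  expect_true(all(res$degenerate[res$peak_id %in% c("allzero", "allone")]))
  expect_equal(unique(res$p[res$peak_id == "allzero"]), 1)
  expect_setequal(unique(res$peak_id), c("allzero", "allone", "ok"))
})

test_that("detection rates equal group-by means", {
  withr::with_seed(41, {
    Y <- Matrix::Matrix(matrix(rbinom(200, 1, 0.4), 20, 10), sparse = TRUE)
    rownames(Y) <- paste0("c", 1:20)
    colnames(Y) <- paste0("p", 1:10)
  })
  cl <- tibble::tibble(cell_id = rownames(Y), cluster = rep(0:3, each = 5))
  r <- detection_rates(Y, cl)
  for (k in 0:3) {
    expect_equal(r[as.character(k), ],
                 colMeans(as.matrix(Y)[cl$cluster == k, ]))
  }
  # 4 cells, 1 detected -> 0.25
  Y2 <- Matrix::Matrix(matrix(c(1, 0, 0, 0), 4, 1), sparse = TRUE)
  rownames(Y2) <- paste0("c", 1:4)
  expect_equal(unname(detection_rates(Y2, rep(0, 4))[1, 1]), 0.25)
  expect_true(all(r >= 0 & r <= 1))
})

# hand-built fixture for the callers: 2 branch groups, clusters ne1/ne2/b1/b2
caller_fixture <- function() {
  k4_peaks <- tibble::tibble(
    chrom = "chr1", start = c(1000L, 20000L, 40000L),
    end = c(1500L, 20500L, 40500L))
  k4_peaks$peak_id <- peak_id(k4_peaks$chrom, k4_peaks$start, k4_peaks$end)
  me3_peaks <- k4_peaks  # same intervals in the repressive modality
  rates <- function(vals) {
    m <- matrix(vals, 4, 3, byrow = FALSE,
                dimnames = list(c("ne1", "ne2", "b1", "b2"), k4_peaks$peak_id))
    m
  }
  # peak 1: true bivalent, resolves in branch A (k4 up, me3 down)
  # peak 2: me3 below 5% in NE -> excluded
  # peak 3: both high in NE but no differential -> not called
  k4_rates <- rates(c(0.30, 0.25, 0.50, 0.05,
                      0.30, 0.30, 0.40, 0.05,
                      0.30, 0.30, 0.30, 0.30))
  me3_rates <- rates(c(0.30, 0.25, 0.05, 0.50,
                       0.04, 0.04, 0.30, 0.05,
                       0.30, 0.30, 0.30, 0.30))
  diff_tbl <- function(effects, lfcs, fdrs) {
    tibble::tibble(
      peak_id = rep(k4_peaks$peak_id, each = 2),
      group = rep(c("brA", "brB"), 3),
      effect = effects, detection_lfc = lfcs, p = fdrs, fdr = fdrs,
      degenerate = FALSE)
  }
  k4_diff <- diff_tbl(c(2, -2, 1.5, -1.5, 0.1, -0.1),
                      c(1.5, -1.5, 1.2, -1.2, 0.05, -0.05),
                      c(1e-10, 1e-10, 1e-8, 1e-8, 0.9, 0.9))
  me3_diff <- diff_tbl(c(-2, 2, -1.5, 1.5, 0.1, -0.1),
                       c(-1.5, 1.5, -1.2, 1.2, 0.05, -0.05),
                       c(1e-10, 1e-10, 1e-8, 1e-8, 0.9, 0.9))
  list(k4_peaks = k4_peaks, me3_peaks = me3_peaks, k4_rates = k4_rates,
       me3_rates = me3_rates, k4_diff = k4_diff, me3_diff = me3_diff)
}

test_that("bivalent calls require NE detection of both marks and opposite effects", {
  fx <- caller_fixture()
  calls <- call_bivalent(fx$k4_peaks, fx$me3_peaks, fx$k4_rates, fx$me3_rates,
                         fx$k4_diff, fx$me3_diff,
                         stage_clusters = c("ne1", "ne2"))
  expect_equal(unique(calls$k4_peak_id), fx$k4_peaks$peak_id[1])
  # branch A resolves by activation, branch B by repression
  expect_equal(calls$class[calls$branch == "brA"], "activated")
  expect_equal(calls$class[calls$branch == "brB"], "repressed")
  expect_error(call_bivalent(fx$k4_peaks, fx$me3_peaks, fx$k4_rates,
                             fx$me3_rates, fx$k4_diff, fx$me3_diff,
                             stage_clusters = character()), "empty")
})

test_that("switching calls enforce the exactly-one-mark rule and direction", {
  me3_peaks <- tibble::tibble(chrom = "chr1", start = c(1000L, 20000L),
                              end = c(1500L, 20500L))
  me3_peaks$peak_id <- peak_id(me3_peaks$chrom, me3_peaks$start, me3_peaks$end)
  ac_peaks <- me3_peaks
  mk <- function(vals) matrix(vals, 3, 2, dimnames = list(c("ne", "b1", "b2"),
                                                          me3_peaks$peak_id))
  # peak 1: me3 in NE, K27ac gained in branch A with me3 depleted -> switch
  # peak 2: both marks NE-detected -> bivalency territory, excluded
  me3_rates <- mk(c(0.40, 0.03, 0.40,
                    0.30, 0.30, 0.30))
  ac_rates <- mk(c(0.02, 0.45, 0.02,
                   0.30, 0.30, 0.30))
  dtb <- function(peak, eff, lfc, fdr) {
    tibble::tibble(peak_id = rep(me3_peaks$peak_id, each = 2),
                   group = rep(c("brA", "brB"), 2),
                   effect = eff, detection_lfc = lfc, p = fdr, fdr = fdr,
                   degenerate = FALSE)
  }
  me3_diff <- dtb(NULL, c(-2, 2, 0.1, -0.1), c(-1.5, 1.5, 0.01, -0.01),
                  c(1e-9, 1e-9, 0.8, 0.8))
  ac_diff <- dtb(NULL, c(2, -2, 0.1, -0.1), c(1.5, -1.5, 0.01, -0.01),
                 c(1e-9, 1e-9, 0.8, 0.8))
  calls <- call_switching(me3_peaks, ac_peaks, me3_rates, ac_rates,
                          me3_diff, ac_diff, stage_clusters = "ne")
  expect_equal(unique(calls$me3_peak_id), me3_peaks$peak_id[1])
  expect_equal(unique(calls$direction), "activating")
  expect_equal(unique(calls$branch), "brA")
})

test_that("bivalent and switching calls are disjoint on the same peak pair", {
  # a pair detected in NE in both marks can be bivalent but never switching;
  # a pair with exactly one NE mark can switch but never be bivalent
  fx <- caller_fixture()
  biv <- call_bivalent(fx$k4_peaks, fx$me3_peaks, fx$k4_rates, fx$me3_rates,
                       fx$k4_diff, fx$me3_diff, c("ne1", "ne2"))
  sw <- call_switching(fx$me3_peaks, fx$k4_peaks, fx$me3_rates, fx$k4_rates,
                       fx$me3_diff, fx$k4_diff, c("ne1", "ne2"))
  both <- intersect(unique(biv$me3_peak_id), unique(sw$me3_peak_id))
  expect_length(both, 0)
})

test_that("locus classification applies the 2 kb / 3 kb rules", {
  genes <- gene_models(tibble::tibble(gene_id = "g1", chrom = "chr1",
                                      start = 10000L, end = 15000L,
                                      strand = "+"))
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(9000L, 19500L, 16500L, 2000L),
    end = c(9100L, 19600L, 16600L, 2100L))
  peaks$peak_id <- peak_id(peaks$chrom, peaks$start, peaks$end)
  got <- classify_locus(peaks, genes)
  # 900 bp from the TSS -> promoter; 4.5 kb from the body -> distal;
  # 1.5 kb from the body but 6.5 kb from the TSS -> other; far -> distal
  expect_equal(got$locus_class, c("promoter", "distal", "other", "distal"))
})

test_that("region embedding filters follow the cluster-breadth and max-rate rules", {
  withr::with_seed(42, {
    n_cl <- 60
    # peak A: broad (rate 0.2 in 55 clusters); peak B: broad but weak (0.08);
    # peak C: narrow (40 clusters); plus filler peaks to stabilize the PCA
    mk_rate <- function(broad_n, level) {
      r <- rep(0, n_cl)
      r[seq_len(broad_n)] <- level
      r + runif(n_cl, 0, 0.02)
    }
    rates <- cbind(
      A = mk_rate(55, 0.2), B = mk_rate(55, 0.08), C = mk_rate(40, 0.2),
      sapply(1:12, function(i) mk_rate(sample(51:60, 1), runif(1, 0.15, 0.4))))
  })
  colnames(rates)[4:15] <- paste0("F", 1:12)
  peaks <- tibble::tibble(chrom = "chr1",
                          start = seq(0, by = 10000L, length.out = 15),
                          end = seq(500L, by = 10000L, length.out = 15))
  peaks$peak_id <- colnames(rates)
  rownames(rates) <- paste0("cl", seq_len(60))
  rem <- region_embedding_build(list(H3K27ac = rates), list(H3K27ac = peaks),
                                min_clusters = 50, min_rate = 0.10,
                                n_pcs = 5, knn_k = 5, seed = 1)
  kept_peaks <- rem$member_peaks$peak_id
  expect_true("A" %in% kept_peaks)
  expect_false("B" %in% kept_peaks)  # never above 10%
  expect_false("C" %in% kept_peaks)  # too few clusters
  expect_equal(unique(rem$regions$class), "H3K27ac")
})

test_that("region classes record the contributing marks", {
  rates1 <- matrix(0.3, 60, 1, dimnames = list(paste0("cl", 1:60), "X"))
  peaks1 <- tibble::tibble(chrom = "chr1", start = 0L, end = 500L, peak_id = "X")
  rates2 <- matrix(0.3, 60, 1, dimnames = list(paste0("cl", 1:60), "Y"))
  peaks2 <- tibble::tibble(chrom = "chr1", start = 100L, end = 600L, peak_id = "Y")
  # overlapping peaks from two marks merge into one bivalent-class region;
  # clustering needs more observations than neighbors, so replicate regions
  rates1b <- cbind(rates1, matrix(runif(60 * 8, 0.11, 0.4), 60,
                                  dimnames = list(NULL, paste0("Z", 1:8))))
  peaks1b <- dplyr::bind_rows(peaks1, tibble::tibble(
    chrom = "chr2", start = seq(0L, by = 10000L, length.out = 8),
    end = seq(500L, by = 10000L, length.out = 8), peak_id = paste0("Z", 1:8)))
  rem <- region_embedding_build(
    list(H3K4me3 = rates1b, H3K27me3 = rates2),
    list(H3K4me3 = peaks1b, H3K27me3 = peaks2),
    min_clusters = 50, min_rate = 0.10, n_pcs = 3, knn_k = 3, seed = 1)
  merged <- rem$regions$class[rem$regions$chrom == "chr1"]
  expect_equal(merged, "H3K27me3+H3K4me3")
})

test_that("the regulatory census yields the four-way classification", {
  act <- list(rna = c(g1 = 0.4, g2 = 0.3, g3 = 0.01, g4 = 0.02))
  rep_ <- list(me3 = c(g1 = 0.3, g2 = 0.01, g3 = 0.4, g4 = 0.01))
  cen <- gene_regulatory_census(act, rep_)
  expect_equal(cen$class,
               c("active_and_repressed", "always_active",
                 "always_repressed", "inactive_unmarked"))
})

test_that("bulk peak fold changes reduce to the closed form", {
  intensity <- matrix(c(10, 10, 40, 10, 20, 20), 2,
                      dimnames = list(c("pk1", "pk2"),
                                      c("ctrl", "trt1", "trt2")))
  design <- tibble::tibble(sample = c("ctrl", "trt1", "trt2"),
                           condition = c("control", "treated", "treated"),
                           concentration = c(NA, 1, 1))
  lfc <- bulk_peak_lfc(intensity, design, pseudocount = 0)
  # pk1: mean(log2(40/10), log2(20/10)) = 1.5; pk2: mean(0, 1) = 0.5
  expect_equal(lfc$lfc[lfc$peak_id == "pk1"], 1.5)
  expect_equal(lfc$lfc[lfc$peak_id == "pk2"], 0.5)
  # treated == control -> 0
  i2 <- matrix(c(7, 7), 1, 2, dimnames = list("pk", c("a", "b")))
  d2 <- tibble::tibble(sample = c("a", "b"),
                       condition = c("control", "treated"),
                       concentration = c(1, 1))
  expect_equal(bulk_peak_lfc(i2, d2)$lfc, 0)
  expect_error(bulk_peak_lfc(i2, dplyr::mutate(d2, condition = "treated")),
               "control")
})
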