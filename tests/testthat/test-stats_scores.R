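test_that("module scores are centered under exchangeable gene sets", {
  withr::with_seed(60, {
    act <- matrix(rexp(1000 * 200, 1), 1000, 200,
                  dimnames = list(paste0("c", 1:1000), paste0("g", 1:200)))
  })
  # whole-universe gene set is its own background
  sc <- module_score(act, colnames(act), seed = 1)
  expect_lt(abs(mean(sc$score)), 0.02)
  # mean over random sets stays near zero
  means <- withr::with_seed(61, vapply(1:20, function(i) {
    set <- sample(colnames(act), 20)
    mean(module_score(act, set, seed = i)$score)
  }, 1))
  expect_lt(abs(mean(means)), 0.02)
  # identical seeds give identical scores
  expect_identical(module_score(act, colnames(act)[1:10], seed = 3)$score,
                   module_score(act, colnames(act)[1:10], seed = 3)$score)
  expect_error(module_score(act, "g1"), "smaller than 2|>= 2")
})

test_that("a planted per-cell activity shift of a gene set is recovered", {
  # the score is background-matched on gene averages, so a shift present in a
  # subset of cells (leaving averages near their base levels) is what the
  # statistic is built to detect
  withr::with_seed(62, {
    base <- runif(150, 3, 7)
    act <- matrix(rnorm(800 * 150), 800, 150,
                  dimnames = list(paste0("c", 1:800), paste0("g", 1:150))) +
      matrix(base, 800, 150, byrow = TRUE)
    set <- paste0("g", 1:15)
    delta <- 0.7
    hot <- 1:240  # 30% of cells carry the signal
    act[hot, set] <- act[hot, set] + delta
  })
  sc <- module_score(act, set, seed = 2)
  gap <- mean(sc$score[hot]) - mean(sc$score[-hot])
  expect_lt(abs(gap - delta), 0.1)
})

test_that("bivalency scores are z-score differences over clusters", {
  k4 <- c(a = 1, b = 2, c = 3, d = 4)
  me3 <- c(a = 1, b = 2, c = 3, d = 4)
  bs <- bivalency_score(k4, me3)
  expect_equal(bs$bivalency_score, rep(0, 4))
  # direct recomputation on a random fixture
  withr::with_seed(63, {
    x <- rnorm(8); y <- rnorm(8)
  })
  names(x) <- names(y) <- paste0("cl", 1:8)
  bs2 <- bivalency_score(x, y)
  expect_equal(bs2$bivalency_score,
               as.numeric(scale(x)) - as.numeric(scale(y)), tolerance = 1e-12)
  expect_error(bivalency_score(c(a = 1, b = 2), c(a = 1, b = 2)), ">= 3")
})

test_that("variance partitioning reproduces closed-form R-squared", {
  # 3 clusters per region, 2 regions; hand-computable fixture
  region <- c("X", "X", "X", "Y", "Y", "Y")
  pt <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  # feature 1: pure region effect; feature 2: constant
  cm <- rbind(f_region = c(1, 1, 1, 5, 5, 5),
              f_const = rep(2, 6))
  vp <- regional_variance(cm, region, pt)
  expect_equal(vp$r2_region[1], 1, tolerance = 1e-12)
  expect_equal(vp$r2_both[1], 1, tolerance = 1e-12)
  expect_equal(unlist(vp[2, c("r2_region", "r2_pseudotime", "r2_both")]),
               c(r2_region = 0, r2_pseudotime = 0, r2_both = 0))
  # hand computation for a mixed feature against lm()
  y <- c(1.2, 0.8, 1.5, 3.9, 4.2, 4.4)
  vp2 <- regional_variance(rbind(y = y), region, pt)
  expect_equal(vp2$r2_region, summary(lm(y ~ factor(region)))$r.squared)
  expect_equal(vp2$r2_pseudotime, summary(lm(y ~ pt))$r.squared)
  expect_equal(vp2$r2_both, summary(lm(y ~ pt + factor(region)))$r.squared)
})

test_that("the joint model never explains less than either single model", {
  withr::with_seed(64, {
    cm <- matrix(rnorm(30 * 12), 30, 12)
    region <- sample(c("p", "q", "r"), 12, TRUE)
    pt <- runif(12)
  })
  region[1:3] <- c("p", "q", "r")  # ensure all levels present
  vp <- regional_variance(cm, region, pt)
  expect_true(all(vp$r2_both >= pmax(vp$r2_region, vp$r2_pseudotime) - 1e-9))
  expect_true(all(vp$r2_both <= 1 & vp$r2_both >= 0))
})

test_that("the CMH test reduces to the single-stratum 2x2 test", {
  withr::with_seed(65, {
    n <- 400
    cluster <- sample(c("k0", "k1"), n, TRUE, prob = c(0.3, 0.7))
    treated <- sample(c("treated", "control"), n, TRUE)
    strata <- rep("t1", n)
  })
  res <- cmh_composition(cluster, treated, strata)
  k0 <- res[res$cluster == "k0", ]
  tab <- table(cluster == "k0", treated)[2:1, 2:1]
  or_plain <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_equal(k0$odds_ratio, unname(or_plain), tolerance = 1e-10)
  # the single-stratum MH statistic is the (N-1)/N-scaled Pearson chi-square
  x2 <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  want_p <- pchisq((n - 1) / n * unname(x2), df = 1, lower.tail = FALSE)
  expect_equal(k0$p, want_p, tolerance = 1e-8)
})

test_that("the MH common odds ratio matches the textbook formula across strata", {
  # classic stratified 2x2xK fixture, recomputed by sum(ad/n)/sum(bc/n)
  a <- c(12, 30); b <- c(18, 10); c_ <- c(8, 20); d <- c(22, 40)
  cluster <- c(); cond <- c(); strata <- c()
  for (k in 1:2) {
    cluster <- c(cluster, rep(c("in", "out", "in", "out"),
                              c(a[k], b[k], c_[k], d[k])))
    cond <- c(cond, rep(c("treated", "treated", "control", "control"),
                        c(a[k], b[k], c_[k], d[k])))
    strata <- c(strata, rep(paste0("t", k), a[k] + b[k] + c_[k] + d[k]))
  }
  res <- cmh_composition(cluster, cond, strata)
  n_k <- a + b + c_ + d
  or_mh <- sum(a * d / n_k) / sum(b * c_ / n_k)
  expect_equal(res$odds_ratio[res$cluster == "in"], or_mh, tolerance = 1e-10)
  # cross-check p against the standard implementation
  tab <- array(0, c(2, 2, 2))
  for (k in 1:2) tab[, , k] <- matrix(c(a[k], c_[k], b[k], d[k]), 2)
  want <- mantelhaen.test(tab, correct = FALSE)
  expect_equal(res$p[res$cluster == "in"], want$p.value, tolerance = 1e-8)
})

test_that("CMH on identical per-stratum tables equals the pooled single-stratum test", {
  a <- 15; b <- 25; c_ <- 10; d <- 30
  one <- rep(c("in", "out", "in", "out"), c(a, b, c_, d))
  cond1 <- rep(c("treated", "treated", "control", "control"), c(a, b, c_, d))
  res_pooled <- cmh_composition(c(one, one), c(cond1, cond1),
                                rep("t1", 2 * length(one)))
  res_strat <- cmh_composition(c(one, one), c(cond1, cond1),
                               rep(c("t1", "t2"), each = length(one)))
  expect_equal(res_strat$odds_ratio, res_pooled$odds_ratio, tolerance = 1e-10)
})

test_that("a flat 2x2 table gives OR 1 and p near 1", {
  cluster <- rep(c("in", "out", "in", "out"), each = 10)
  cond <- rep(c("treated", "treated", "control", "control"), each = 10)
  res <- cmh_composition(cluster, cond, rep("t1", 40))
  expect_equal(res$odds_ratio[res$cluster == "in"], 1)
  expect_gt(res$p[res$cluster == "in"], 0.9)
})

test_that("logistic DE recovers a planted detection shift and stays calibrated", {
  withr::with_seed(66, {
    n <- 800
    treated <- rep(c(TRUE, FALSE), each = n / 2)
    covar <- data.frame(n_umi = rnorm(n))
    planted <- rbinom(n, 1, ifelse(treated, 0.5, 0.25))
    nulls <- matrix(rbinom(n * 60, 1, 0.3), n, 60)
    Y <- cbind(planted = planted, nulls)
    colnames(Y) <- c("planted", paste0("null", 1:60))
    rownames(Y) <- paste0("c", 1:n)
  })
  res <- de_logistic(Y, treated, covar)
  expect_true(res$significant[res$gene_id == "planted"])
  expect_gt(res$detection_lfc[res$gene_id == "planted"], 0.5)
  # effect direction agrees with the raw rate difference for significant genes
  sig <- res[res$significant, ]
  if (nrow(sig)) expect_true(all(sign(sig$coef) == sign(sig$detection_lfc)))
  # null genes essentially never pass FDR < 0.01
  expect_lt(mean(res$significant[res$gene_id != "planted"]), 0.05)
})

test_that("separated genes fall back to a penalized fit instead of failing", {
  treated <- rep(c(TRUE, FALSE), each = 30)
  Y <- cbind(sep = as.numeric(treated))  # perfectly predicts the condition
  rownames(Y) <- paste0("c", 1:60)
  res <- de_logistic(Y, treated)
  expect_true(res$separated)
  expect_true(is.finite(res$p))
  expect_lt(res$p, 0.01)
})

test_that("motif enrichment matches the hypergeometric oracle", {
  withr::with_seed(67, {
    occ <- matrix(rbinom(20 * 4, 1, 0.4), 20, 4,
                  dimnames = list(paste0("pk", 1:20), paste0("m", 1:4)))
  })
  fg <- paste0("pk", 1:8)
  bg <- paste0("pk", 9:20)
  res <- motif_enrichment(fg, bg, occ)
  for (m in res$motif) {
    fh <- sum(occ[fg, m]); bh <- sum(occ[bg, m])
    want <- fisher.test(matrix(c(fh, 8 - fh, bh, 12 - bh), 2))$p.value
    expect_equal(res$p[res$motif == m], want, tolerance = 1e-12)
    # two-sided Fisher equals summed hypergeometric tail probabilities
    probs <- dhyper(0:8, fh + bh, 20 - fh - bh, 8)
    expect_equal(want, sum(probs[probs <= dhyper(fh, fh + bh, 20 - fh - bh, 8) *
                                   (1 + 1e-7)]), tolerance = 1e-9)
  }
  # extreme table: all foreground, no background
  occ2 <- cbind(hot = c(rep(1, 8), rep(0, 12)))
  rownames(occ2) <- paste0("pk", 1:20)
  r2 <- motif_enrichment(fg, bg, occ2)
  expect_true(is.finite(r2$odds_ratio))
  expect_lt(r2$p, 1e-4)
  # identical frequencies: p = 1
  occ3 <- cbind(flat = rep(c(1, 0), 10))
  rownames(occ3) <- paste0("pk", 1:20)
  fg3 <- paste0("pk", c(1, 2, 3, 4)); bg3 <- paste0("pk", c(5, 6, 7, 8))
  expect_equal(motif_enrichment(fg3, bg3, occ3)$p, 1)
  # absent motifs are skipped
  occ4 <- cbind(absent = rep(0, 20), hot = occ2[, 1])
  rownames(occ4) <- paste0("pk", 1:20)
  expect_false("absent" %in% motif_enrichment(fg, bg, occ4)$motif)
})

test_that("perturbation-region selection enforces the DE, depletion and window rules", {
  genes <- gene_models(tibble::tibble(
    gene_id = c("hit", "weak"), chrom = "chr1",
    start = c(100000L, 500000L), end = c(105000L, 505000L),
    strand = c("+", "+")))
  de <- tibble::tibble(gene_id = c("hit", "weak"),
                       fdr = c(1e-6, 1e-2), detection_lfc = c(2, 2))
  # gap to the gene body at 100,000: peak 1 ends at 90,001 (9,999 bp away),
  # peak 2 at 90,000 (exactly 10,000 bp, excluded by the strict window)
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(89901L, 89900L, 95000L, 489901L),
    end = c(90001L, 90000L, 95100L, 490001L))
  peaks$peak_id <- peak_id(peaks$chrom, peaks$start, peaks$end)
  lfc <- tibble::tibble(peak_id = peaks$peak_id, lfc = c(-2, -2, -0.5, -2))
  sel <- select_perturbation_regions(de, lfc, peaks, genes)
  # peak 1: 9,999 bp from the gene body -> selected
  expect_true(peaks$peak_id[1] %in% sel)
  # peak 2: 10,001 bp away -> outside the strict < 10 kb window
  expect_false(peaks$peak_id[2] %in% sel)
  # peak 3: close but lfc -0.5 -> not depleted
  expect_false(peaks$peak_id[3] %in% sel)
  # peak 4: near a gene that fails the DE filter
  expect_false(peaks$peak_id[4] %in% sel)
})
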