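#' Module score with binned background matching
#'
#' The score of a gene set in each cell is the mean value over the set minus
#' the mean over a matched control set: genes are stratified into
#' `n_bins` bins of average activity, and each set gene draws `n_ctrl`
#' control genes from its own bin (excluding the set itself, unless a bin
#' holds nothing else), so depth and expression-level structure cancel in
#' expectation.
#'
#' @param activity Cells-by-genes matrix (log-normalized activity or
#'   expression).
#' @param gene_set Character vector of gene ids (>= 2, subset of columns).
#' @param n_bins Number of average-activity bins (default 24).
#' @param n_ctrl Control genes drawn per set gene (default 100).
#' @param seed Seed for the control draw.
#' @return Tibble `cell_id`, `score`.
#' @export
module_score <- function(activity, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 1L) {
  stopifnot(length(gene_set) >= 2, all(gene_set %in% colnames(activity)))
  avg <- Matrix::colMeans(activity)
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- colnames(activity)
  ctrl_genes <- withr::with_seed(as.integer(seed), {
    unlist(lapply(gene_set, function(g) {
      pool <- setdiff(names(bin)[bin == bin[[g]]], gene_set)
      if (!length(pool)) pool <- names(bin)[bin == bin[[g]]]
      sample(pool, min(n_ctrl, length(pool)), replace = length(pool) < n_ctrl)
    }))
  })
  set_mean <- Matrix::rowMeans(activity[, gene_set, drop = FALSE])
  ctrl_mean <- Matrix::rowMeans(activity[, ctrl_genes, drop = FALSE])
  tibble::tibble(
    cell_id = rownames(activity) %||% as.character(seq_len(nrow(activity))),
    score = as.numeric(set_mean - ctrl_mean)
  )
}

#' Bivalency score per cluster
#'
#' `zscore(activation score) - zscore(repression score)` over clusters:
#' values near 0 indicate bivalency, positive values activation dominance
#' (H3K4me3), negative values repression dominance (H3K27me3).
#'
#' @param k4_scores,me3_scores Named numeric vectors of per-cluster module
#'   scores over the same cluster universe (>= 3 clusters).
#' @return Tibble `cluster`, `activation_z`, `repression_z`,
#'   `bivalency_score`.
#' @export
bivalency_score <- function(k4_scores, me3_scores) {
  stopifnot(length(k4_scores) >= 3,
            identical(names(k4_scores), names(me3_scores)))
  za <- as.numeric(scale(k4_scores))
  zr <- as.numeric(scale(me3_scores))
  tibble::tibble(
    cluster = names(k4_scores) %||% as.character(seq_along(k4_scores)),
    activation_z = za, repression_z = zr,
    bivalency_score = za - zr
  )
}

# R^2 of OLS fit of each response column on a design matrix
.r2_multi <- function(X, Y) {
  qr_x <- qr(X)
  fitted <- qr.fitted(qr_x, Y)
  tss <- colSums(scale(Y, scale = FALSE)^2)
  rss <- colSums((Y - fitted)^2)
  r2 <- 1 - rss / tss
  r2[tss < 1e-12] <- 0  # constant features carry no variance to explain
  pmin(pmax(r2, 0), 1)
}

#' Variance partitioning between region and pseudotime
#'
#' Fits three Gaussian linear models per feature on cluster-level means —
#' region factor alone, pseudotime alone, and both — and reports each
#' model's R-squared as the fraction of variance explained.
#'
#' @param cluster_means Features-by-clusters matrix of mean expression or
#'   activity.
#' @param region Region label per cluster (>= 2 levels).
#' @param pt Numeric pseudotime per cluster.
#' @return Tibble `feature`, `r2_region`, `r2_pseudotime`, `r2_both`.
#' @export
regional_variance <- function(cluster_means, region, pt) {
  region <- factor(region)
  stopifnot(nlevels(region) >= 2, is.numeric(pt),
            length(region) == ncol(cluster_means),
            length(pt) == ncol(cluster_means))
  Y <- t(as.matrix(cluster_means))
  X_region <- stats::model.matrix(~region)
  X_pt <- stats::model.matrix(~pt)
  X_both <- stats::model.matrix(~pt + region)
  tibble::tibble(
    feature = rownames(cluster_means) %||% as.character(seq_len(nrow(cluster_means))),
    r2_region = unname(.r2_multi(X_region, Y)),
    r2_pseudotime = unname(.r2_multi(X_pt, Y)),
    r2_both = unname(.r2_multi(X_both, Y))
  )
}

# Mantel-Haenszel machinery on a 2x2xK array (a,b,c,d per stratum):
# common OR = sum(a*d/n) / sum(b*c/n); chi-square on sum(a) vs hypergeometric
.mh_test <- function(tab, correct_if_zero = TRUE) {
  a <- tab[1, 1, ]; b <- tab[1, 2, ]; c_ <- tab[2, 1, ]; d <- tab[2, 2, ]
  n <- a + b + c_ + d
  keep <- (a + b) > 0 & (c_ + d) > 0 & (a + c_) > 0 & (b + d) > 0
  dropped <- sum(!keep)
  a <- a[keep]; b <- b[keep]; c_ <- c_[keep]; d <- d[keep]; n <- n[keep]
  if (!length(a)) return(list(or = NA_real_, p = NA_real_, dropped = dropped))
  or <- sum(a * d / n) / sum(b * c_ / n)
  expect <- (a + b) * (a + c_) / n
  vars <- (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
  dev <- abs(sum(a) - sum(expect))
  cc <- if (correct_if_zero && any(tab == 0)) 0.5 else 0
  stat <- (max(dev - cc, 0))^2 / sum(vars)
  list(or = or, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       dropped = dropped)
}

#' Compositional Cochran-Mantel-Haenszel test per cluster
#'
#' For each cluster, tests whether membership (in-cluster versus rest)
#' associates with treatment, stratified by sampling timepoint: a 2x2xK
#' table per cluster, Mantel-Haenszel common odds ratio and two-sided
#' chi-square p (0.5 continuity correction applied when any cell is zero).
#' Strata with an empty margin are dropped from that cluster's test.
#' P-values are BH-corrected and flagged at the significance threshold.
#'
#' @param cluster Cluster label per cell.
#' @param condition Condition per cell (`"treated"` / `"control"`, or
#'   logical).
#' @param strata Stratum (timepoint) per cell.
#' @param threshold Significance threshold on the FDR (default 1e-4).
#' @return Tibble `cluster`, `odds_ratio`, `p`, `fdr`, `significant`,
#'   `strata_dropped`.
#' @export
cmh_composition <- function(cluster, condition, strata, threshold = 1e-4) {
  treated <- if (is.logical(condition)) condition else condition == "treated"
  if (!any(treated) || all(treated)) stop("need both conditions in >= 1 stratum")
  strata <- factor(strata)
  clusters <- sort(unique(cluster))
  res <- purrr::map_dfr(clusters, function(cl) {
    tab <- array(0, dim = c(2, 2, nlevels(strata)))
    for (k in seq_len(nlevels(strata))) {
      in_k <- strata == levels(strata)[k]
      tab[, , k] <- c(sum(cluster[in_k] == cl & treated[in_k]),
                      sum(cluster[in_k] != cl & treated[in_k]),
                      sum(cluster[in_k] == cl & !treated[in_k]),
                      sum(cluster[in_k] != cl & !treated[in_k]))
    }
    mh <- .mh_test(tab)
    tibble::tibble(cluster = cl, odds_ratio = mh$or, p = mh$p,
                   strata_dropped = mh$dropped)
  })
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$fdr) & res$fdr < threshold
  res[, c("cluster", "odds_ratio", "p", "fdr", "significant", "strata_dropped")]
}

# ridge-penalized logistic IRLS fallback for separated fits
.ridge_logit <- function(X, y, lambda = 1e-2, iter = 50L) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X)); pen[1, 1] <- 0
  for (i in seq_len(iter)) {
    eta <- X %*% beta
    mu <- 1 / (1 + exp(-eta))
    w <- as.vector(mu * (1 - mu)) + 1e-10
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w) + pen, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  mu <- 1 / (1 + exp(-X %*% beta))
  mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(coefficients = as.vector(beta), deviance = dev)
}

#' Logistic-regression differential expression (perturbation arm)
#'
#' Per gene, fits a logistic model of treatment membership on gene detection
#' plus nuisance covariates (`treatment ~ gene + n_umi + timepoint +
#' cluster`) and tests the gene term by likelihood ratio against the
#' covariate-only null. BH correction; a gene is significant at FDR < 0.01
#' and |log2 detection fold change| > 0.1. Perfect separation triggers a
#' ridge-penalized refit, flagged in the output.
#'
#' @param Y Binary cells-by-genes detection matrix (counts thresholded at
#'   > 0).
#' @param condition Treatment indicator per cell (logical or
#'   `"treated"`/`"control"`).
#' @param covariates Data frame of per-cell covariates (e.g. `n_umi`,
#'   `timepoint`, `cluster`); factors are expanded to dummies.
#' @param fdr_threshold,lfc_threshold Significance thresholds (0.01, 0.1).
#' @param pseudocount Pseudocount on detection rates (default 0.01).
#' @return Tibble `gene_id`, `coef`, `detection_lfc`, `p`, `fdr`,
#'   `significant`, `separated`.
#' @export
de_logistic <- function(Y, condition, covariates = NULL,
                        fdr_threshold = 0.01, lfc_threshold = 0.1,
                        pseudocount = 0.01) {
  treated <- if (is.logical(condition)) condition else condition == "treated"
  if (!any(treated) || all(treated)) stop("both conditions must be present")
  X_null <- if (is.null(covariates)) {
    matrix(1, nrow(Y), 1)
  } else {
    stats::model.matrix(~., data = as.data.frame(covariates))
  }
  genes <- colnames(Y) %||% as.character(seq_len(ncol(Y)))
  Y <- as.matrix(Y)
  y <- as.numeric(treated)
  fit_null <- suppressWarnings(stats::glm.fit(X_null, y,
                                              family = stats::binomial()))
  res <- purrr::map_dfr(seq_along(genes), function(g) {
    x <- Y[, g]
    X_full <- cbind(X_null, gene = x)
    fit <- suppressWarnings(stats::glm.fit(X_full, y,
                                           family = stats::binomial()))
    separated <- !fit$converged || abs(fit$coefficients[["gene"]]) > 15
    if (separated) {
      rf <- .ridge_logit(X_full, y)
      rn <- .ridge_logit(X_null, y)
      stat <- max(rn$deviance - rf$deviance, 0)
      coef <- rf$coefficients[length(rf$coefficients)]
    } else {
      stat <- max(fit_null$deviance - fit$deviance, 0)
      coef <- fit$coefficients[["gene"]]
    }
    rate_t <- mean(x[treated]); rate_c <- mean(x[!treated])
    tibble::tibble(
      gene_id = genes[g], coef = coef,
      detection_lfc = .detection_lfc(rate_t, rate_c, pseudocount),
      p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
      separated = separated
    )
  })
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < fdr_threshold &
    abs(res$detection_lfc) > lfc_threshold
  res
}

#' Transcription-factor motif enrichment (Fisher exact)
#'
#' Per motif, a two-sided Fisher exact test on foreground versus background
#' hit counts from a peak-by-motif occurrence table; BH correction with a
#' 0.05 threshold. Motifs absent everywhere are skipped. The reported odds
#' ratio uses a Haldane 0.5 correction so extreme tables stay finite.
#'
#' @param foreground,background Peak-id sets (background disjoint from the
#'   foreground, or a superset from which the foreground is removed).
#' @param occurrences Binary peaks-by-motifs matrix with peak-id rownames.
#' @param threshold FDR threshold for the `significant` flag (default 0.05).
#' @return Tibble `motif`, `fg_hit`, `fg_miss`, `bg_hit`, `bg_miss`,
#'   `odds_ratio`, `p`, `fdr`, `significant`.
#' @export
motif_enrichment <- function(foreground, background, occurrences,
                             threshold = 0.05) {
  stopifnot(all(foreground %in% rownames(occurrences)))
  background <- setdiff(background, foreground)
  stopifnot(all(background %in% rownames(occurrences)))
  fg <- occurrences[foreground, , drop = FALSE]
  bg <- occurrences[background, , drop = FALSE]
  motifs <- colnames(occurrences) %||% as.character(seq_len(ncol(occurrences)))
  res <- purrr::map_dfr(seq_along(motifs), function(m) {
    fh <- sum(fg[, m] > 0); bh <- sum(bg[, m] > 0)
    if (fh + bh == 0) return(tibble::tibble())
    fm <- nrow(fg) - fh; bm <- nrow(bg) - bh
    tab <- matrix(c(fh, fm, bh, bm), 2)
    tibble::tibble(
      motif = motifs[m], fg_hit = fh, fg_miss = fm, bg_hit = bh, bg_miss = bm,
      odds_ratio = ((fh + 0.5) * (bm + 0.5)) / ((fm + 0.5) * (bh + 0.5)),
      p = stats::fisher.test(tab)$p.value
    )
  })
  if (!nrow(res)) return(res)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < threshold
  res
}

#' Select perturbation-responsive regions for motif enrichment
#'
#' Peaks depleted upon treatment (log2 fold change < `peak_lfc_threshold`)
#' lying within `window` bp of genes passing the DE filter
#' (FDR < `de_fdr` and log2 fold change > `de_lfc`).
#'
#' @param de_table DE tibble with `gene_id`, `fdr`, and a fold-change column
#'   (`detection_lfc` or `lfc`).
#' @param peak_lfc Tibble `peak_id`, `lfc` (bulk perturbation fold changes).
#' @param peaks Peak interval tibble with `peak_id`.
#' @param genes Gene-model tibble.
#' @param window Distance window in bp (default 10,000; strict `<`).
#' @param de_fdr,de_lfc DE thresholds (1e-4, 1).
#' @param peak_lfc_threshold Depletion threshold (default -1).
#' @return Character vector of selected peak ids.
#' @export
select_perturbation_regions <- function(de_table, peak_lfc, peaks, genes,
                                        window = 10000L, de_fdr = 1e-4,
                                        de_lfc = 1, peak_lfc_threshold = -1) {
  lfc_col <- intersect(c("detection_lfc", "lfc"), names(de_table))[1]
  if (is.na(lfc_col)) stop("de_table needs a fold-change column")
  hits_genes <- de_table$gene_id[de_table$fdr < de_fdr &
                                   de_table[[lfc_col]] > de_lfc]
  if (!length(hits_genes)) return(character())
  depleted <- peak_lfc$peak_id[peak_lfc$lfc < peak_lfc_threshold]
  cand <- peaks[peaks$peak_id %in% depleted, ]
  if (!nrow(cand)) return(character())
  gsub_genes <- genes[genes$gene_id %in% hits_genes, ]
  d <- GenomicRanges::distanceToNearest(.as_granges(cand),
                                        .as_granges(gsub_genes))
  sel <- S4Vectors::queryHits(d)[S4Vectors::mcols(d)$distance < window]
  unique(cand$peak_id[sel])
}
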