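#' Per-cluster mean profiles
#'
#' Averages a cells-by-features matrix over cluster members, yielding the
#' clusters-by-features profile used for cross-modality matching.
#'
#' @param mat Cells-by-features matrix (log-normalized expression or gene
#'   activity); rownames are cell ids.
#' @param labels Tibble with `cell_id`, `cluster` (as from [cluster_highres()]).
#' @param features Features to keep, in order (must exist in `mat`).
#' @return List of class `epi_profile`: `profile` (clusters x features,
#'   cluster ids sorted), `sizes`, `clusters`.
#' @export
cluster_profiles <- function(mat, labels, features = colnames(mat)) {
  stopifnot(all(features %in% colnames(mat)))
  labels <- labels[labels$cell_id %in% rownames(mat), ]
  sizes <- table(labels$cluster)
  if (any(sizes == 0) || nrow(labels) == 0) stop("empty cluster")
  cl <- sort(unique(labels$cluster))
  m <- mat[labels$cell_id, features, drop = FALSE]
  grp <- factor(labels$cluster, levels = cl)
  sums <- rowsum(as.matrix(m), grp)
  prof <- sums / as.vector(table(grp))
  rownames(prof) <- as.character(cl)
  structure(list(profile = prof, sizes = as.vector(table(grp)), clusters = cl),
            class = "epi_profile")
}

#' Correlation-distance cost matrix between two profile sets
#'
#' `cost(i, j) = 1 - sign * r(a_i, b_j)` with Pearson `r` over the shared
#' feature columns; `sign = +1` for activating marks, `sign = -1` for the
#' repressive mark H3K27me3 (anti-correlation is a good match).
#'
#' @param a,b `epi_profile` objects (or bare matrices) with identical,
#'   identically ordered feature columns.
#' @param sign `+1` or `-1`.
#' @return Numeric cost matrix (rows of `a` x rows of `b`). Zero-variance
#'   profiles get the matrix maximum (correlation undefined), with a warning.
#' @export
matching_cost <- function(a, b, sign = 1) {
  stopifnot(sign %in% c(1, -1))
  pa <- if (inherits(a, "epi_profile")) a$profile else a
  pb <- if (inherits(b, "epi_profile")) b$profile else b
  stopifnot(ncol(pa) == ncol(pb))
  r <- suppressWarnings(stats::cor(t(pa), t(pb)))
  cost <- 1 - sign * r
  if (anyNA(cost)) {
    warning("zero-variance profile(s); their costs set to the matrix maximum")
    cost[is.na(cost)] <- max(cost, na.rm = TRUE)
  }
  dimnames(cost) <- list(rownames(pa), rownames(pb))
  cost
}

# ---- integral min-cost max-flow (successive shortest paths, Bellman-Ford) --
# nodes: 1 = source, 2 = sink, then A nodes, B nodes, optional null nodes.
# edges stored as parallel vectors with residual twins.
.mcmf_solve <- function(from, to, cap, cost, n_nodes, source, sink) {
  m <- length(from)
  # build residual structure: forward edges 1..m, backward m+1..2m
  ef <- c(from, to); et <- c(to, from)
  ecap <- c(cap, rep(0, m)); ecost <- c(cost, -cost)
  twin <- c(m + seq_len(m), seq_len(m))
  adj <- split(seq_len(2 * m), ef)
  total_flow <- 0; total_cost <- 0
  flow <- rep(0, m)
  repeat {
    dist <- rep(Inf, n_nodes); dist[source] <- 0
    pre <- rep(NA_integer_, n_nodes)
    # Bellman-Ford (handles residual negative costs)
    for (iter in seq_len(n_nodes)) {
      changed <- FALSE
      for (e in seq_len(2 * m)) {
        if (ecap[e] > 0 && dist[ef[e]] + ecost[e] < dist[et[e]] - 1e-12) {
          dist[et[e]] <- dist[ef[e]] + ecost[e]
          pre[et[e]] <- e
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (!is.finite(dist[sink])) break
    # bottleneck along path
    path <- integer(0); v <- sink
    while (v != source) { e <- pre[v]; path <- c(path, e); v <- ef[e] }
    push <- min(ecap[path])
    for (e in path) {
      ecap[e] <- ecap[e] - push
      ecap[twin[e]] <- ecap[twin[e]] + push
      if (e <= m) flow[e] <- flow[e] + push else flow[twin[e]] <- flow[twin[e]] - push
    }
    total_flow <- total_flow + push
    total_cost <- total_cost + push * dist[sink]
  }
  list(flow = flow, total_flow = total_flow, total_cost = total_cost)
}

#' Min-cost max-flow bipartite matching with a null sink
#'
#' Builds a sparsified bipartite graph keeping each node's `knn_k` cheapest
#' edges (union over both sides), adds a null node on each side whose edge
#' cost is the given percentile of all pairwise costs (so clusters without a
#' convincing counterpart can opt out), and solves an integral min-cost
#' max-flow with uniform capacities `ceil(max(n_a, n_b) / min(n_a, n_b))` on
#' the smaller side. Ties between equal-cost optima are broken toward the
#' lexicographically smallest (row, column) pairs.
#'
#' @param cost Finite numeric cost matrix (rows = e.g. RNA clusters, columns
#'   = chromatin clusters).
#' @param knn_k Edges kept per node (default 10).
#' @param null_cost_percentile Percentile of all costs used for null edges
#'   (default 99).
#' @param null_cost Optional absolute null-edge cost overriding the
#'   percentile.
#' @param capacity Capacity scheme; only `"uniform"` is implemented.
#' @return List of class `epi_match`: `pairs` (tibble `row`, `col`, `cost`),
#'   `unmatched_row`, `unmatched_col`, `fallback_pairs` (empty tibble),
#'   `total_cost`.
#' @export
mcmf_match <- function(cost, knn_k = 10L, null_cost_percentile = 99,
                       null_cost = NULL, capacity = "uniform") {
  stopifnot(all(is.finite(cost)), capacity == "uniform")
  na <- nrow(cost); nb <- ncol(cost)
  if (is.null(null_cost)) {
    null_cost <- stats::quantile(cost, null_cost_percentile / 100, names = FALSE)
  }
  # shift to non-negative; tiny index bias gives deterministic tie-breaking
  shift <- min(c(cost, null_cost), 0)
  w <- cost - shift + outer(seq_len(na), seq_len(nb),
                            function(i, j) (i * nb + j) * 1e-9)
  wnull <- null_cost - shift + 0.5  # bias null above equal-cost real edges
  # keep each node's knn_k cheapest edges (union of row-wise and col-wise)
  keep <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) keep[i, order(w[i, ])[seq_len(min(knn_k, nb))]] <- TRUE
  for (j in seq_len(nb)) keep[order(w[, j])[seq_len(min(knn_k, na))], j] <- TRUE
  cap_small <- ceiling(max(na, nb) / min(na, nb))
  cap_a <- if (na <= nb) cap_small else 1L
  cap_b <- if (nb <= na) cap_small else 1L
  # node ids: 1 source, 2 sink, A: 2+i, B: 2+na+j, null sink node last.
  # Flow enters through the A side only; every A unit goes to a real B
  # (edge capacity 1, B -> sink capacity cap_b) or to the null node at the
  # percentile cost, so expensive matches are dropped rather than forced.
  A <- function(i) 2L + i; Bn <- function(j) 2L + na + j
  null_node <- 2L + na + nb + 1L
  n_nodes <- null_node
  ef <- c(rep(1L, na), Bn(seq_len(nb)))
  et <- c(A(seq_len(na)), rep(2L, nb))
  ecap <- c(rep(cap_a, na), rep(cap_b, nb))
  ecost <- rep(0, na + nb)
  idx <- which(keep, arr.ind = TRUE)
  ef <- c(ef, A(idx[, 1])); et <- c(et, Bn(idx[, 2]))
  ecap <- c(ecap, rep(1L, nrow(idx))); ecost <- c(ecost, w[idx])
  edge_pair_start <- na + nb  # offset of first real pair edge
  ef <- c(ef, A(seq_len(na)), null_node)
  et <- c(et, rep(null_node, na), 2L)
  ecap <- c(ecap, rep(cap_a, na), na * cap_a)
  ecost <- c(ecost, rep(wnull, na), 0)
  sol <- .mcmf_solve(ef, et, ecap, ecost, n_nodes, source = 1L, sink = 2L)
  pair_edges <- edge_pair_start + seq_len(nrow(idx))
  used <- sol$flow[pair_edges] > 0
  rown <- rownames(cost) %||% as.character(seq_len(na))
  coln <- colnames(cost) %||% as.character(seq_len(nb))
  pairs <- tibble::tibble(
    row = rown[idx[used, 1]],
    col = coln[idx[used, 2]],
    cost = cost[idx[used, , drop = FALSE]]
  )
  pairs <- dplyr::arrange(pairs, .data$row, .data$col)
  out <- list(
    pairs = pairs,
    unmatched_row = setdiff(rown, pairs$row),
    unmatched_col = setdiff(coln, pairs$col),
    fallback_pairs = tibble::tibble(row = character(), col = character(),
                                    cost = numeric()),
    total_cost = sum(pairs$cost),
    cost_matrix = cost
  )
  class(out) <- "epi_match"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.epi_match <- function(x, ...) {
  cat(sprintf("<epi_match> %d pairs (total cost %.4f), %d + %d unmatched, %d fallback\n",
              nrow(x$pairs), x$total_cost, length(x$unmatched_row),
              length(x$unmatched_col), nrow(x$fallback_pairs)))
  invisible(x)
}

#' Resolve unmatched clusters by best correlation
#'
#' Every cluster left unmatched by [mcmf_match()] gains a fallback partner:
#' its minimum-cost counterpart (many-to-one allowed). Ties break toward the
#' lowest cluster id.
#'
#' @param match An `epi_match`.
#' @param cost The cost matrix the match was computed on (defaults to the one
#'   stored in the match).
#' @return The `epi_match` with `fallback_pairs` filled in.
#' @export
resolve_unmatched <- function(match, cost = match$cost_matrix) {
  rown <- rownames(cost) %||% as.character(seq_len(nrow(cost)))
  coln <- colnames(cost) %||% as.character(seq_len(ncol(cost)))
  fb <- list()
  for (r in match$unmatched_row) {
    j <- which.min(cost[match(r, rown), ])  # which.min takes first = lowest id
    fb[[length(fb) + 1]] <- tibble::tibble(row = r, col = coln[j],
                                           cost = cost[match(r, rown), j])
  }
  for (cc in match$unmatched_col) {
    i <- which.min(cost[, match(cc, coln)])
    fb[[length(fb) + 1]] <- tibble::tibble(row = rown[i], col = cc,
                                           cost = cost[i, match(cc, coln)])
  }
  match$fallback_pairs <- if (length(fb)) dplyr::bind_rows(fb) else
    match$fallback_pairs
  match
}

#' Transfer RNA cluster annotations to chromatin clusters
#'
#' @param match An `epi_match` (rows = RNA clusters, columns = chromatin
#'   clusters), after [resolve_unmatched()] if any cluster went unmatched.
#' @param rna_annotations Named character vector or tibble (`cluster`,
#'   `state`) mapping RNA cluster ids to state names.
#' @return Tibble with `chrom_cluster`, `rna_cluster`, `state`, `pair_type`.
#' @export
transfer_labels <- function(match, rna_annotations) {
  if (is.data.frame(rna_annotations)) {
    ann <- stats::setNames(rna_annotations$state,
                           as.character(rna_annotations$cluster))
  } else {
    ann <- rna_annotations
  }
  all_pairs <- dplyr::bind_rows(
    dplyr::mutate(match$pairs, pair_type = "matched"),
    dplyr::mutate(match$fallback_pairs, pair_type = "fallback")
  )
  # one label per chromatin cluster: matched pairs win over fallbacks,
  # then the cheapest pair wins
  all_pairs <- all_pairs |>
    dplyr::arrange(.data$pair_type == "fallback", .data$cost) |>
    dplyr::distinct(.data$col, .keep_all = TRUE)
  missing <- setdiff(colnames(match$cost_matrix) %||%
                       as.character(seq_len(ncol(match$cost_matrix))),
                     all_pairs$col)
  if (length(missing)) {
    stop("chromatin cluster(s) with neither pair nor fallback: ",
         paste(missing, collapse = ", "))
  }
  if (!all(all_pairs$row %in% names(ann))) {
    stop("unannotated RNA cluster(s): ",
         paste(setdiff(all_pairs$row, names(ann)), collapse = ", "))
  }
  tibble::tibble(
    chrom_cluster = all_pairs$col,
    rna_cluster = all_pairs$row,
    state = unname(ann[all_pairs$row]),
    pair_type = all_pairs$pair_type
  )
}
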