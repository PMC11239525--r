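#' Diffusion pseudotime from an embedding
#'
#' Builds a Gaussian-kernel diffusion map on a kNN graph of the embedding,
#' takes ranks along the first nontrivial diffusion component, orients them
#' so the `root_hint` cells come early, and normalizes ranks to `(0, 1]`
#' (sorted values are `i/N`).
#'
#' @param embedding Cells-by-components matrix with rownames.
#' @param root_hint Cell ids expected at the start of the trajectory.
#' @param knn_k Neighbors for the graph (default 50; large enough to bridge
#'   sparse transition corridors between dense states).
#' @return Tibble with `cell_id`, `pseudotime`.
#' @export
diffusion_pseudotime <- function(embedding, root_hint, knn_k = 50L) {
  n <- nrow(embedding)
  stopifnot(n >= 50, length(root_hint) >= 1)
  ids <- rownames(embedding) %||% as.character(seq_len(n))
  nn <- RANN::nn2(embedding, k = min(knn_k + 1L, n))
  # connectivity check
  g <- igraph::graph_from_edgelist(
    cbind(rep(seq_len(n), ncol(nn$nn.idx) - 1L), as.vector(nn$nn.idx[, -1])),
    directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    stop("kNN graph is disconnected: component sizes ",
         paste(comp$csize, collapse = ", "))
  }
  # adaptive Gaussian kernel, symmetrized
  sigma <- nn$nn.dists[, ceiling(knn_k / 2)] + 1e-12
  ii <- rep(seq_len(n), ncol(nn$nn.idx) - 1L)
  jj <- as.vector(nn$nn.idx[, -1])
  dd <- as.vector(nn$nn.dists[, -1])
  wij <- exp(-dd^2 / (sigma[ii] * sigma[jj]))
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(wij, wij),
                            dims = c(n, n), use.last.ij = FALSE)
  W <- (W + Matrix::t(W)) / 2
  Matrix::diag(W) <- 1
  d <- Matrix::rowSums(W)
  S <- Matrix::Diagonal(x = 1 / sqrt(d)) %*% W %*% Matrix::Diagonal(x = 1 / sqrt(d))
  S <- (S + Matrix::t(S)) / 2
  eig <- irlba::partial_eigen(S, n = 3)
  # first eigenvector is trivial (constant after D^-1/2 scaling)
  dc1 <- (1 / sqrt(d)) * eig$vectors[, 2]
  root_idx <- match(root_hint, ids)
  if (anyNA(root_idx)) stop("root_hint cells not in embedding")
  if (mean(rank(dc1)[root_idx]) > (n + 1) / 2) dc1 <- -dc1
  pt <- rank(dc1, ties.method = "first") / n
  tibble::tibble(cell_id = ids, pseudotime = pt)
}

#' Forward-biased transition matrix on the cell-cell kNN graph
#'
#' Edge weights on the symmetrized kNN graph are `exp(beta * (pt(v) - pt(u)))`
#' so transitions toward later pseudotime are up-weighted; rows are
#' normalized to sum to 1.
#'
#' @param embedding Cells-by-components matrix with rownames.
#' @param pseudotime Tibble `cell_id`, `pseudotime` covering all cells.
#' @param knn_k Neighbors (default 50).
#' @param beta Forward-bias strength (default 4).
#' @return Sparse row-stochastic matrix with cell ids as dimnames.
#' @export
transition_matrix <- function(embedding, pseudotime, knn_k = 50L, beta = 4) {
  n <- nrow(embedding)
  ids <- rownames(embedding) %||% as.character(seq_len(n))
  pt <- pseudotime$pseudotime[match(ids, pseudotime$cell_id)]
  if (anyNA(pt)) stop("pseudotime missing for some cells")
  nn <- RANN::nn2(embedding, k = min(knn_k + 1L, n))$nn.idx
  ii <- rep(seq_len(n), ncol(nn) - 1L)
  jj <- as.vector(nn[, -1])
  # symmetrize neighborhoods so no cell is isolated in either direction
  from <- c(ii, jj); to <- c(jj, ii)
  keep <- !duplicated(cbind(from, to))
  from <- from[keep]; to <- to[keep]
  w <- exp(beta * (pt[to] - pt[from]))
  T_ <- Matrix::sparseMatrix(i = from, j = to, x = w, dims = c(n, n))
  rs <- Matrix::rowSums(T_)
  if (any(rs == 0)) stop("isolated cell(s): ", paste(ids[rs == 0], collapse = ", "))
  T_ <- Matrix::Diagonal(x = 1 / rs) %*% T_
  dimnames(T_) <- list(ids, ids)
  methods::as(T_, "CsparseMatrix")
}

#' Absorption probabilities into terminal states
#'
#' Terminal cells are made absorbing; for every transient cell the
#' probability of absorption into each terminal state is the
#' fundamental-matrix solution `(I - Q)^(-1) R` of the absorbing Markov
#' chain, summed over the terminal cells of each state. Rows sum to 1 and
#' terminal cells get probability 1 for their own state.
#'
#' @param T_ Row-stochastic transition matrix with cell-id dimnames.
#' @param terminal_sets Named list of disjoint, nonempty cell-id sets.
#' @return List of class `epi_fates`: `probs` (cells x states matrix),
#'   `states`.
#' @export
absorption_probabilities <- function(T_, terminal_sets) {
  stopifnot(length(terminal_sets) >= 1, !is.null(names(terminal_sets)))
  ids <- rownames(T_)
  term_cells <- unlist(terminal_sets, use.names = FALSE)
  if (anyDuplicated(term_cells)) stop("terminal sets must be disjoint")
  if (any(lengths(terminal_sets) == 0)) stop("empty terminal set")
  if (!all(term_cells %in% ids)) stop("terminal cells not in transition matrix")
  is_term <- ids %in% term_cells
  trans <- which(!is_term); term <- which(is_term)
  Q <- T_[trans, trans, drop = FALSE]
  R <- T_[trans, term, drop = FALSE]
  A <- Matrix::Diagonal(length(trans)) - Q
  Fmat <- tryCatch(
    as.matrix(Matrix::solve(A, R)),
    error = function(e) stop("absorbing chain is not solvable (transient cells ",
                             "without a path to any terminal set): ", conditionMessage(e))
  )
  states <- names(terminal_sets)
  probs <- matrix(0, nrow = length(ids), ncol = length(states),
                  dimnames = list(ids, states))
  # columns of R follow the matrix order of terminal cells, not the
  # terminal_sets grouping
  state_lookup <- stats::setNames(rep(states, times = lengths(terminal_sets)),
                                  unlist(terminal_sets, use.names = FALSE))
  state_of_term <- unname(state_lookup[ids[term]])
  for (s in states) {
    cols <- which(state_of_term == s)
    probs[trans, s] <- rowSums(Fmat[, cols, drop = FALSE])
    probs[ids %in% terminal_sets[[s]], s] <- 1
  }
  bad <- abs(rowSums(probs) - 1) > 1e-6
  if (any(bad)) {
    stop(sum(bad), " cell(s) have no path to any terminal set")
  }
  structure(list(probs = probs, states = states), class = "epi_fates")
}

#' @export
print.epi_fates <- function(x, ...) {
  cat(sprintf("<epi_fates> %d cells x %d terminal states (%s)\n",
              nrow(x$probs), length(x$states), paste(x$states, collapse = ", ")))
  invisible(x)
}

#' Coarse-grained trajectory graph over clusters
#'
#' Connects high-resolution clusters by k-nearest neighbors in fate-vector
#' space, keeps only edges running forward in pseudotime, and drops edges
#' whose endpoints carry different region labels (labels in
#' `wildcard_regions`, by default the root/neuroepithelium label, connect to
#' anything). The result is a DAG by construction.
#'
#' @param cluster_fates Clusters-by-states matrix of mean fate vectors
#'   (rownames are cluster ids).
#' @param cluster_pseudotime Named numeric vector of mean pseudotime per
#'   cluster.
#' @param cluster_regions Named character vector of region labels.
#' @param k Neighbors per cluster (default 10).
#' @param wildcard_regions Region labels treated as compatible with every
#'   region (default `"root"`).
#' @return List of class `epi_trajectory_graph` with `nodes` and `edges`
#'   tibbles.
#' @export
build_trajectory_graph <- function(cluster_fates, cluster_pseudotime,
                                   cluster_regions, k = 10L,
                                   wildcard_regions = "root") {
  n <- nrow(cluster_fates)
  if (k >= n) stop("k must be smaller than the number of clusters")
  ids <- rownames(cluster_fates) %||% as.character(seq_len(n))
  pt <- cluster_pseudotime[ids]
  reg <- cluster_regions[ids]
  if (anyNA(pt) || anyNA(reg)) stop("pseudotime/region missing for some clusters")
  nn <- RANN::nn2(cluster_fates, k = k + 1L)$nn.idx
  ii <- rep(seq_len(n), k)
  jj <- as.vector(nn[, -1])
  dist <- sqrt(rowSums((cluster_fates[ii, , drop = FALSE] -
                          cluster_fates[jj, , drop = FALSE])^2))
  edges <- tibble::tibble(from = ids[ii], to = ids[jj], weight = dist)
  # orient forward in pseudotime, then apply the region rule
  swap <- pt[edges$from] > pt[edges$to]
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- dplyr::distinct(edges, .data$from, .data$to, .keep_all = TRUE)
  edges <- edges[pt[edges$from] < pt[edges$to], ]
  compatible <- reg[edges$from] == reg[edges$to] |
    reg[edges$from] %in% wildcard_regions | reg[edges$to] %in% wildcard_regions
  edges <- edges[compatible, ]
  nodes <- tibble::tibble(cluster = ids, pseudotime = unname(pt),
                          region = unname(reg),
                          size = attr(cluster_fates, "sizes")[ids] %||% NA)
  structure(list(nodes = nodes, edges = edges,
                 fates = cluster_fates), class = "epi_trajectory_graph")
}

#' @export
print.epi_trajectory_graph <- function(x, ...) {
  cat(sprintf("<epi_trajectory_graph> %d clusters, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Circular projection of fate probabilities
#'
#' Terminal states are spaced evenly on the unit circle at angles
#' `alpha_t = 2*pi*(t-1)/n_t`; each cell is placed at
#' `x_i = sum_t f_it cos(alpha_t)`, `y_i = sum_t f_it sin(alpha_t)`.
#'
#' @param fates An `epi_fates` or a cells-by-states probability matrix.
#' @param angles Optional named vector of angles (radians) overriding the
#'   even spacing.
#' @return Tibble `cell_id`, `x`, `y` with the angles as an attribute.
#' @export
circular_projection <- function(fates, angles = NULL) {
  f <- if (inherits(fates, "epi_fates")) fates$probs else fates
  nt <- ncol(f)
  stopifnot(nt >= 2)
  if (is.null(angles)) {
    angles <- 2 * pi * (seq_len(nt) - 1) / nt
    names(angles) <- colnames(f)
  }
  out <- tibble::tibble(
    cell_id = rownames(f) %||% as.character(seq_len(nrow(f))),
    x = as.vector(f %*% cos(angles)),
    y = as.vector(f %*% sin(angles))
  )
  attr(out, "angles") <- angles
  out
}

#' kNN enrichment of a condition in fate-probability space
#'
#' For each cell, the fraction of treated cells among its k nearest
#' neighbors (Euclidean in fate space) is compared to the global treated
#' fraction: `score = log2((local + eps) / (global + eps))`.
#'
#' @param fates `epi_fates` or probability matrix.
#' @param condition Logical or two-level vector (TRUE / second level =
#'   treated), aligned with the fate rows.
#' @param k Neighbors (default 100).
#' @param eps Small constant guarding the log (default 1e-9).
#' @return Tibble `cell_id`, `local_fraction`, `score`.
#' @export
knn_enrichment <- function(fates, condition, k = 100L, eps = 1e-9) {
  f <- if (inherits(fates, "epi_fates")) fates$probs else fates
  n <- nrow(f)
  if (k >= n) stop("k must be smaller than the number of cells")
  treated <- if (is.logical(condition)) condition else
    condition == sort(unique(condition))[2]
  if (!any(treated) || all(treated)) stop("both conditions must be present")
  nn <- RANN::nn2(f, k = k + 1L)$nn.idx[, -1, drop = FALSE]
  local <- rowMeans(matrix(treated[nn], nrow = n))
  global <- mean(treated)
  tibble::tibble(
    cell_id = rownames(f) %||% as.character(seq_len(n)),
    local_fraction = local,
    score = log2((local + eps) / (global + eps))
  )
}
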