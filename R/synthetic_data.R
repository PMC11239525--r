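#' Lineage specification for the synthetic dataset
#'
#' Describes the branching differentiation tree the generator emulates:
#' pluripotent cells (PSC) pass through a neuroepithelium (NE) stage and
#' diversify into four regional branches (telencephalon, diencephalon,
#' mesencephalon, rhombencephalon), each ending in a neuronal terminal state.
#' Pseudotime ranges increase from root to leaves; cells per state set the
#' per-modality sample sizes.
#'
#' @param cells_per_state Named integer vector overriding the default cell
#'   numbers per state (applies to every modality).
#' @return Tibble with columns `state`, `parent`, `branch`, `stage`,
#'   `timepoint_group`, `pt_min`, `pt_max`, `n_cells`, `terminal`.
#' @export
lineage_spec <- function(cells_per_state = NULL) {
  branches <- c("telencephalon", "diencephalon", "mesencephalon", "rhombencephalon")
  spec <- tibble::tibble(
    state = c("PSC", "NE",
              paste0(branches, "_npc"), paste0(branches, "_neuron")),
    parent = c(NA, "PSC", rep("NE", 4), paste0(branches, "_npc")),
    branch = c("root", "root", branches, branches),
    stage = c("pluripotent", "neuroepithelium", rep("progenitor", 4), rep("neuron", 4)),
    timepoint_group = c("EB", "Mid", rep("Late", 8)),
    pt_min = c(0, 0.12, rep(0.35, 4), rep(0.70, 4)),
    pt_max = c(0.12, 0.35, rep(0.70, 4), rep(1.00, 4)),
    n_cells = c(300L, 500L, rep(250L, 4), rep(150L, 4)),
    terminal = c(rep(FALSE, 6), rep(TRUE, 4))
  )
  if (!is.null(cells_per_state)) {
    idx <- match(names(cells_per_state), spec$state)
    if (anyNA(idx)) stop("unknown state in cells_per_state")
    spec$n_cells[idx] <- as.integer(cells_per_state)
  }
  # tree checks: connected, acyclic, pseudotime increases root -> leaves
  for (i in which(!is.na(spec$parent))) {
    p <- match(spec$parent[i], spec$state)
    if (is.na(p)) stop("unreachable state in tree: ", spec$state[i])
    if (spec$pt_min[i] < spec$pt_max[p] - 1e-9) {
      stop("pseudotime ranges must increase from root to leaves")
    }
  }
  spec
}

#' Emission specification for the synthetic dataset
#'
#' Parametrizes how counts are emitted. Chromatin sparsity is modeled as a
#' per-cell, per-peak detection event: at the modality's median depth a peak
#' with state probability `p` is detected with probability exactly `p`
#' (binomial thinning in depth scales this as `1-(1-p)^(depth/median)`), and
#' a detected peak carries `1 + Poisson` fragments calibrated so per-cell
#' totals match the depth draw. RNA counts are negative binomial with
#' per-state relative means scaled to the cell's UMI draw.
#'
#' @param n_peaks Peaks per chromatin mark.
#' @param n_genes Number of genes.
#' @param depth_median Named vector of per-modality median depths (fragments
#'   for marks, UMIs for RNA).
#' @param depth_sdlog Log-normal sd of per-cell depth.
#' @param nb_size Negative-binomial size (inverse dispersion) for RNA.
#' @param p_base Baseline detection probability of unplanted peaks.
#' @param p_marker Detection probability of active marker peaks.
#' @param n_bivalent,n_switching Numbers of planted bivalent / switching regions.
#' @param n_primed Number of planted primed genes on the telencephalon
#'   trajectory.
#' @param priming_bins Reference number of pseudotime bins for planted lags.
#' @param priming_lags Candidate lags (in bins) sampled per primed gene.
#' @param p_primed_low,p_primed_high Chromatin detection before / after the
#'   planted onset of primed genes.
#' @param transition_width Half-width (pseudotime units) of the blending
#'   window around state boundaries; outside it a cell carries its state's
#'   realized profile.
#' @return List of emission parameters.
#' @export
emission_spec <- function(n_peaks = 3000L,
                          n_genes = 2000L,
                          depth_median = c(RNA = 9000, H3K27ac = 600,
                                           H3K27me3 = 400, H3K4me3 = 600),
                          depth_sdlog = 0.3,
                          nb_size = 2,
                          p_base = 0.02,
                          p_marker = 0.40,
                          n_bivalent = 50L,
                          n_switching = 50L,
                          n_primed = 40L,
                          priming_bins = 20L,
                          priming_lags = 1:5,
                          p_primed_low = 0.05,
                          p_primed_high = 0.60,
                          transition_width = 0.03) {
  stopifnot(p_base >= 0, p_base <= 1, p_marker >= 0, p_marker <= 1,
            nb_size > 0, all(depth_median > 0))
  as.list(environment())
}

# deterministic genomic layout: genes and standalone peaks tiled on 5
# chromosomes with 10 kb spacing so unrelated peaks never overlap (+/- 2 kb)
.layout_loci <- function(n, width, chrom_count = 5L, spacing = 10000L,
                         offset = 0L) {
  chrom <- paste0("chr", (seq_len(n) - 1L) %% chrom_count + 1L)
  slot <- (seq_len(n) - 1L) %/% chrom_count
  start <- offset + slot * spacing
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + width))
}

# per-state detection probability matrix for one chromatin mark
.state_probs <- function(mark, peaks, lineage, emission) {
  states <- lineage$state
  P <- matrix(emission$p_base, nrow = length(states), ncol = nrow(peaks),
              dimnames = list(states, peaks$peak_id))
  branches <- unique(lineage$branch[lineage$branch != "root"])
  states_of <- function(br) lineage$state[lineage$branch == br]
  pm <- emission$p_marker
  for (k in seq_len(nrow(peaks))) {
    cls <- peaks$class[k]
    br <- peaks$target_branch[k]
    if (cls == "housekeeping") {
      if (mark == "H3K4me3") P[, k] <- 0.45
      if (mark == "H3K27ac") P[, k] <- 0.35
      if (mark == "H3K27me3") P[, k] <- 0.01
    } else if (cls == "psc_marker") {
      if (mark %in% c("H3K4me3", "H3K27ac")) {
        P[, k] <- 0.01
        P["PSC", k] <- pm
      }
      if (mark == "H3K27me3") {
        P[, k] <- 0.25  # repressed once pluripotency exits
        P["PSC", k] <- 0.01
      }
    } else if (cls == "ne_marker") {
      if (mark %in% c("H3K4me3", "H3K27ac")) P["NE", k] <- pm
      if (mark == "H3K27me3") {
        post <- lineage$state[lineage$stage %in% c("progenitor", "neuron")]
        P[post, k] <- 0.20
        P["PSC", k] <- 0.20  # marked before the neuroepithelium transition
        P["NE", k] <- 0.01
      }
    } else if (cls == "branch_marker") {
      if (mark %in% c("H3K4me3", "H3K27ac")) {
        P[, k] <- 0.01
        P[states_of(br), k] <- pm
      }
      if (mark == "H3K27me3") {
        # Polycomb-marked in pluripotency, resolved by the realized
        # neuroepithelium, re-repressed where the identity is not adopted
        P[, k] <- 0.01
        P["PSC", k] <- 0.25
        other <- setdiff(branches, br)
        P[unlist(lapply(other, states_of)), k] <- 0.25
      }
    } else if (cls == "neuron") {
      if (mark %in% c("H3K4me3", "H3K27ac")) {
        P[, k] <- 0.01
        P[lineage$state[lineage$stage == "neuron"], k] <- pm
      }
      if (mark == "H3K27me3") {
        # Polycomb-repressed until neuronal differentiation
        P[, k] <- 0.20
        P[lineage$state[lineage$stage == "progenitor"], k] <- 0.25
        P[lineage$state[lineage$stage == "neuron"], k] <- 0.01
      }
    } else if (cls == "primed") {
      # K27ac handled per cell (pseudotime-dependent); K4me3 constitutive
      if (mark == "H3K4me3") P[, k] <- 0.30
      if (mark == "H3K27ac") P[, k] <- emission$p_primed_low
      if (mark == "H3K27me3") P[, k] <- 0.01
    } else if (cls == "bivalent") {
      act <- peaks$activated_branch[k]
      rep_ <- peaks$repressed_branch[k]
      if (mark %in% c("H3K4me3", "H3K27me3")) {
        P[c("PSC", "NE"), k] <- c(0.25, 0.30)
        for (b in branches) {
          p_here <- if (mark == "H3K4me3") {
            if (b == act) 0.45 else if (b == rep_) 0.01 else 0.25
          } else {
            if (b == act) 0.01 else if (b == rep_) 0.45 else 0.25
          }
          P[states_of(b), k] <- p_here
        }
      }
    } else if (cls == "switching") {
      if (mark == "H3K27me3") {
        P[, k] <- 0.35
        P["NE", k] <- 0.40
        P[states_of(br), k] <- 0.01
      }
      if (mark == "H3K27ac") {
        P[, k] <- 0.01
        P[states_of(br), k] <- 0.45
      }
    }
    # background peaks keep p_base
  }
  P
}


# Per-cell emission profiles, continuous in pseudotime along the lineage:
# a state's profile is fully realized at its pseudotime midpoint; before it
# the cell blends from the parent state's profile, after it the cell blends
# toward the next state on the path to the cell's destiny leaf (so late
# neuroepithelium cells are already primed toward a specific branch).
.blended_profiles <- function(P, lineage, state, pt, destiny, width = 0.03) {
  si <- match(state, lineage$state)
  parent_i <- match(lineage$parent[si], lineage$state)
  out <- matrix(P[si, ], length(pt), ncol(P), byrow = TRUE)
  # entry window around pt_min: 50/50 parent/own at the boundary itself,
  # converging to the realized profile by pt_min + width
  if (!is.na(parent_i)) {
    entry <- pt < lineage$pt_min[si] + width
    if (any(entry)) {
      a <- (pt[entry] - (lineage$pt_min[si] - width)) / (2 * width)
      a <- pmin(pmax(a, 0), 1)
      out[entry, ] <- outer(1 - a, P[parent_i, ]) + outer(a, P[si, ])
    }
  }
  # exit window before pt_max: blend toward the next state on the path to
  # the cell's destiny leaf, reaching 50/50 at the boundary
  if (!lineage$terminal[si]) {
    exit <- pt > lineage$pt_max[si] - width
    if (any(exit)) {
      next_state <- .next_toward(lineage, state, destiny[exit])
      for (nx in unique(next_state)) {
        rows <- which(exit)[next_state == nx]
        ni <- match(nx, lineage$state)
        a <- (pt[rows] - (lineage$pt_max[si] - width)) / (2 * width)
        a <- pmin(pmax(a, 0), 0.5)
        out[rows, ] <- outer(1 - a, P[si, ]) + outer(a, P[ni, ])
      }
    }
  }
  out
}

# next state on the path from `state` to each destiny leaf
.next_toward <- function(lineage, state, destiny) {
  vapply(destiny, function(d) {
    path <- d
    while (lineage$parent[match(path[1], lineage$state)] != state &&
           !is.na(lineage$parent[match(path[1], lineage$state)])) {
      path <- c(lineage$parent[match(path[1], lineage$state)], path)
    }
    path[1]
  }, "")
}

# detection + fragment-count emission for one mark given per-cell state/pt
.emit_chromatin <- function(mark, peaks, cells, lineage, emission, primed) {
  P <- .state_probs(mark, peaks, lineage, emission)
  d <- cells$depth
  r <- d / stats::median(d)
  n_peak <- nrow(peaks)
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (si in seq_len(nrow(lineage))) {
    st <- lineage$state[si]
    rows <- which(cells$state == st)
    if (!length(rows)) next
    p_cell <- .blended_profiles(P, lineage, st, cells$pseudotime[rows],
                                cells$destiny[rows], emission$transition_width)
    # p_eff = 1 - (1-p)^r per cell
    peff <- 1 - exp(r[rows] * log1p(-p_cell))
    det <- matrix(stats::rbinom(length(peff), 1L, peff), nrow = length(rows))
    # primed K27ac peaks: onset along the telencephalon trajectory quantile
    if (mark == "H3K27ac" && nrow(primed)) {
      q <- cells$traj_quantile[rows]
      for (g in seq_len(nrow(primed))) {
        k <- primed$peak_col[g]
        p_cell <- ifelse(!is.na(q) & q >= primed$chrom_onset_q[g],
                         emission$p_primed_high, emission$p_primed_low)
        peffk <- 1 - exp(r[rows] * log1p(-p_cell))
        det[, k] <- stats::rbinom(length(rows), 1L, peffk)
        peff[, k] <- peffk
      }
    }
    lambda <- pmax(0, d[rows] / pmax(rowSums(peff), 1e-9) - 1)
    nz <- which(det == 1L, arr.ind = TRUE)
    if (nrow(nz)) {
      cnt <- 1L + stats::rpois(nrow(nz), lambda[nz[, 1]])
      ii <- c(ii, rows[nz[, 1]]); jj <- c(jj, nz[, 2]); xx <- c(xx, cnt)
    }
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = as.double(xx),
                            dims = c(nrow(cells), n_peak))
  count_matrix(m, cells$cell_id, peaks$peak_id, modality = mark)
}

# per-state relative expression weights for RNA
.rna_weights <- function(genes, lineage) {
  states <- lineage$state
  W <- matrix(0.3, nrow = length(states), ncol = nrow(genes),
              dimnames = list(states, genes$gene_id))
  states_of <- function(br) lineage$state[lineage$branch == br]
  for (k in seq_len(nrow(genes))) {
    cls <- genes$class[k]
    if (cls == "housekeeping") W[, k] <- 5
    else if (cls == "psc_marker") { W[, k] <- 0.3; W["PSC", k] <- 6 }
    else if (cls == "ne_marker") { W[, k] <- 0.3; W["NE", k] <- 6 }
    else if (cls == "branch_marker") {
      W[, k] <- 0.3; W[states_of(genes$target_branch[k]), k] <- 6
    } else if (cls == "neuron") {
      W[, k] <- 0.3; W[lineage$state[lineage$stage == "neuron"], k] <- 6
    } else if (cls == "primed") {
      W[, k] <- 0.1  # kept low so the planted RNA onset is a sharp step
    } else if (cls == "silent") W[, k] <- 0.2
  }
  W
}

.emit_rna <- function(genes, cells, lineage, emission, primed) {
  W <- .rna_weights(genes, lineage)
  n_gene <- nrow(genes)
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (si in seq_len(nrow(lineage))) {
    st <- lineage$state[si]
    rows <- which(cells$state == st)
    if (!length(rows)) next
    w <- .blended_profiles(W, lineage, st, cells$pseudotime[rows],
                           cells$destiny[rows], emission$transition_width)
    if (nrow(primed)) {
      q <- cells$traj_quantile[rows]
      for (g in seq_len(nrow(primed))) {
        k <- primed$gene_col[g]
        w[, k] <- ifelse(!is.na(q) & q >= primed$rna_onset_q[g], 6, 0.1)
      }
    }
    mu <- w / rowSums(w) * cells$depth[rows]
    cnt <- matrix(stats::rnbinom(length(mu), size = emission$nb_size, mu = mu),
                  nrow = length(rows))
    nz <- which(cnt > 0L, arr.ind = TRUE)
    if (nrow(nz)) {
      ii <- c(ii, rows[nz[, 1]]); jj <- c(jj, nz[, 2]); xx <- c(xx, cnt[nz])
    }
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = as.double(xx),
                            dims = c(nrow(cells), n_gene))
  count_matrix(m, cells$cell_id, genes$gene_id, modality = "RNA")
}

#' Simulate a multimodal single-cell dataset with planted ground truth
#'
#' Generates independent cell populations per modality (RNA plus the three
#' histone marks) along the branching lineage in `lineage`, with planted
#' region-specific peaks, bivalent regions (H3K4me3 + H3K27me3 in
#' neuroepithelium, resolved per branch), switching regions (H3K27me3 in
#' neuroepithelium, H3K27ac in one target branch) and primed genes whose
#' H3K27ac activation precedes RNA expression by a planted number of
#' pseudotime bins.
#'
#' @param lineage A [lineage_spec()].
#' @param emission An [emission_spec()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List with elements `counts` (named list of [count_matrix()]),
#'   `metadata` (per-cell tibble), `peaks` (named list of interval tibbles
#'   per mark), `genes` (gene-model tibble) and `truth` (list of tibbles:
#'   `cells`, `bivalent`, `switching`, `primed`, `region_peaks`).
#' @export
simulate_dataset <- function(lineage = lineage_spec(),
                             emission = emission_spec(),
                             seed = 1L) {
  if (sum(lineage$terminal) < 2) stop("need at least 2 terminal states")
  withr::with_seed(as.integer(seed), {
    n_genes <- emission$n_genes
    # gene classes, proportional to the gene universe (5% marker classes)
    n_marker <- max(1L, round(0.05 * n_genes))
    branches <- c("telencephalon", "diencephalon", "mesencephalon", "rhombencephalon")
    n_primed <- min(emission$n_primed,
                    max(0L, n_genes - round(0.35 * n_genes) - 7L * n_marker))
    class_vec <- rep("silent", n_genes)
    class_vec[seq_len(round(0.35 * n_genes))] <- "housekeeping"
    cursor <- round(0.35 * n_genes)
    class_vec[cursor + seq_len(n_marker)] <- "psc_marker"; cursor <- cursor + n_marker
    class_vec[cursor + seq_len(n_marker)] <- "ne_marker"; cursor <- cursor + n_marker
    target_branch <- rep(NA_character_, n_genes)
    for (b in branches) {
      class_vec[cursor + seq_len(n_marker)] <- "branch_marker"
      target_branch[cursor + seq_len(n_marker)] <- b
      cursor <- cursor + n_marker
    }
    class_vec[cursor + seq_len(n_marker)] <- "neuron"; cursor <- cursor + n_marker
    if (n_primed > 0) class_vec[cursor + seq_len(n_primed)] <- "primed"

    loci <- .layout_loci(n_genes, width = 5000L)
    genes <- tibble::tibble(
      gene_id = sprintf("gene%04d", seq_len(n_genes)),
      chrom = loci$chrom, start = loci$start, end = loci$end,
      strand = rep(c("+", "-"), length.out = n_genes),
      class = class_vec, target_branch = target_branch
    )
    genes <- gene_models(genes)

    # promoter peaks (one per gene, identical interval across marks)
    prom <- tibble::tibble(
      chrom = genes$chrom,
      start = pmax(0L, genes$tss - 250L),
      end = genes$tss + 250L,
      class = genes$class, target_branch = genes$target_branch,
      gene_id = genes$gene_id,
      activated_branch = NA_character_, repressed_branch = NA_character_
    )
    # planted standalone regions on separate loci (offset keeps them clear
    # of gene bodies and of each other)
    biv_loci <- .layout_loci(emission$n_bivalent, width = 600L, offset = 6000L)
    biv <- tibble::tibble(
      chrom = biv_loci$chrom, start = biv_loci$start, end = biv_loci$end,
      class = "bivalent", target_branch = NA_character_, gene_id = NA_character_,
      activated_branch = sample(branches, emission$n_bivalent, replace = TRUE),
      repressed_branch = NA_character_
    )
    biv$repressed_branch <- vapply(biv$activated_branch, function(a) {
      sample(setdiff(branches, a), 1L)
    }, "")
    # switching regions occupy a slot range disjoint from the bivalent ones
    # so the two planted sets never pair after +/-2 kb extension
    sw_loci <- .layout_loci(emission$n_switching, width = 600L, offset = 106000L)
    sw <- tibble::tibble(
      chrom = sw_loci$chrom, start = sw_loci$start, end = sw_loci$end,
      class = "switching",
      target_branch = sample(branches, emission$n_switching, replace = TRUE),
      gene_id = NA_character_,
      activated_branch = NA_character_, repressed_branch = NA_character_
    )
    bg_n <- function(extra) max(0L, emission$n_peaks - nrow(prom) - extra)
    bg <- function(n, offset) {
      l <- .layout_loci(n, width = 400L, offset = offset)
      tibble::tibble(chrom = l$chrom, start = l$start, end = l$end,
                     class = "background", target_branch = NA_character_,
                     gene_id = NA_character_, activated_branch = NA_character_,
                     repressed_branch = NA_character_)
    }
    peak_sets <- list(
      H3K4me3 = dplyr::bind_rows(prom, biv, bg(bg_n(nrow(biv)), 8700L)),
      H3K27me3 = dplyr::bind_rows(prom, biv, sw, bg(bg_n(nrow(biv) + nrow(sw)), 8700L)),
      H3K27ac = dplyr::bind_rows(prom, sw, bg(bg_n(nrow(sw)), 8700L))
    )
    peak_sets <- lapply(peak_sets, function(p) {
      p$peak_id <- peak_id(p$chrom, p$start, p$end)
      p
    })

    # cells: independent population per modality, same lineage sizes
    make_cells <- function(mod) {
      st <- rep(lineage$state, lineage$n_cells)
      n <- length(st)
      pt <- stats::runif(n, lineage$pt_min[match(st, lineage$state)],
                         lineage$pt_max[match(st, lineage$state)])
      depth <- stats::rlnorm(n, log(emission$depth_median[[mod]]),
                             emission$depth_sdlog)
      branches_all <- unique(lineage$branch[lineage$branch != "root"])
      destiny <- ifelse(
        st %in% lineage$state[lineage$terminal], st,
        ifelse(grepl("_npc$", st), sub("_npc$", "_neuron", st),
               paste0(sample(branches_all, n, replace = TRUE), "_neuron")))
      # sampling timepoints track developmental time: transition-corridor
      # cells at the end of the neuroepithelium window are sampled "Late"
      tp <- cut(pt, breaks = c(-Inf, 0.17, 0.30, Inf),
                labels = c("EB", "Mid", "Late"))
      cells <- tibble::tibble(
        cell_id = sprintf("%s_cell%05d", mod, seq_len(n)),
        modality = mod, state = st, destiny = destiny,
        branch = lineage$branch[match(st, lineage$state)],
        stage = lineage$stage[match(st, lineage$state)],
        timepoint_group = as.character(tp),
        pseudotime = pt, depth = depth, condition = "control"
      )
      # quantile along the telencephalic trajectory (NA off-trajectory)
      on_traj <- cells$state %in% c("PSC", "NE", "telencephalon_npc",
                                    "telencephalon_neuron")
      q <- rep(NA_real_, n)
      q[on_traj] <- (rank(cells$pseudotime[on_traj], ties.method = "first") - 0.5) /
        sum(on_traj)
      cells$traj_quantile <- q
      cells
    }
    modalities <- c("RNA", "H3K27ac", "H3K27me3", "H3K4me3")
    cells <- stats::setNames(lapply(modalities, make_cells), modalities)

    # primed gene truth: chromatin onset bin and RNA onset bin (B bins)
    B <- emission$priming_bins
    primed_idx <- which(genes$class == "primed")
    primed <- tibble::tibble(
      gene_id = genes$gene_id[primed_idx],
      gene_col = primed_idx,
      peak_col = primed_idx,  # promoter peak shares the gene's column index
      chrom_bin = sample(6:12, length(primed_idx), replace = TRUE),
      lag = sample(emission$priming_lags, length(primed_idx), replace = TRUE)
    )
    primed$rna_bin <- primed$chrom_bin + primed$lag
    primed$chrom_onset_q <- (primed$chrom_bin - 1) / B
    primed$rna_onset_q <- (primed$rna_bin - 1) / B

    counts <- list(
      RNA = .emit_rna(genes, cells$RNA, lineage, emission, primed),
      H3K27ac = .emit_chromatin("H3K27ac", peak_sets$H3K27ac, cells$H3K27ac,
                                lineage, emission, primed),
      H3K27me3 = .emit_chromatin("H3K27me3", peak_sets$H3K27me3,
                                 cells$H3K27me3, lineage, emission,
                                 primed[0, ]),
      H3K4me3 = .emit_chromatin("H3K4me3", peak_sets$H3K4me3, cells$H3K4me3,
                                lineage, emission, primed[0, ])
    )
    metadata <- dplyr::bind_rows(cells)[, c("cell_id", "modality", "timepoint_group",
                                            "condition")]
    metadata$line <- "simulated"

    truth <- list(
      cells = dplyr::bind_rows(cells)[, c("cell_id", "modality", "state", "branch",
                                          "stage", "timepoint_group", "pseudotime",
                                          "condition")],
      bivalent = tibble::tibble(
        k4_peak_id = peak_sets$H3K4me3$peak_id[peak_sets$H3K4me3$class == "bivalent"],
        me3_peak_id = peak_sets$H3K27me3$peak_id[peak_sets$H3K27me3$class == "bivalent"],
        activated_branch = biv$activated_branch,
        repressed_branch = biv$repressed_branch
      ),
      switching = tibble::tibble(
        me3_peak_id = peak_sets$H3K27me3$peak_id[peak_sets$H3K27me3$class == "switching"],
        ac_peak_id = peak_sets$H3K27ac$peak_id[peak_sets$H3K27ac$class == "switching"],
        branch = sw$target_branch
      ),
      primed = tibble::tibble(
        gene_id = primed$gene_id,
        chrom_modality = "H3K27ac",
        chrom_bin = primed$chrom_bin, rna_bin = primed$rna_bin,
        lag = primed$lag, n_bins = B
      ),
      region_peaks = {
        bm <- peak_sets$H3K27ac$class == "branch_marker"
        tibble::tibble(
          peak_id = peak_sets$H3K27ac$peak_id[bm],
          modality = "H3K27ac",
          branch = peak_sets$H3K27ac$target_branch[bm],
          direction = "up"
        )
      }
    )
    peaks_out <- lapply(peak_sets, function(p) {
      p[, c("chrom", "start", "end", "peak_id", "class")]
    })
    epi_log("simulated dataset: seed %d, %d genes, %d peaks/mark", seed,
            n_genes, emission$n_peaks)
    list(counts = counts, metadata = metadata, peaks = peaks_out,
         genes = genes[, c("gene_id", "chrom", "start", "end", "strand", "tss",
                           "class", "target_branch")],
         truth = truth)
  })
}

#' Write a simulated dataset to disk in the package's exchange formats
#'
#' @param dataset Result of [simulate_dataset()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty directory.
#' @return Tibble manifest of written files.
#' @export
write_dataset <- function(dataset, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop(out_dir, " exists and is not empty (use force = TRUE)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (mod in names(dataset$counts)) {
    cm <- dataset$counts[[mod]]
    write_mtx_triplet(cm,
                      file.path(out_dir, paste0(mod, "_matrix.mtx")),
                      file.path(out_dir, paste0(mod, "_features.tsv")),
                      file.path(out_dir, paste0(mod, "_barcodes.tsv")))
    files[[length(files) + 1]] <- tibble::tibble(
      file = paste0(mod, c("_matrix.mtx", "_features.tsv", "_barcodes.tsv")),
      kind = "matrix", modality = mod)
    if (mod != "RNA") {
      write_peak_bed(dataset$peaks[[mod]],
                     file.path(out_dir, paste0(mod, "_peaks.bed")))
      files[[length(files) + 1]] <- tibble::tibble(
        file = paste0(mod, "_peaks.bed"), kind = "peaks", modality = mod)
    }
  }
  write_gene_models(dataset$genes, file.path(out_dir, "gene_models.tsv"))
  write_cell_metadata(dataset$metadata, file.path(out_dir, "cell_metadata.tsv"))
  truth <- .flatten_truth(dataset$truth)
  utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files[[length(files) + 1]] <- tibble::tibble(
    file = c("gene_models.tsv", "cell_metadata.tsv", "truth.tsv"),
    kind = c("genes", "metadata", "truth"), modality = NA_character_)
  dplyr::bind_rows(files)
}

# one row per cell plus one row per planted feature
.flatten_truth <- function(truth) {
  cells <- dplyr::mutate(truth$cells, record = "cell",
                         id = .data$cell_id, detail = .data$state)
  biv <- tibble::tibble(record = "bivalent", id = truth$bivalent$k4_peak_id,
                        modality = "H3K4me3+H3K27me3",
                        detail = paste0("activated:", truth$bivalent$activated_branch,
                                        ";repressed:", truth$bivalent$repressed_branch),
                        pair_id = truth$bivalent$me3_peak_id)
  sw <- tibble::tibble(record = "switching", id = truth$switching$me3_peak_id,
                       modality = "H3K27me3+H3K27ac",
                       detail = truth$switching$branch,
                       pair_id = truth$switching$ac_peak_id)
  pr <- tibble::tibble(record = "primed", id = truth$primed$gene_id,
                       modality = truth$primed$chrom_modality,
                       detail = sprintf("chrom_bin:%d;rna_bin:%d;lag:%d",
                                        truth$primed$chrom_bin,
                                        truth$primed$rna_bin, truth$primed$lag),
                       pair_id = NA_character_)
  rp <- tibble::tibble(record = "region_peak", id = truth$region_peaks$peak_id,
                       modality = truth$region_peaks$modality,
                       detail = truth$region_peaks$branch, pair_id = NA_character_)
  dplyr::bind_rows(
    cells[, c("record", "id", "modality", "detail", "branch", "pseudotime",
              "condition")],
    biv, sw, pr, rp
  )
}

#' Simulate stepped detection profiles with planted pseudotime lags
#'
#' A focused generator for the priming statistic: binary detection of a
#' chromatin mark steps from `p_low` to `p_high` at a planted onset bin, and
#' RNA detection steps at onset + lag. Null genes stay at `p_low` in both
#' modalities.
#'
#' @param n_primed,n_null Numbers of primed and null genes.
#' @param n_bins Number of pseudotime bins.
#' @param cells_per_bin Cells per bin (shared by both modalities).
#' @param p_low,p_high Detection probability before / after onset.
#' @param lags Candidate lags (bins) sampled per primed gene.
#' @param onset_range Candidate chromatin onset bins.
#' @param seed Integer seed.
#' @return List with `chrom` and `rna` binary matrices (cells x genes),
#'   `bins` (per-cell bin index) and `truth` tibble (gene, onset, lag).
#' @export
simulate_priming_truth <- function(n_primed = 100L, n_null = 100L,
                                   n_bins = 20L, cells_per_bin = 150L,
                                   p_low = 0.05, p_high = 0.6,
                                   lags = 1:5, onset_range = 6:12,
                                   seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n_cells <- n_bins * cells_per_bin
    bins <- rep(seq_len(n_bins), each = cells_per_bin)
    n_genes <- n_primed + n_null
    onset <- c(sample(onset_range, n_primed, replace = TRUE),
               rep(NA_integer_, n_null))
    lag <- c(sample(lags, n_primed, replace = TRUE), rep(NA_integer_, n_null))
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    emit <- function(onset_bins) {
      p <- matrix(p_low, nrow = n_cells, ncol = n_genes)
      for (g in seq_len(n_genes)) {
        if (!is.na(onset_bins[g])) p[bins >= onset_bins[g], g] <- p_high
      }
      m <- matrix(stats::rbinom(length(p), 1L, p), nrow = n_cells,
                  dimnames = list(sprintf("cell%05d", seq_len(n_cells)), gene_ids))
      m
    }
    list(chrom = emit(onset), rna = emit(onset + lag), bins = bins,
         truth = tibble::tibble(gene_id = gene_ids, onset = onset, lag = lag,
                                primed = !is.na(onset)))
  })
}
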