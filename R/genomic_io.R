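#' Canonical peak identifier
#'
#' Peaks are identified throughout the package as `"chrom:start-end"` strings
#' (0-based, half-open BED coordinates), so interval tables and count matrices
#' can be joined by id.
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open interval bounds.
#' @return Character vector of peak ids.
#' @export
peak_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Parse canonical peak ids back into an interval tibble
#'
#' @param ids Character vector of `"chrom:start-end"` ids.
#' @return Tibble with columns `chrom`, `start`, `end`, `peak_id`.
#' @export
parse_peak_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed peak id(s): ", paste(utils::head(ids[bad], 3), collapse = ", "))
  }
  tibble::tibble(
    chrom = vapply(m, `[`, "", 2L),
    start = as.integer(vapply(m, `[`, "", 3L)),
    end = as.integer(vapply(m, `[`, "", 4L)),
    peak_id = ids
  )
}

.check_intervals <- function(x, where = "intervals") {
  if (any(x$start < 0)) stop(where, ": negative start coordinate")
  if (any(x$end <= x$start)) {
    i <- which(x$end <= x$start)[1]
    stop(where, ": empty or inverted interval at row ", i)
  }
  if (any(!nzchar(x$chrom))) stop(where, ": empty chromosome name")
  invisible(x)
}

#' Read a BED file of peak intervals
#'
#' Coordinates stay in the native BED convention: 0-based, half-open.
#'
#' @param path Path to a tab-separated BED file (>= 3 columns).
#' @return Tibble with columns `chrom`, `start`, `end`, `name` (NA when the
#'   file has only three columns) and `peak_id`.
#' @export
read_peak_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- vapply(fields, length, 1L)
  if (any(n_fields < 3L)) {
    stop("malformed BED line ", which(n_fields < 3L)[1], ": fewer than 3 columns")
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinate")
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[`, "", 1L),
    start = start,
    end = end,
    name = ifelse(n_fields >= 4L, vapply(fields, function(f) f[4], ""), NA_character_)
  )
  .check_intervals(out, path)
  out$peak_id <- peak_id(out$chrom, out$start, out$end)
  out
}

#' Write peak intervals as BED
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_bed <- function(x, path) {
  .check_intervals(x, "write_peak_bed")
  has_name <- "name" %in% names(x) && !all(is.na(x$name))
  lines <- if (has_name) {
    sprintf("%s\t%d\t%d\t%s", x$chrom, x$start, x$end, x$name)
  } else {
    sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Sparse count matrix with identities
#'
#' A light container for a sparse cells-by-features count matrix together
#' with its cell ids, feature ids and modality tag. `values` is a
#' [Matrix::dgCMatrix-class] with cells as rows.
#'
#' @param values Sparse (or dense) non-negative integer matrix, cells x features.
#' @param cell_ids,feature_ids Character vectors naming rows and columns.
#' @param modality One of `"RNA"`, `"H3K27ac"`, `"H3K27me3"`, `"H3K4me3"`, `"ATAC"`.
#' @return Object of class `count_matrix`.
#' @export
count_matrix <- function(values, cell_ids, feature_ids,
                         modality = c("RNA", "H3K27ac", "H3K27me3", "H3K4me3", "ATAC")) {
  modality <- match.arg(modality)
  values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  if (nrow(values) != length(cell_ids) || ncol(values) != length(feature_ids)) {
    stop("count_matrix: dimensions do not match id list lengths")
  }
  if (anyDuplicated(cell_ids)) stop("count_matrix: duplicate cell ids")
  if (anyDuplicated(feature_ids)) stop("count_matrix: duplicate feature ids")
  if (length(values@x) && any(values@x < 0)) stop("count_matrix: negative entries")
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(
    list(values = values, cell_ids = cell_ids, feature_ids = feature_ids,
         modality = modality),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s: %d cells x %d features, %d nonzeros\n",
              x$modality, nrow(x$values), ncol(x$values), length(x$values@x)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Read a MatrixMarket triplet matrix with feature/barcode sidecars
#'
#' Reads the 10x-style trio of files: a MatrixMarket coordinate matrix
#' (features x cells, as emitted by Cell Ranger) plus one-id-per-line feature
#' and barcode files. The returned matrix is transposed to cells x features.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param features_path,barcodes_path One id per line.
#' @param modality Modality tag for the result.
#' @return A [count_matrix()].
#' @export
read_mtx_triplet <- function(matrix_path, features_path, barcodes_path,
                             modality = "RNA") {
  m <- Matrix::readMM(matrix_path)
  features <- readLines(features_path)
  barcodes <- readLines(barcodes_path)
  features <- features[nzchar(features)]
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != length(features)) {
    stop("feature file has ", length(features), " ids but matrix has ",
         nrow(m), " rows")
  }
  if (ncol(m) != length(barcodes)) {
    stop("barcode file has ", length(barcodes), " ids but matrix has ",
         ncol(m), " columns")
  }
  m <- methods::as(m, "CsparseMatrix")
  if (length(m@x) && any(m@x < 0)) stop("negative entry in count matrix")
  if (length(m@x) && any(m@x != round(m@x))) stop("non-integer entry in count matrix")
  count_matrix(Matrix::t(m), barcodes, features, modality = modality)
}

#' Write a count matrix as MatrixMarket triplet plus sidecars
#'
#' @param cm A [count_matrix()].
#' @param matrix_path,features_path,barcodes_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_mtx_triplet <- function(cm, matrix_path, features_path, barcodes_path) {
  Matrix::writeMM(Matrix::t(cm$values), matrix_path)
  writeLines(cm$feature_ids, features_path)
  writeLines(cm$cell_ids, barcodes_path)
  invisible(matrix_path)
}

#' Read a 10x-style fragments file
#'
#' Five tab-separated columns: chrom, start, end, barcode, count. Rows are
#' sorted by (chrom, start) on load.
#'
#' @param path Path to an uncompressed fragments TSV.
#' @return Tibble with columns `chrom`, `start`, `end`, `barcode`, `count`.
#' @export
read_fragments <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "barcode", "count"),
                         colClasses = c("character", "integer", "integer",
                                        "character", "integer"))
  x <- tibble::as_tibble(x)
  .check_intervals(x, path)
  if (any(x$count < 1)) {
    stop(path, ": fragment count < 1 at row ", which(x$count < 1)[1])
  }
  dplyr::arrange(x, .data$chrom, .data$start, .data$end, .data$barcode)
}

#' Write fragments as TSV
#'
#' @param x Fragment tibble as returned by [read_fragments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end", "barcode", "count")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-model table
#'
#' Tab-separated columns `gene_id`, `chrom`, `start`, `end`, `strand` (with a
#' header line). The TSS is derived from the strand: `start` for `+` genes,
#' `end - 1` for `-` genes (0-based).
#'
#' @param path Path to the TSV.
#' @return Gene-model tibble with a `tss` column.
#' @export
read_gene_models <- function(path) {
  x <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                           stringsAsFactors = FALSE))
  gene_models(x)
}

#' Validate and complete a gene-model tibble
#'
#' @param x Tibble with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @return The tibble with a derived `tss` column.
#' @export
gene_models <- function(x) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(x)))
  if (!all(x$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  .check_intervals(x, "gene models")
  x$tss <- ifelse(x$strand == "+", x$start, x$end - 1L)
  tibble::as_tibble(x)
}

#' Write a gene-model table as TSV
#'
#' @param x Gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(x, path) {
  utils::write.table(x[, c("gene_id", "chrom", "start", "end", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extend intervals symmetrically, clamping at zero
#'
#' @param x Interval tibble (`chrom`, `start`, `end`).
#' @param slop Basepairs added on both sides.
#' @return The tibble with extended coordinates.
#' @export
extend_intervals <- function(x, slop) {
  stopifnot(slop >= 0)
  x$start <- pmax(0L, as.integer(x$start) - as.integer(slop))
  x$end <- as.integer(x$end) + as.integer(slop)
  x
}

.as_granges <- function(x) {
  # BED half-open 0-based -> IRanges closed 1-based
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

#' All overlapping pairs between two interval sets after extension
#'
#' Both sets are extended by `slop` basepairs on each side (starts clamped at
#' 0) before intersection; a pair is reported when the extended intervals
#' overlap on the same chromosome. Indices are 1-based.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`).
#' @param slop Extension in basepairs (applied to both sets).
#' @return Tibble with columns `i` (index into `a`) and `j` (index into `b`).
#' @export
intersect_intervals <- function(a, b, slop = 0L) {
  stopifnot(slop >= 0)
  ga <- .as_granges(extend_intervals(a, slop))
  gb <- .as_granges(extend_intervals(b, slop))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  tibble::tibble(i = S4Vectors::queryHits(hits), j = S4Vectors::subjectHits(hits))
}

#' Validate a dataset directory
#'
#' Checks that a directory contains the files a simulated (or exported)
#' dataset is expected to hold, and that they parse: per-modality MTX trios,
#' peak BEDs for the chromatin marks, gene models, cell metadata and the
#' truth table if present. Reports dimensions for each matrix.
#'
#' @param dir Dataset directory.
#' @return Tibble with one row per modality (`modality`, `n_cells`,
#'   `n_features`), invisibly printed as messages.
#' @export
validate_dataset_dir <- function(dir) {
  stopifnot(dir.exists(dir))
  mods <- c("RNA", "H3K27ac", "H3K27me3", "H3K4me3")
  out <- purrr::map_dfr(mods, function(mod) {
    mtx <- file.path(dir, paste0(mod, "_matrix.mtx"))
    if (!file.exists(mtx)) return(tibble::tibble())
    cm <- read_mtx_triplet(mtx,
                           file.path(dir, paste0(mod, "_features.tsv")),
                           file.path(dir, paste0(mod, "_barcodes.tsv")),
                           modality = mod)
    if (mod != "RNA") {
      bed <- read_peak_bed(file.path(dir, paste0(mod, "_peaks.bed")))
      if (!identical(bed$peak_id, cm$feature_ids)) {
        stop(mod, ": peak BED does not match matrix feature ids")
      }
    }
    tibble::tibble(modality = mod, n_cells = nrow(cm$values),
                   n_features = ncol(cm$values))
  })
  meta_path <- file.path(dir, "cell_metadata.tsv")
  if (!file.exists(meta_path)) stop("missing cell_metadata.tsv")
  meta <- read_cell_metadata(meta_path)
  if (anyDuplicated(meta$cell_id)) stop("duplicate cell ids in metadata")
  message(sprintf("validated %s: %d modalities, %d metadata rows",
                  dir, nrow(out), nrow(meta)))
  out
}

#' Read per-cell metadata
#'
#' @param path TSV with header; must contain a `cell_id` column.
#' @return Tibble of metadata.
#' @export
read_cell_metadata <- function(path) {
  x <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                           stringsAsFactors = FALSE))
  stopifnot("cell_id" %in% names(x))
  x
}

#' Write per-cell metadata
#'
#' @param x Metadata tibble with `cell_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_metadata <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# stage logging: dimensions, survivor counts and seeds, switchable via option
epi_log <- function(...) {
  if (isTRUE(getOption("epilineage.verbose", FALSE))) {
    message("[epilineage] ", sprintf(...))
  }
  invisible(NULL)
}
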