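# Count containers and layered-matrix I/O (paired MatrixMarket triplets or
# dense TSV layers), gene sets and the QC filters applied before fitting.

#' Paired spliced/unspliced count dataset
#'
#' @param S,U non-negative integer matrices (cells x genes) of spliced and
#'   unspliced UMI counts, identically shaped and ordered.
#' @param cell_ids,gene_ids optional identifier vectors; defaults are built
#'   from the dimnames or generated.
#' @param batch optional per-cell batch/condition labels (character or factor).
#' @return a `cv_dataset` list with elements `S`, `U`, `cell_ids`, `gene_ids`,
#'   `batch`.
#' @export
count_dataset <- function(S, U, cell_ids = NULL, gene_ids = NULL, batch = NULL) {
  S <- as.matrix(S); U <- as.matrix(U)
  if (!identical(dim(S), dim(U)))
    stop("'S' and 'U' must share dimensions", call. = FALSE)
  if (any(S < 0) || any(U < 0) || any(S != round(S)) || any(U != round(U)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(S) <- "integer"
  storage.mode(U) <- "integer"
  if (is.null(cell_ids)) cell_ids <- rownames(S)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(S)))
  if (is.null(gene_ids)) gene_ids <- colnames(S)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene_%d", seq_len(ncol(S)))
  if (length(cell_ids) != nrow(S) || length(gene_ids) != ncol(S))
    stop("identifier lengths do not match the count matrices", call. = FALSE)
  if (!is.null(batch)) {
    if (length(batch) != nrow(S)) stop("'batch' must have one label per cell")
    batch <- as.character(batch)
  }
  dimnames(S) <- dimnames(U) <- list(cell_ids, gene_ids)
  structure(list(S = S, U = U, cell_ids = cell_ids, gene_ids = gene_ids,
                 batch = batch),
            class = "cv_dataset")
}

#' @export
print.cv_dataset <- function(x, ...) {
  cat(sprintf("cv_dataset: %d cells x %d genes", nrow(x$S), ncol(x$S)))
  if (!is.null(x$batch))
    cat(sprintf(" (%d conditions)", length(unique(x$batch))))
  cat(sprintf("\n  mean spliced %.2f, mean unspliced %.2f UMIs/cell/gene\n",
              mean(x$S), mean(x$U)))
  invisible(x)
}

#' Subset a count dataset
#'
#' @param data a [count_dataset()].
#' @param cells,genes index vectors (integer, logical or identifier).
#' @return the subsetted `cv_dataset`.
#' @export
dataset_subset <- function(data, cells = NULL, genes = NULL) {
  stopifnot(inherits(data, "cv_dataset"))
  if (is.null(cells)) cells <- seq_along(data$cell_ids)
  if (is.null(genes)) genes <- seq_along(data$gene_ids)
  if (is.character(cells)) cells <- match(cells, data$cell_ids)
  if (is.character(genes)) genes <- match(genes, data$gene_ids)
  count_dataset(data$S[cells, , drop = FALSE][, genes, drop = FALSE],
                data$U[cells, , drop = FALSE][, genes, drop = FALSE],
                data$cell_ids[cells], data$gene_ids[genes],
                if (!is.null(data$batch)) data$batch[cells])
}

#' Write a dataset as paired layer files
#'
#' `mtx` writes sparse MatrixMarket triplets (`spliced.mtx`,
#' `unspliced.mtx`) with `genes.tsv` and `cells.tsv` sidecars (cells.tsv
#' carries the batch column when present); `tsv` writes dense tab-separated
#' layers.
#'
#' @param data a [count_dataset()].
#' @param dir output directory (created if missing).
#' @param format `"mtx"` or `"tsv"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir, format = c("mtx", "tsv")) {
  stopifnot(inherits(data, "cv_dataset"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(data$S, sparse = TRUE),
                    file.path(dir, "spliced.mtx"))
    Matrix::writeMM(Matrix::Matrix(data$U, sparse = TRUE),
                    file.path(dir, "unspliced.mtx"))
  } else {
    write.table(data$S, file.path(dir, "spliced.tsv"), sep = "\t", quote = FALSE)
    write.table(data$U, file.path(dir, "unspliced.tsv"), sep = "\t", quote = FALSE)
  }
  writeLines(data$gene_ids, file.path(dir, "genes.tsv"))
  cells <- data.frame(cell_id = data$cell_ids)
  if (!is.null(data$batch)) cells$batch <- data$batch
  write.table(cells, file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a paired spliced/unspliced dataset
#'
#' Reads the layer layout written by [write_dataset()]: `mtx_pair` expects
#' `spliced.mtx` + `unspliced.mtx` plus `genes.tsv`/`cells.tsv` name files;
#' `tsv` expects dense `spliced.tsv`/`unspliced.tsv`.
#'
#' @param dir directory containing the layer files.
#' @param format `"mtx_pair"` or `"tsv"`.
#' @param round round near-integer values instead of erroring on them.
#' @return a [count_dataset()].
#' @export
read_dataset <- function(dir, format = c("mtx_pair", "tsv"), round = FALSE) {
  format <- match.arg(format)
  need <- if (format == "mtx_pair") c("spliced.mtx", "unspliced.mtx")
          else c("spliced.tsv", "unspliced.tsv")
  have <- list.files(dir)
  missing <- setdiff(need, have)
  if (length(missing))
    stop("missing layer file(s) ", paste(missing, collapse = ", "),
         " in ", dir, "; available: ", paste(have, collapse = ", "),
         call. = FALSE)
  if (format == "mtx_pair") {
    S <- as.matrix(Matrix::readMM(file.path(dir, "spliced.mtx")))
    U <- as.matrix(Matrix::readMM(file.path(dir, "unspliced.mtx")))
  } else {
    S <- as.matrix(read.delim(file.path(dir, "spliced.tsv")))
    U <- as.matrix(read.delim(file.path(dir, "unspliced.tsv")))
  }
  if (!identical(dim(S), dim(U)))
    stop("spliced and unspliced layers disagree on shape", call. = FALSE)
  gene_ids <- cell_ids <- batch <- NULL
  gf <- file.path(dir, "genes.tsv")
  if (file.exists(gf)) {
    gene_ids <- readLines(gf)
    if (length(gene_ids) != ncol(S))
      stop("genes.tsv lists ", length(gene_ids), " genes but layers have ",
           ncol(S), " columns", call. = FALSE)
  }
  cf <- file.path(dir, "cells.tsv")
  if (file.exists(cf)) {
    cells <- read.delim(cf)
    cell_ids <- as.character(cells$cell_id)
    if ("batch" %in% names(cells)) batch <- as.character(cells$batch)
  }
  if (any(abs(S - round(S)) > 0) || any(abs(U - round(U)) > 0)) {
    if (!round) stop("layers contain non-integer values; use round = TRUE")
    S <- round(S); U <- round(U)
  }
  count_dataset(S, U, cell_ids, gene_ids, batch)
}

#' Cycling gene sets
#'
#' The `small` set (97 genes: 43 S-phase + 54 G2/M markers) is resolved from
#' the marker lists bundled with Seurat, the same literature source commonly
#' used for cell cycle scoring. Larger curated sets are not shipped; supply
#' them as `custom` with a character vector or a one-symbol-per-line file.
#'
#' @param name `"small"` or `"custom"`.
#' @param genes character vector or path to a gene-list file (for `custom`).
#' @param species `"human"` (upper-case symbols) or `"mouse"` (title case).
#' @return a `cv_gene_set` list with `name` and `genes`.
#' @export
get_gene_set <- function(name = c("small", "custom"), genes = NULL,
                         species = c("human", "mouse")) {
  name <- match.arg(name)
  species <- match.arg(species)
  if (name == "small") {
    if (!requireNamespace("Seurat", quietly = TRUE))
      stop("the 'small' gene set requires the Seurat package; ",
           "supply a custom list otherwise", call. = FALSE)
    cc <- Seurat::cc.genes
    genes <- unique(c(cc$s.genes, cc$g2m.genes))
  } else {
    if (is.null(genes)) stop("'custom' gene sets need a 'genes' argument")
    if (length(genes) == 1 && file.exists(genes)) genes <- readLines(genes)
  }
  genes <- unique(format_gene_case(genes, species))
  if (!length(genes)) stop("gene set is empty", call. = FALSE)
  structure(list(name = name, genes = genes), class = "cv_gene_set")
}

#' Species-specific gene-symbol casing
#'
#' @param genes character vector of symbols.
#' @param species `"human"` (all upper) or `"mouse"` (title case).
#' @return recased symbols.
#' @export
format_gene_case <- function(genes, species = c("human", "mouse")) {
  species <- match.arg(species)
  if (species == "human") toupper(genes)
  else paste0(toupper(substr(genes, 1, 1)), tolower(substring(genes, 2)))
}

#' Mean-expression gene filters
#'
#' Restricts to a gene set (matched case-insensitively) and removes genes at
#' or below the mean-UMI thresholds: a gene is kept when mean unspliced
#' `> min_mean_u` AND mean spliced `> min_mean_s` (boundary values removed).
#'
#' @param data a [count_dataset()].
#' @param gene_set optional [get_gene_set()] or character vector.
#' @param min_mean_u,min_mean_s non-negative mean-UMI thresholds.
#' @return list with the filtered `data` and a `report` (class
#'   `cv_filter_report`).
#' @export
filter_genes <- function(data, gene_set = NULL, min_mean_u = 0.1,
                         min_mean_s = 0.3) {
  stopifnot(inherits(data, "cv_dataset"), min_mean_u >= 0, min_mean_s >= 0)
  n_input <- length(data$gene_ids)
  keep <- rep(TRUE, n_input)
  if (!is.null(gene_set)) {
    genes <- if (inherits(gene_set, "cv_gene_set")) gene_set$genes else gene_set
    keep <- toupper(data$gene_ids) %in% toupper(genes)
  }
  n_set <- sum(keep)
  mu_u <- colMeans(data$U); mu_s <- colMeans(data$S)
  keep <- keep & mu_u > min_mean_u & mu_s > min_mean_s
  n_mean <- sum(keep)
  if (n_mean == 0)
    stop("no genes survive filtering; lower min_mean_u/min_mean_s ",
         "or check the gene set", call. = FALSE)
  report <- structure(list(n_input_genes = n_input,
                           n_after_set_intersection = n_set,
                           n_after_mean_filters = n_mean,
                           n_after_correlation_delay_filters = NA_integer_,
                           min_mean_u = min_mean_u, min_mean_s = min_mean_s),
                      class = "cv_filter_report")
  list(data = dataset_subset(data, genes = which(keep)), report = report)
}

#' @export
print.cv_filter_report <- function(x, ...) {
  cat("gene filter report:\n")
  cat(sprintf("  input genes              %d\n", x$n_input_genes))
  cat(sprintf("  after gene-set match     %d\n", x$n_after_set_intersection))
  cat(sprintf("  after mean-UMI filters   %d  (U > %.3g, S > %.3g)\n",
              x$n_after_mean_filters, x$min_mean_u, x$min_mean_s))
  if (!is.na(x$n_after_correlation_delay_filters))
    cat(sprintf("  after corr/delay filters %d\n",
                x$n_after_correlation_delay_filters))
  invisible(x)
}

#' Fit-based gene filters
#'
#' After an initial manifold-learning pass on spliced and unspliced counts,
#' keeps genes whose fitted unspliced and spliced expectation curves are
#' strongly correlated along the phase grid and whose unspliced-spliced delay
#' is not strongly negative. Genes with near-zero first-harmonic amplitude
#' (undefined peak phase) are removed first.
#'
#' @param data a [count_dataset()] (gene order matching the fits).
#' @param manifold_s,manifold_u manifold fits on spliced counts and on
#'   unspliced counts (phases conditioned on the spliced fit).
#' @param min_us_corr Pearson correlation floor for the expectation curves.
#' @param min_delay delay floor in radians (genes below it are removed).
#' @param min_amplitude first-harmonic amplitude below which a gene's peak is
#'   treated as undefined.
#' @param use correlate fitted expectation curves on a phase grid
#'   (`"expectation"`, default) or the raw count matrices (`"raw"`).
#' @return list of filtered `data` and `report`.
#' @export
filter_by_fit <- function(data, manifold_s, manifold_u, min_us_corr = 0.8,
                          min_delay = -0.25, min_amplitude = 0.05,
                          use = c("expectation", "raw")) {
  stopifnot(inherits(data, "cv_dataset"))
  use <- match.arg(use)
  dl <- us_delays(manifold_s, manifold_u, min_amplitude = min_amplitude)
  if (use == "expectation") {
    grid <- seq(0, 2 * pi, length.out = 64)
    es <- log(expected_spliced(grid, manifold_s$nu_loc))
    eu <- log(expected_spliced(grid, manifold_u$nu_loc))
    us_corr <- vapply(seq_len(ncol(es)),
                      function(j) suppressWarnings(cor(es[, j], eu[, j])),
                      numeric(1))
  } else {
    us_corr <- vapply(seq_len(ncol(data$S)),
                      function(j) suppressWarnings(cor(data$S[, j], data$U[, j])),
                      numeric(1))
  }
  us_corr[is.na(us_corr)] <- -Inf
  keep <- dl$defined & us_corr >= min_us_corr &
    (!is.na(dl$delay) & dl$delay >= min_delay)
  if (!any(keep))
    stop("no genes survive the correlation/delay filters", call. = FALSE)
  report <- structure(list(n_input_genes = length(keep),
                           n_after_set_intersection = length(keep),
                           n_after_mean_filters = length(keep),
                           n_after_correlation_delay_filters = sum(keep),
                           min_us_corr = min_us_corr, min_delay = min_delay),
                      class = "cv_filter_report")
  list(data = dataset_subset(data, genes = which(keep)), report = report)
}
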