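#' Cell-level count container for a cytokine stimulation screen
#'
#' `CellCounts` bundles a sparse cells-by-genes integer count matrix with
#' the per-cell metadata the pipeline needs: donor, cell type, stimulation
#' condition (a cytokine name or `"PBS"`), the PBS well index (1..6, for
#' PBS cells), and the plate row of the well. Extra metadata columns
#' (e.g. a precomputed mitochondrial fraction) are carried along.
#'
#' @param counts cells x genes matrix (dense or `Matrix` sparse) of
#'   non-negative integers.
#' @param meta data.frame with one row per cell; required columns
#'   `donor`, `cell_type`, `condition`; `pbs_well` (1..6) required for
#'   PBS cells; `plate_row` optional (needed for abundance testing).
#' @param genes character vector of unique gene identifiers, one per
#'   column of `counts`.
#' @return An object of class `CellCounts`.
#' @export
CellCounts <- function(counts, meta, genes = colnames(counts)) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(genes)) stop("gene identifiers are required")
  genes <- as.character(genes)
  if (ncol(counts) != length(genes))
    stop("gene list length does not match count matrix columns")
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  if (nrow(counts) != nrow(meta))
    stop(sprintf("metadata rows (%d) do not match count matrix cells (%d)",
                 nrow(meta), nrow(counts)))
  req <- c("donor", "cell_type", "condition")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("missing column: ", paste(miss, collapse = ", "))
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integers")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  is_pbs <- meta$condition == "PBS"
  if (any(is_pbs)) {
    if (!"pbs_well" %in% names(meta))
      stop("missing column: pbs_well (required for PBS cells)")
    w <- meta$pbs_well[is_pbs]
    if (any(is.na(w)) || any(!w %in% seq_len(max(6, max(w)))))
      stop("every PBS cell needs a well index in 1..6")
  }
  colnames(counts) <- genes
  rownames(counts) <- rownames(meta) <- meta[["cell"]] %||%
    sprintf("cell%06d", seq_len(nrow(meta)))
  structure(list(counts = counts, meta = meta, genes = genes),
            class = "CellCounts")
}

#' @export
print.CellCounts <- function(x, ...) {
  cat(sprintf("CellCounts: %d cells x %d genes\n", nrow(x$counts),
              length(x$genes)))
  cat(sprintf("  donors: %d | cell types: %d | conditions: %d\n",
              length(unique(x$meta$donor)),
              length(unique(x$meta$cell_type)),
              length(unique(x$meta$condition))))
  invisible(x)
}

#' @export
dim.CellCounts <- function(x) dim(x$counts)

#' Subset a CellCounts object by cells
#'
#' @param cc a `CellCounts` object.
#' @param cells logical or integer index over cells.
#' @return The subsetted `CellCounts`.
#' @export
subset_cells <- function(cc, cells) {
  stopifnot(inherits(cc, "CellCounts"))
  structure(list(counts = cc$counts[cells, , drop = FALSE],
                 meta = cc$meta[cells, , drop = FALSE],
                 genes = cc$genes),
            class = "CellCounts")
}

#' Read a count matrix triplet (MTX + metadata CSV + gene CSV)
#'
#' Reads the sparse-matrix triplet layout emitted by combinatorial
#' barcoding pipelines: a Matrix Market coordinate file plus one CSV of
#' per-cell metadata and one CSV (single column or `gene` column) of gene
#' identifiers. Orientation is auto-detected from the metadata/gene list
#' lengths and normalised to cells-as-rows.
#'
#' @param dir directory containing the triplet, or `NULL` when the three
#'   paths are given explicitly.
#' @param mtx,meta,genes explicit file paths (default the split-pipe
#'   names `count_matrix.mtx`, `cell_metadata.csv`, `all_genes.csv`
#'   under `dir`).
#' @return A validated [CellCounts] object.
#' @export
read_counts <- function(dir = NULL,
                        mtx = file.path(dir, "count_matrix.mtx"),
                        meta = file.path(dir, "cell_metadata.csv"),
                        genes = file.path(dir, "all_genes.csv")) {
  for (f in c(mtx, meta, genes))
    if (!file.exists(f)) stop("file not found: ", f)
  m <- Matrix::readMM(mtx)
  md <- utils::read.csv(meta, stringsAsFactors = FALSE)
  gn <- utils::read.csv(genes, stringsAsFactors = FALSE)
  gn <- if ("gene" %in% names(gn)) gn$gene else gn[[1]]
  n_cells <- nrow(md); n_genes <- length(gn)
  if (nrow(m) == n_cells && ncol(m) == n_genes) {
    # cells x genes, as expected
  } else if (nrow(m) == n_genes && ncol(m) == n_cells) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(paste0("dimension mismatch in %s: matrix is %dx%d but ",
                        "metadata has %d cells and gene list %d genes"),
                 mtx, nrow(m), ncol(m), n_cells, n_genes))
  }
  CellCounts(m, md, gn)
}

#' Write a CellCounts object as an MTX triplet
#'
#' Inverse of [read_counts]; writes `count_matrix.mtx`,
#' `cell_metadata.csv` and `all_genes.csv` into `dir`.
#'
#' @param cc a `CellCounts` object.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(cc, dir) {
  stopifnot(inherits(cc, "CellCounts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cc$counts, file.path(dir, "count_matrix.mtx"))
  utils::write.csv(cc$meta, file.path(dir, "cell_metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(gene = cc$genes),
                   file.path(dir, "all_genes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Gene annotation table
#'
#' Per-gene boolean flags used by the donor-baseline gene filter:
#' protein-coding, ribosomal, mitochondrial, sex-chromosome (X/Y).
#' Genes absent from the table look up as all-false with a warning.
#'
#' @param gene character vector of gene ids.
#' @param protein_coding,ribosomal,mitochondrial,sex_chromosome logical
#'   vectors recycled against `gene`.
#' @return data.frame of class `GeneAnnotation`.
#' @export
gene_annotation <- function(gene, protein_coding = TRUE, ribosomal = FALSE,
                            mitochondrial = FALSE, sex_chromosome = FALSE) {
  ann <- data.frame(gene = as.character(gene),
                    protein_coding = as.logical(protein_coding),
                    ribosomal = as.logical(ribosomal),
                    mitochondrial = as.logical(mitochondrial),
                    sex_chromosome = as.logical(sex_chromosome),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$gene)) stop("gene ids must be unique")
  class(ann) <- c("GeneAnnotation", "data.frame")
  ann
}

# Look up annotation rows for `genes`; missing genes get all-false flags.
lookup_annotation <- function(ann, genes) {
  idx <- match(genes, ann$gene)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " genes missing from annotation; ",
            "treated as all-false")
  }
  out <- data.frame(gene = genes, protein_coding = FALSE, ribosomal = FALSE,
                    mitochondrial = FALSE, sex_chromosome = FALSE,
                    stringsAsFactors = FALSE)
  hit <- !is.na(idx)
  out[hit, -1] <- ann[idx[hit], c("protein_coding", "ribosomal",
                                  "mitochondrial", "sex_chromosome")]
  out
}

#' Quality-control filter on cells
#'
#' Removes low-quality cells by three thresholds: a cell must have at
#' least `min_genes` and at most `max_genes` detected genes, and strictly
#' less than `max_mito` fraction of counts from mitochondrial genes.
#' Mitochondrial genes are taken from `ann` when supplied, otherwise by
#' the conventional `"MT-"` name prefix.
#'
#' @param cc a [CellCounts] object.
#' @param min_genes minimum detected genes (inclusive), default 400.
#' @param max_genes maximum detected genes (inclusive), default 7000.
#' @param max_mito mitochondrial-content bound (exclusive), default 0.15.
#' @param ann optional [gene_annotation] table.
#' @return Filtered `CellCounts`; removal counts per criterion are
#'   attached as attribute `"qc_removed"`.
#' @export
qc_filter <- function(cc, min_genes = 400, max_genes = 7000,
                      max_mito = 0.15, ann = NULL) {
  stopifnot(inherits(cc, "CellCounts"))
  detected <- Matrix::rowSums(cc$counts > 0)
  mito_genes <- if (!is.null(ann)) {
    lookup_annotation(ann, cc$genes)$mitochondrial
  } else {
    startsWith(cc$genes, "MT-")
  }
  tot <- Matrix::rowSums(cc$counts)
  mito_frac <- if (any(mito_genes)) {
    Matrix::rowSums(cc$counts[, mito_genes, drop = FALSE]) / pmax(tot, 1)
  } else rep(0, nrow(cc$counts))
  low  <- detected < min_genes
  high <- detected > max_genes
  mito <- mito_frac >= max_mito
  keep <- !(low | high | mito)
  if (!any(keep)) stop("no cells pass QC")
  cd_log("qc_filter: removed %d low-gene, %d high-gene, %d high-mito cells",
         sum(low), sum(high), sum(mito))
  out <- subset_cells(cc, keep)
  attr(out, "qc_removed") <- c(low_genes = sum(low), high_genes = sum(high),
                               high_mito = sum(mito))
  out
}
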