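#' Configuration for the synthetic cytokine-screen generator
#'
#' Builds the configuration for [simulate_screen]. Defaults emulate one
#' donor cohort of the kind this pipeline targets: 12 donors, 12 PBMC
#' cell types, a panel of cytokine stimulations plus six PBS control
#' wells per donor, negative-binomial counts over a few hundred genes.
#' Effects are planted declaratively and are returned as ground truth.
#'
#' @param n_donors number of donors (12).
#' @param n_celltypes number of cell types (12).
#' @param cytokines character vector of cytokine condition names.
#' @param n_pbs_wells PBS control wells per donor (6).
#' @param n_genes panel size (200).
#' @param cells_per_group expected cells per (donor, cell type, well)
#'   (20; realised counts are Poisson).
#' @param depth_mean mean UMI depth per cell (5000, lognormal sdlog 0.3).
#' @param dispersion NB dispersions (1/size) for the two gene classes,
#'   `c(housekeeping = 0.2, responsive = 0.4)`.
#' @param well_effect_sd sdlog of the multiplicative per-(PBS well, gene)
#'   plate artifact (0.05).
#' @param effect_gene_cpm baseline cpm pinned for planted response genes
#'   (300); keeps planted effects a small share of the library so they do
#'   not perturb the cpm composition of the rest of the panel.
#' @param effects list of planted responses, each
#'   `list(cytokine, genes, lfc, cell_types = NULL, donors = NULL)`;
#'   `cell_types = NULL` means all cell types (subject to receptor
#'   gating), `donors = NULL` means all donors. `lfc` is recycled over
#'   `genes`.
#' @param donor_group optional baseline shift for a donor subset:
#'   `list(donors, genes, lfc)` applied in every condition (emulating an
#'   interferon-high donor group).
#' @param receptors optional receptor gating:
#'   `list(<cytokine> = list(genes, cpm_by_celltype))` where
#'   `cpm_by_celltype` is a named numeric vector of baseline receptor
#'   cpm; the cytokine's responses fire only in cell types whose
#'   receptor cpm is at least `receptor_gate`.
#' @param receptor_gate minimum receptor cpm for a response (8).
#' @param cytokine_genes optional named list mapping cytokines to their
#'   encoding gene(s) in the panel.
#' @param cytokine_gene_cpm baseline cpm of cytokine-encoding genes (20;
#'   low but detectable, so production responses can clear the
#'   detection filter).
#' @param cascade optional secondary-response cascade:
#'   `list(primary, secondary, production_lfc = 2)`. Under stimulation
#'   with `primary`, primary-target cell types upregulate `secondary`'s
#'   encoding gene by `production_lfc`, and cell types gated for
#'   `secondary` (but not for `primary`) receive `secondary`'s planted
#'   effect profile.
#' @param well_artifacts list of planted plate artifacts, each
#'   `list(genes, wells, lfc)`, applied in the listed PBS wells only.
#' @param abundance_effects list of planted cell-recovery changes, each
#'   `list(cell_type, cytokine, log2fc)`.
#' @param similarity_groups optional named integer vector labelling
#'   cytokines with their planted response-similarity group.
#' @param seed mandatory RNG seed.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_donors = 12, n_celltypes = 12,
                       cytokines = paste0("CK", 1:10),
                       n_pbs_wells = 6, n_genes = 200,
                       cells_per_group = 20, depth_mean = 5000,
                       dispersion = c(housekeeping = 0.2, responsive = 0.4),
                       well_effect_sd = 0.05, effect_gene_cpm = 300,
                       effects = list(), donor_group = NULL,
                       receptors = NULL, receptor_gate = 8,
                       cytokine_genes = NULL, cytokine_gene_cpm = 20,
                       cascade = NULL, well_artifacts = list(),
                       abundance_effects = list(),
                       similarity_groups = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(cells_per_group >= 1, n_pbs_wells >= 1)
  for (e in effects)
    if (!all(is.finite(e$lfc))) stop("planted log2FCs must be finite")
  cfg <- list(n_donors = n_donors, n_celltypes = n_celltypes,
              cytokines = cytokines, n_pbs_wells = n_pbs_wells,
              n_genes = n_genes, cells_per_group = cells_per_group,
              depth_mean = depth_mean, dispersion = dispersion,
              well_effect_sd = well_effect_sd,
              effect_gene_cpm = effect_gene_cpm, effects = effects,
              donor_group = donor_group, receptors = receptors,
              receptor_gate = receptor_gate,
              cytokine_genes = cytokine_genes,
              cytokine_gene_cpm = cytokine_gene_cpm, cascade = cascade,
              well_artifacts = well_artifacts,
              abundance_effects = abundance_effects,
              similarity_groups = similarity_groups, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

# cell types gated for a cytokine: all when no receptor spec, else those
# whose receptor baseline cpm meets the gate
gated_celltypes <- function(cfg, cytokine, cell_types) {
  r <- cfg$receptors[[cytokine]]
  if (is.null(r)) return(cell_types)
  on <- r$cpm_by_celltype[cell_types]
  cell_types[!is.na(on) & on >= cfg$receptor_gate]
}

#' Simulate a multi-donor cytokine stimulation screen
#'
#' Draws negative-binomial counts for every (donor, cell type, well)
#' group. Gene baselines are lognormal with mild cell-type variation;
#' planted effects multiply the expected cpm by `2^lfc` where they
#' apply; PBS wells carry multiplicative lognormal plate artifacts
#' shared across donors. Deterministic under the config seed.
#'
#' @param cfg a [sim_config] object.
#' @return `list(cells = CellCounts, truth = GroundTruth)` where the
#'   ground truth records planted DEG sets, donor groups, secondary
#'   edges, similarity groups, expected baseline cpm and the config.
#' @export
simulate_screen <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  donors <- sprintf("D%02d", seq_len(cfg$n_donors))
  cts <- sprintf("CT%02d", seq_len(cfg$n_celltypes))
  cyts <- cfg$cytokines

  # check planted genes exist
  all_eff_genes <- unlist(c(lapply(cfg$effects, `[[`, "genes"),
                            lapply(cfg$well_artifacts, `[[`, "genes"),
                            if (!is.null(cfg$donor_group))
                              list(cfg$donor_group$genes)))
  if (length(bad <- setdiff(all_eff_genes, genes)))
    stop("planted effect on gene(s) absent from panel: ",
         paste(bad, collapse = ", "))

  # baselines: per-gene lognormal, mild per-cell-type variation
  base <- stats::rlnorm(cfg$n_genes, log(50), 1.2)
  basemat <- matrix(base, cfg$n_genes, cfg$n_celltypes) *
    matrix(stats::rlnorm(cfg$n_genes * cfg$n_celltypes, 0, 0.3),
           cfg$n_genes, cfg$n_celltypes)
  dimnames(basemat) <- list(genes, cts)
  basemat <- sweep(basemat, 2, colSums(basemat), "/") * 1e6
  # response genes pinned to a moderate cpm so planted effects stay a
  # small share of the library and do not shift the cpm composition of
  # the remaining panel
  resp_genes <- unique(unlist(lapply(cfg$effects, `[[`, "genes")))
  basemat[match(resp_genes, genes), ] <- cfg$effect_gene_cpm
  # receptor genes pinned to their configured per-cell-type cpm
  for (cy in names(cfg$receptors)) {
    r <- cfg$receptors[[cy]]
    for (g in r$genes)
      basemat[g, names(r$cpm_by_celltype)] <- r$cpm_by_celltype
  }
  # cytokine-encoding genes: low but detectable unless receptor-pinned
  pinned <- unlist(lapply(cfg$receptors, `[[`, "genes"))
  for (gset in cfg$cytokine_genes)
    basemat[setdiff(gset, pinned), ] <- cfg$cytokine_gene_cpm
  basemat <- sweep(basemat, 2, colSums(basemat), "/") * 1e6

  responsive <- unique(all_eff_genes)
  size_g <- ifelse(genes %in% responsive,
                   1 / cfg$dispersion[["responsive"]],
                   1 / cfg$dispersion[["housekeeping"]])

  # per-(PBS well, gene) plate artifact, shared across donors
  well_fac <- matrix(stats::rlnorm(cfg$n_pbs_wells * cfg$n_genes, 0,
                                   cfg$well_effect_sd),
                     cfg$n_pbs_wells, cfg$n_genes)
  for (wa in cfg$well_artifacts)
    well_fac[wa$wells, match(wa$genes, genes)] <-
      well_fac[wa$wells, match(wa$genes, genes), drop = FALSE] * 2^wa$lfc

  conditions <- c(paste0("PBS", seq_len(cfg$n_pbs_wells)), cyts)
  plate_rows <- rep(1:8, length.out = length(conditions))
  names(plate_rows) <- conditions

  # expected-lfc modifier for one (donor, ct, condition)
  lfc_vec <- function(donor, ct, cond) {
    lfc <- numeric(cfg$n_genes)
    dg <- cfg$donor_group
    if (!is.null(dg) && donor %in% dg$donors)
      lfc[match(dg$genes, genes)] <- lfc[match(dg$genes, genes)] + dg$lfc
    if (!startsWith(cond, "PBS")) {
      for (e in cfg$effects) {
        if (e$cytokine != cond) next
        tgt <- e$cell_types %||% gated_celltypes(cfg, cond, cts)
        if (!ct %in% tgt) next
        if (!is.null(e$donors) && !donor %in% e$donors) next
        idx <- match(e$genes, genes)
        lfc[idx] <- lfc[idx] + rep_len(e$lfc, length(idx))
      }
      ca <- cfg$cascade
      if (!is.null(ca) && cond == ca$primary) {
        prim_tgt <- gated_celltypes(cfg, ca$primary, cts)
        sec_tgt <- setdiff(gated_celltypes(cfg, ca$secondary, cts), prim_tgt)
        if (ct %in% prim_tgt) {
          pg <- cfg$cytokine_genes[[ca$secondary]]
          idx <- match(pg, genes)
          lfc[idx] <- lfc[idx] + (ca$production_lfc %||% 2)
        }
        if (ct %in% sec_tgt) {
          for (e in cfg$effects) {
            if (e$cytokine != ca$secondary) next
            idx <- match(e$genes, genes)
            lfc[idx] <- lfc[idx] + rep_len(e$lfc, length(idx))
          }
        }
      }
    }
    lfc
  }

  blocks <- list(); metas <- list()
  for (d in donors) for (ct in cts) for (cond in conditions) {
    is_pbs <- startsWith(cond, "PBS")
    wellno <- if (is_pbs) as.integer(sub("PBS", "", cond)) else NA_integer_
    mu <- basemat[, ct] * 2^lfc_vec(d, ct, cond)
    if (is_pbs) mu <- mu * well_fac[wellno, ]
    n_target <- cfg$cells_per_group
    if (!is_pbs) for (ab in cfg$abundance_effects)
      if (ab$cell_type == ct && ab$cytokine == cond)
        n_target <- n_target * 2^ab$log2fc
    n <- stats::rpois(1, n_target)
    if (n == 0) next
    depth <- stats::rlnorm(n, log(cfg$depth_mean) - 0.3^2 / 2, 0.3)
    p <- mu / sum(mu)
    mumat <- outer(depth, p)  # n x genes
    cnt <- matrix(stats::rnbinom(n * cfg$n_genes, mu = as.vector(mumat),
                                 size = rep(size_g, each = n)),
                  n, cfg$n_genes)
    blocks[[length(blocks) + 1L]] <- methods::as(Matrix::Matrix(
      cnt, sparse = TRUE), "CsparseMatrix")
    metas[[length(metas) + 1L]] <- data.frame(
      donor = d, cell_type = ct,
      condition = if (is_pbs) "PBS" else cond,
      pbs_well = wellno, plate_row = plate_rows[[cond]],
      stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, blocks)
  meta <- do.call(rbind, metas[rep(seq_along(metas),
                                   vapply(blocks, nrow, 0L))])
  rownames(meta) <- NULL
  cells <- CellCounts(counts, meta, genes)

  # ground truth: expand planted DEG table with receptor gating applied
  degs <- list()
  for (e in cfg$effects) {
    tgt <- e$cell_types %||% gated_celltypes(cfg, e$cytokine, cts)
    if (!is.null(e$donors) && length(e$donors) < cfg$n_donors / 2)
      next  # minority-donor effects are not consensus DEGs
    for (ct in tgt)
      degs[[length(degs) + 1L]] <- data.frame(
        cell_type = ct, cytokine = e$cytokine, gene = e$genes,
        lfc = rep_len(e$lfc, length(e$genes)), stringsAsFactors = FALSE)
  }
  degs <- if (length(degs)) unique(do.call(rbind, degs)) else
    data.frame(cell_type = character(0), cytokine = character(0),
               gene = character(0), lfc = numeric(0))
  secondary <- NULL
  if (!is.null(cfg$cascade)) {
    ca <- cfg$cascade
    prim_tgt <- gated_celltypes(cfg, ca$primary, cts)
    sec_tgt <- setdiff(gated_celltypes(cfg, ca$secondary, cts), prim_tgt)
    if (length(sec_tgt))
      secondary <- data.frame(primary = ca$primary,
                              secondary = ca$secondary,
                              cell_type = sec_tgt, stringsAsFactors = FALSE)
  }
  truth <- structure(list(
    degs = degs,
    donor_group = cfg$donor_group$donors,
    secondary_edges = secondary,
    similarity_groups = cfg$similarity_groups,
    baseline_cpm = basemat,
    genes = genes, donors = donors, cell_types = cts,
    config = cfg), class = "GroundTruth")
  list(cells = cells, truth = truth)
}

#' Recovery metrics against planted ground truth
#'
#' Precision/recall of a called set of (key, ...) rows against the
#' planted set, matched on the shared columns.
#'
#' @param truth,called data.frames with identical key columns.
#' @param by key columns to match on (default the intersection).
#' @return `list(precision, recall, n_truth, n_called)`.
#' @export
recovery_metrics <- function(truth, called,
                             by = intersect(names(truth), names(called))) {
  if (!length(by)) stop("no shared key columns between truth and result")
  tk <- do.call(paste, c(truth[by], sep = "\r"))
  ck <- do.call(paste, c(called[by], sep = "\r"))
  tp <- sum(ck %in% tk)
  list(precision = if (length(ck)) tp / length(ck) else NA_real_,
       recall = if (length(tk)) sum(tk %in% ck) / length(tk) else NA_real_,
       n_truth = length(tk), n_called = length(ck))
}

#' Adjusted Rand index between two partitions
#'
#' Thin wrapper over `mclust::adjustedRandIndex` matching elements by
#' name when both labellings are named.
#'
#' @param truth,called cluster label vectors.
#' @return The adjusted Rand index.
#' @export
partition_ari <- function(truth, called) {
  if (!is.null(names(truth)) && !is.null(names(called))) {
    shared <- intersect(names(truth), names(called))
    if (!length(shared)) stop("no shared identifiers between partitions")
    truth <- truth[shared]; called <- called[shared]
  }
  if (length(truth) != length(called)) stop("partition length mismatch")
  mclust::adjustedRandIndex(truth, called)
}
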