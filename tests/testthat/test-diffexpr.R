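test_that("de_consensus: identical conditions give zero log2FC and no
           DEGs; label swap negates log2FC and preserves p", {
  genes <- sprintf("g%d", 1:5)
  raw <- matrix(rep(c(100, 200, 50, 10, 640), 6), 6, 5, byrow = TRUE,
                dimnames = list(NULL, genes))
  keys <- data.frame(donor = rep(c("D1", "D2", "D3"), each = 2),
                     cell_type = "T",
                     condition = rep(c("PBS", "CKA"), 3),
                     pbs_well = rep(c(1L, NA), 3))
  pb <- manual_pb(keys, raw)
  res <- de_consensus(pb, "T", "CKA")
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$p == 1))

  # asymmetric counts: swapping condition labels negates the estimate
  raw2 <- raw
  raw2[keys$condition == "CKA", 1] <- c(400, 380, 420)
  pb2 <- manual_pb(keys, raw2)
  keys_sw <- keys
  keys_sw$condition <- ifelse(keys$condition == "PBS", "CKA", "PBS")
  keys_sw$pbs_well <- rep(c(NA, 1L), 3)
  pb_sw <- manual_pb(keys_sw, raw2)
  a <- de_consensus(pb2, "T", "CKA")
  b <- de_consensus(pb_sw, "T", "CKA")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("donors below the 10-cell filter are excluded and fewer than
           two qualifying donors skips the contrast", {
  genes <- c("g1", "g2")
  keys <- data.frame(donor = rep(c("D1", "D2", "D3"), each = 2),
                     cell_type = "T",
                     condition = rep(c("PBS", "CKA"), 3),
                     pbs_well = rep(c(1L, NA), 3))
  raw <- matrix(100, 6, 2, dimnames = list(NULL, genes))
  # D3's PBS pseudobulk has only 9 cells
  n_cells <- c(100L, 100L, 100L, 100L, 9L, 100L)
  pb <- manual_pb(keys, raw, n_cells = n_cells)
  res <- de_consensus(pb, "T", "CKA")
  expect_equal(unique(res$n_donors), 2L)
  # two donors below the filter -> skip
  n_cells2 <- c(100L, 100L, 9L, 100L, 9L, 100L)
  expect_null(de_consensus(manual_pb(keys, raw, n_cells = n_cells2),
                           "T", "CKA"))
})

test_that("the 5%-of-cells detection filter drops unexpressed genes", {
  genes <- c("g1", "g2")
  keys <- data.frame(donor = rep(c("D1", "D2"), each = 2),
                     cell_type = "T",
                     condition = rep(c("PBS", "CKA"), 2),
                     pbs_well = rep(c(1L, NA), 2))
  raw <- matrix(c(100, 2, 100, 2, 100, 2, 100, 2), 4, 2, byrow = TRUE,
                dimnames = list(NULL, genes))
  # g2 detected in 2% of cells in both conditions
  n_expr <- cbind(g1 = rep(90, 4), g2 = rep(2, 4))
  pb <- manual_pb(keys, raw, n_cells = rep(100L, 4), n_expr = n_expr)
  res <- de_consensus(pb, "T", "CKA")
  expect_equal(res$gene, "g1")
})

test_that("planted effects are recovered with calibrated log2FC and
           the DEG rule reaches precision/recall >= 0.9", {
  sim <- basic_sim()
  dg <- deg_sets(sim$det)
  m <- recovery_metrics(sim$truth$degs, dg,
                        by = c("cell_type", "cytokine", "gene"))
  expect_gte(m$precision, 0.9)
  expect_gte(m$recall, 0.9)
  # upregulated planted genes: estimate within +-0.3 of truth
  up <- sim$truth$degs[sim$truth$degs$lfc > 0, ]
  mm <- merge(sim$det, up, by = c("cell_type", "cytokine", "gene"))
  expect_true(all(abs(mm$log2fc - mm$lfc) < 0.3))
  expect_true(all(mm$padj < 0.05))
})

test_that("per-well support counts wells passing the well-level DE rule
           and is invariant to well order", {
  sim <- basic_sim()
  pws <- per_well_support(sim$pb, "CT01", "CK1")
  planted <- sprintf("G%03d", 1:10)
  expect_true(all(pws$wells_supported[planted] >= 4))
  expect_equal(pws$n_wells_available, 6L)
  # unperturbed genes rarely gain full support
  others <- setdiff(names(pws$wells_supported), planted)
  expect_lt(mean(pws$wells_supported[others] >= 4), 0.05)
})

test_that("a gene shifted in only two PBS wells gains at most two wells
           of support and is excluded from DEGs", {
  cfg <- sim_config(
    n_donors = 12, n_celltypes = 1, cytokines = "CKA", n_genes = 150,
    cells_per_group = 20,
    well_artifacts = list(list(genes = "G140", wells = c(1, 2),
                               lfc = 1.5)),
    seed = 13)
  sim <- simulate_screen(cfg)
  pb <- pseudobulk(sim$cells)
  pws <- per_well_support(pb, "CT01", "CKA")
  expect_lte(pws$wells_supported[["G140"]], 2)
  det <- de_table(pb)
  expect_false(any(det$is_deg[det$gene == "G140"]))
})

test_that("ratio_filter matches direct arithmetic and escalates
           across cytokines and cell types", {
  base <- data.frame(gene = "g1", cell_type = "T", cytokine = "CKA",
                     log2fc = 1, p = 0.01, padj = 0.01,
                     wells_supported = 6L, n_wells_available = 6L)
  wl <- function(v) setNames(as.list(v), paste0("lfc_w", 1:6))
  d1 <- cbind(base, wl(rep(1, 6)))
  expect_equal(ratio_filter(d1)$ratio, 0)
  expect_false(ratio_filter(d1)$high_ratio)

  alt <- c(2, -2, 2, -2, 2, -2)
  d2 <- cbind(base, wl(alt))
  expect_equal(ratio_filter(d2)$ratio, oracle_ratio(alt))
  expect_equal(ratio_filter(d2)$ratio, sd(alt) / 0.25)
  expect_true(ratio_filter(d2)$high_ratio)

  # escalation: high in 10 cytokines in each of 5 cell types -> removed
  grid <- expand.grid(cytokine = paste0("CK", 1:10),
                      cell_type = paste0("T", 1:5),
                      stringsAsFactors = FALSE)
  det <- cbind(gene = "g1", grid, log2fc = 1, p = 0.01, padj = 0.01,
               wells_supported = 6L, n_wells_available = 6L, wl(alt))
  out <- ratio_filter(det)
  expect_true(all(out$removed_by_ratio))
  # one cell type short of the gate -> kept
  out2 <- ratio_filter(det[det$cell_type != "T5", ])
  expect_false(any(out2$removed_by_ratio))
})

test_that("call_degs applies the joint padj / lfc / wells rule at its
           printed boundaries", {
  row <- function(padj, lfc, wells, avail = 6L)
    data.frame(gene = "g", cell_type = "T", cytokine = "CK",
               log2fc = lfc, p = padj / 2, padj = padj,
               wells_supported = wells, n_wells_available = avail,
               removed_by_ratio = FALSE)
  expect_true(call_degs(row(0.04, 0.30, 4))$is_deg)
  expect_false(call_degs(row(0.04, 0.30, 3))$is_deg)
  expect_false(call_degs(row(0.06, 1.0, 6))$is_deg)
  expect_false(call_degs(row(0.04, 0.25, 6))$is_deg)  # strict |lfc| >
  expect_true(call_degs(row(0.04, -0.30, 4))$is_deg)
  expect_equal(call_degs(row(0.04, -0.30, 4))$direction, "down")
  # proportional rule with 5 available wells: ceiling(4/6*5) = 4
  expect_true(call_degs(row(0.04, 0.3, 4, avail = 5L))$is_deg)
  expect_false(call_degs(row(0.04, 0.3, 3, avail = 5L))$is_deg)
})

test_that("null screens yield (almost) no DEGs after all filters", {
  degs <- vapply(1:3, function(s) {
    cfg <- sim_config(n_donors = 12, n_celltypes = 1, cytokines = "CKA",
                      n_genes = 200, cells_per_group = 10,
                      seed = 1000 + s)
    sim <- simulate_screen(cfg)
    sum(de_table(pseudobulk(sim$cells))$is_deg)
  }, 0)
  expect_lte(mean(degs), 1)
})

test_that("external DE tables are schema-validated", {
  good <- data.frame(cell_type = "T", cytokine = "CK", gene = "g",
                     log2fc = 1, p = 0.01, padj = 0.02)
  expect_silent(de_external(good))
  expect_error(de_external(good[-3]), "missing column")
  bad <- good; bad$padj <- 0.001
  expect_error(de_external(bad), "padj < p")
})

test_that("the donor-adjusted backend agrees with an independent
           NB-GLM route (edgeR) on effect genes", {
  sim <- basic_sim()
  ct <- "CT01"; cy <- "CK1"
  pbs <- cytodict:::pb_by_donor(sim$pb, ct, "PBS")
  cyt <- cytodict:::pb_by_donor(sim$pb, ct, cy)
  donors <- intersect(pbs$donor, cyt$donor)
  counts <- t(rbind(pbs$raw[match(donors, pbs$donor), ],
                    cyt$raw[match(donors, cyt$donor), ]))
  colnames(counts) <- c(paste0(donors, "_PBS"), paste0(donors, "_CK"))
  group <- factor(rep(c("PBS", "CK"), each = length(donors)),
                  levels = c("PBS", "CK"))
  donor_f <- factor(rep(donors, 2))
  design <- model.matrix(~ donor_f + group)
  y <- edgeR::DGEList(counts = counts)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  res <- edgeR::glmQLFTest(fit, coef = "groupCK")
  tab <- edgeR::topTags(res, n = Inf)$table
  ours <- de_consensus(sim$pb, ct, cy)
  shared <- intersect(rownames(tab), ours$gene)
  lfc_ref <- tab[shared, "logFC"]
  lfc_ours <- ours$log2fc[match(shared, ours$gene)]
  expect_gt(cor(lfc_ref, lfc_ours), 0.9)
  planted <- sprintf("G%03d", 1:10)
  expect_true(all(abs(lfc_ref[match(planted, shared)] -
                      lfc_ours[match(planted, shared)]) < 0.4))
  # both routes call the planted genes significant
  expect_true(all(tab[planted, "FDR"] < 0.05))
  expect_true(all(ours$padj[match(planted, ours$gene)] < 0.05))
})
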