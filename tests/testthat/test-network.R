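test_that("receptor_expression takes min over subunits and max over
           alternative receptors", {
  genes <- c("r1a", "r1b", "r2")
  keys <- data.frame(donor = "D1", cell_type = c("A", "B"),
                     condition = "PBS", pbs_well = 1L)
  # cpm: A -> r1a 12, r1b 4, r2 20;  B -> r1a 6, r1b 2, r2 5
  raw <- rbind(c(12, 4, 20), c(6, 2, 5)) * 1e3
  raw <- cbind(raw, filler = 1e6 - rowSums(raw))
  colnames(raw) <- c(genes, "filler")
  pb <- manual_pb(keys, raw)
  rmap <- receptor_map(data.frame(
    cytokine = c("CK", "CK", "CK"),
    receptor = c("R1", "R1", "R2"),
    gene = c("r1a", "r1b", "r2")))
  rex <- receptor_expression(pb, rmap)
  # A: max(min(12, 4), 20) = 20; B: max(min(6, 2), 5) = 5
  expect_equal(rex$cpm[rex$cell_type == "A"], 20000, tolerance = 1e-9)
  expect_equal(rex$cpm[rex$cell_type == "B"], 5000, tolerance = 1e-9)
  expect_equal(rex$relative, c(1, 0.25), tolerance = 1e-9)
  # no receptor genes -> NA
  rmap0 <- receptor_map(data.frame(cytokine = "CKZ", receptor = "none",
                                   gene = ""))
  expect_true(all(is.na(receptor_expression(pb, rmap0)$cpm)))
})

test_that("classify_targets yields the four mutually exclusive bands at
           the printed boundaries", {
  expect_equal(classify_targets(20, 2, 1), "primary_target")
  expect_equal(classify_targets(3, 1.8, 1), "secondary_candidate")
  expect_equal(classify_targets(40, 0.8, 1), "weak_despite_receptor")
  expect_equal(classify_targets(10, 2, 1), "unclassified")   # 5<=cpm<=16
  expect_equal(classify_targets(20, 1.2, 1), "unclassified") # M<=1.5T
  expect_equal(classify_targets(40, 1.2, 1), "unclassified") # T<M<1.5T
  expect_equal(classify_targets(c(20, 3, 40), c(2, 1.8, 0.8),
                                c(1, 1, 1)),
               c("primary_target", "secondary_candidate",
                 "weak_despite_receptor"))
})

test_that("cytokine_expressed applies the mean/max/count rule with the
           multimeric minimum", {
  genes <- c("cy1", "cy2a", "cy2b")
  keys <- data.frame(donor = "D1", cell_type = "A",
                     condition = c("PBS", "CKX"), pbs_well = c(1L, NA))
  # condition cpm for cy1: 3 and 25 -> mean 14, max 25
  raw <- rbind(c(3, 5, 3, 1e6 - 11), c(25, 5, 3, 1e6 - 33)) * 30
  colnames(raw) <- c(genes, "filler")
  pb <- manual_pb(keys, raw)
  cg <- data.frame(cytokine = c("C1", "C2", "C2"),
                   gene = c("cy1", "cy2a", "cy2b"),
                   family = "fam")
  ex <- cytokine_expressed(pb, cg)
  expect_true(ex$expressed[ex$cytokine == "C1"])
  # heterodimer: min(mean 5, mean 3) = 3 < 4 -> not expressed
  expect_false(ex$expressed[ex$cytokine == "C2"])
  # single expressing cell type gets relative production 1
  expect_equal(ex$relative_production[ex$cytokine == "C1"], 1)
  # absent gene -> NA with warning
  cg2 <- rbind(cg, data.frame(cytokine = "C3", gene = "missing",
                              family = "fam"))
  expect_warning(ex2 <- cytokine_expressed(pb, cg2), "absent")
  expect_true(all(is.na(ex2$expressed[ex2$cytokine == "C3"])))
})

test_that("communication edges score sender x receiver and prune at
           0.25", {
  expr <- data.frame(cytokine = "CK", cell_type = c("A", "B"),
                     mean_cpm = c(40, 20), expressed = TRUE,
                     relative_production = c(1, 0.5))
  mag <- structure(list(table = data.frame(
    cell_type = c("A", "B"), cytokine = "CK", M = c(0.8, 0.3),
    threshold = 0.2, strong_impact = TRUE)), class = "MagnitudeTable")
  ce <- communication_edges(expr, mag)
  e <- ce$edges
  expect_equal(e$interaction_score,
               e$sender_strength * e$receiver_sensitivity)
  ab <- e[e$sender == "B" & e$receiver == "A", ]
  expect_equal(ab$interaction_score, 0.5 * 0.8)
  # 0.5 * 0.3 = 0.15 < 0.25 pruned but kept in the raw list
  expect_true(any(e$interaction_score < 0.25))
  expect_true(all(ce$pruned$interaction_score >= 0.25))
  # connection strength sums scores over cytokines
  expect_equal(ce$connection_strength["B", "A"], 0.4)
  # sender gate: cytokines never above 10 cpm are present but unscored
  expr2 <- expr; expr2$mean_cpm <- c(8, 4)
  ce2 <- communication_edges(expr2, mag)
  expect_true(all(is.na(ce2$edges$interaction_score)))
})

test_that("regulation_counts requires all subunits to pass and nets
           family members", {
  det <- data.frame(
    cell_type = "A", cytokine = "STIM",
    gene = c("u1", "d1", "h1", "h2", "x1"),
    log2fc = c(1.2, -1.5, 1.5, 0.8, 0.5),
    p = 0.001, padj = 0.01)
  cg <- data.frame(
    cytokine = c("UP", "DOWN", "HET", "HET", "WEAK"),
    gene = c("u1", "d1", "h1", "h2", "x1"),
    family = c("f1", "f1", "f2", "f2", "f1"))
  rc <- regulation_counts(det, cg)
  calls <- setNames(rc$calls$call, rc$calls$regulated)
  expect_equal(calls[["UP"]], "up")
  expect_equal(calls[["DOWN"]], "down")
  expect_equal(calls[["HET"]], "none")   # one subunit at lfc 0.8
  expect_equal(calls[["WEAK"]], "none")  # |lfc| <= 1
  # family f1: 1 up, 1 down; family max count 1 -> net 0
  f1 <- rc$family_scores[rc$family_scores$family == "f1", ]
  expect_equal(f1$score, 0)
})

test_that("a receptor-gated cascade is recovered by target
           classification plus secondary inference", {
  cts <- sprintf("CT%02d", 1:3)
  receptors <- list(
    CKX = list(genes = "G190",
               cpm_by_celltype = setNames(c(100, 1, 1), cts)),
    CKY = list(genes = "G191",
               cpm_by_celltype = setNames(c(1, 100, 1), cts)))
  cfg <- sim_config(
    n_donors = 8, n_celltypes = 3,
    cytokines = c("CKX", "CKY", paste0("N", 1:4)), n_genes = 200,
    cells_per_group = 20,
    effects = list(
      list(cytokine = "CKX", genes = sprintf("G%03d", 1:15), lfc = 2),
      list(cytokine = "CKY", genes = sprintf("G%03d", 21:35), lfc = 2)),
    receptors = receptors, cytokine_genes = list(CKY = "G180"),
    cascade = list(primary = "CKX", secondary = "CKY",
                   production_lfc = 2),
    seed = 12)
  sim <- simulate_screen(cfg)
  pb <- pseudobulk(sim$cells)
  det <- de_table(pb)
  mag <- magnitude_table(pb, det)
  rmap <- receptor_map(data.frame(cytokine = c("CKX", "CKY"),
                                  receptor = c("R1", "R2"),
                                  gene = c("G190", "G191")))
  rex <- receptor_expression(pb, rmap)
  cl <- merge(rex, mag$table, by = c("cytokine", "cell_type"))
  classes <- data.frame(cytokine = cl$cytokine,
                        cell_type = cl$cell_type,
                        class = classify_targets(cl$cpm, cl$M,
                                                 cl$threshold))
  # CT01 is CKX's primary target, CT02 responds without the receptor
  expect_equal(classes$class[classes$cytokine == "CKX" &
                             classes$cell_type == "CT01"],
               "primary_target")
  expect_equal(classes$class[classes$cytokine == "CKX" &
                             classes$cell_type == "CT02"],
               "secondary_candidate")
  cgmap <- data.frame(cytokine = "CKY", gene = "G180", family = "f")
  sec <- infer_secondary(det, classes, cgmap)
  m <- recovery_metrics(sim$truth$secondary_edges,
                        sec[c("primary", "secondary", "cell_type")])
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  # raising the correlation bar above the observed r removes the edge
  expect_equal(nrow(infer_secondary(det, classes, cgmap,
                                    min_cor = 0.999)), 0L)
  # a production log2FC requirement above the planted effect removes it
  expect_equal(nrow(infer_secondary(det, classes, cgmap,
                                    prod_lfc = 5)), 0L)
})
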