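test_that("delta_rank normalizes mean differences by summed sds and
           sorts descending with stable ties", {
  genes <- c("g1", "g2", "g3")
  Xa <- matrix(c(2, 2, 1, 1, 0, 0), 2, 3, dimnames = list(NULL, genes))
  Xb <- matrix(c(1, 1, 1, 1, 2, 2), 2, 3, dimnames = list(NULL, genes))
  # zero sds: epsilon guard kicks in, order by delta then gene id
  rk <- delta_rank(Xa, Xb)
  expect_equal(rk$gene, c("g1", "g2", "g3"))
  # m_a = 2, m_b = 1, sd_a = sd_b = 0.5 -> delta = 1
  set.seed(4)
  xa <- c(1.5, 2.5); xb <- c(0.5, 1.5)  # mean 2 / 1, sd 0.7071 each
  Xa2 <- cbind(g1 = xa); Xb2 <- cbind(g1 = xb)
  expect_equal(delta_rank(Xa2, Xb2)$delta,
               oracle_delta_stat(xa, xb), tolerance = 1e-12)
  expect_equal(delta_rank(Xa2, Xb2)$delta, 1 / sqrt(2), tolerance = 1e-12)
  # identical groups -> all deltas 0
  expect_true(all(delta_rank(Xa, Xa)$delta == 0))
  # antisymmetry: swapping groups negates delta and reverses ranking
  Xa3 <- matrix(rnorm(40), 10, 4,
                dimnames = list(NULL, paste0("g", 1:4)))
  Xb3 <- matrix(rnorm(40), 10, 4,
                dimnames = list(NULL, paste0("g", 1:4)))
  f <- delta_rank(Xa3, Xb3); r <- delta_rank(Xb3, Xa3)
  expect_equal(f$delta, -rev(r$delta), tolerance = 1e-12)
  expect_equal(f$gene, rev(r$gene))
  expect_error(delta_rank(Xa3[0, ], Xb3), "non-empty")
})

test_that("enrichment_score agrees exactly with the exhaustive
           prefix-sum oracle on all subsets of small universes (w=0)", {
  set.seed(5)
  worst <- 0
  for (n in 2:10) {
    genes <- sprintf("g%02d", seq_len(n))
    ranked <- data.frame(gene = genes,
                         delta = sort(rnorm(n), decreasing = TRUE))
    for (mask in seq_len(2^n - 1)) {
      hit <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
      es <- enrichment_score(ranked, genes[hit], w = 0)$es
      worst <- max(worst, abs(es - oracle_es(ranked$delta, hit)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("enrichment_score endpoints: top-heavy sets peak at +1,
           bottom-heavy at -1, full sets end at +1", {
  ranked <- data.frame(gene = paste0("g", 1:4),
                       delta = c(3, 2, 1, 0.5))
  expect_equal(enrichment_score(ranked, c("g1", "g2"), w = 0)$es, 1)
  expect_equal(enrichment_score(ranked, c("g3", "g4"), w = 0)$es, -1)
  all_in <- enrichment_score(ranked, paste0("g", 1:4), w = 0)
  expect_equal(all_in$es, 1)
  expect_equal(all_in$running[4], 1)
  expect_true(is.na(enrichment_score(ranked, "absent")$es))
  # running sum returns to ~0 when the set is a proper subset
  r2 <- enrichment_score(ranked, c("g1", "g3"), w = 0)$running
  expect_equal(r2[4], 0, tolerance = 1e-12)
})

test_that("permutation_null is seed-deterministic, centers |NES| near 1
           on null sets, and its p-values are calibrated", {
  set.seed(6)
  genes <- sprintf("g%03d", 1:100)
  ranked <- data.frame(gene = genes,
                       delta = sort(rnorm(100), decreasing = TRUE))
  a <- permutation_null(ranked, sample(genes, 15), n_perm = 300,
                        seed = 7)
  expect_true(a$p > 0 && a$p <= 1)
  # determinism under the seed, regardless of ambient RNG state
  set.seed(1); s1 <- permutation_null(ranked, genes[1:10],
                                      n_perm = 200, seed = 9)
  set.seed(2); s2 <- permutation_null(ranked, genes[1:10],
                                      n_perm = 200, seed = 9)
  expect_identical(s1, s2)
  # null p-values approximately uniform over repeats
  ps <- vapply(1:120, function(i) {
    rk <- data.frame(gene = genes,
                     delta = sort(rnorm(100), decreasing = TRUE))
    permutation_null(rk, sample(genes, 10), n_perm = 99,
                     seed = 100 + i)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("a planted shift of set genes yields a significant 'up'
           verdict across the hyperparameter grid", {
  set.seed(8)
  n <- 200
  genes <- sprintf("G%03d", 1:n)
  set <- genes[1:20]
  Xa <- matrix(rnorm(100 * n), 100, n, dimnames = list(NULL, genes))
  Xb <- matrix(rnorm(100 * n), 100, n, dimnames = list(NULL, genes))
  Xa[, set] <- Xa[, set] + 1
  rk <- delta_rank(Xa, Xb)
  pn <- permutation_null(rk, set, n_perm = 500, seed = 11)
  expect_lt(pn$p, 0.01)
  expect_gt(pn$es, 0)
  expect_gt(pn$nes, 1)
  gr <- grid_robustness(rk, function(lfc, cpm) set, n_perm = 200,
                        seed = 12)
  expect_equal(gr$verdict, "up")
  expect_equal(gr$n_valid, 25L)
})

test_that("grid_verdict applies the validity, significance and
           sign-consistency votes at their boundaries", {
  mk <- function(n_valid, n_sig, n_cells = 25, signs = 1) {
    valid <- c(rep(TRUE, n_valid), rep(FALSE, n_cells - n_valid))
    p <- ifelse(valid, 0.5, NA)
    p[seq_len(n_sig)] <- 0.01
    es <- rep(0.5, n_cells) * signs
    data.frame(valid = valid, es = es, p = p)
  }
  expect_equal(grid_verdict(mk(20, 18))$verdict, "up")
  expect_equal(grid_verdict(mk(7, 7))$verdict, "none")  # 7/25 < 1/3
  # two-thirds rule: 13 of 20 significant fails, 14 passes
  expect_equal(grid_verdict(mk(20, 13))$verdict, "none")
  expect_equal(grid_verdict(mk(20, 14))$verdict, "up")
  # mixed signs among significant cells -> none
  mixed <- mk(20, 14)
  mixed$es[1:7] <- -0.5
  expect_equal(grid_verdict(mixed)$verdict, "none")
  # all-negative significant cells -> down
  neg <- mk(20, 18)
  neg$es <- -neg$es
  expect_equal(grid_verdict(neg)$verdict, "down")
})

test_that("small-panel mode raises the validity quota and gates on
           signature overlap", {
  ranked <- data.frame(gene = sprintf("p%02d", 1:30),
                       delta = sort(rnorm(30), decreasing = TRUE))
  # signature of 100 genes, only 5 on the panel: overlap 5% < 10%
  sig <- c(sprintf("p%02d", 1:5), sprintf("q%03d", 1:95))
  gr <- grid_robustness(ranked, function(lfc, cpm) sig,
                        small_panel = TRUE, n_perm = 100, seed = 3,
                        min_genes = 3)
  expect_equal(gr$n_valid, 0L)
  expect_equal(gr$verdict, "none")
})

test_that("GMT round trip preserves gene set names and members", {
  sets <- list(`T|CK1|up` = c("g1", "g2"), `B|CK2|down` = "g9")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})

test_that("differential_communication requires all three gates", {
  set.seed(13)
  # query dataset: sender cell type S secretes ck gene, receiver R has
  # the receptor; 60 cells each
  genes <- c("ckgene", "recA", "recB", "fill1", "fill2")
  n <- 180
  meta <- data.frame(donor = "Q", condition = "CKq",
                     cell_type = rep(c("S", "R", "O"), each = 60))
  counts <- matrix(rpois(n * 5, 20), n, 5)
  counts[meta$cell_type == "S", 1] <- rpois(60, 200)   # sender signal
  counts[meta$cell_type != "S", 1] <- 0
  counts[meta$cell_type == "R", 2:3] <- rpois(120, 100)
  counts[meta$cell_type != "R", 2:3] <- 0
  cc <- CellCounts(counts, meta, genes)
  cg <- data.frame(cytokine = "CK", gene = "ckgene", family = "f")
  rmap <- receptor_map(data.frame(cytokine = "CK", receptor = "R1",
                                  gene = c("recA", "recB")))
  verdicts <- data.frame(cell_type = c("S", "R", "O"), cytokine = "CK",
                         verdict = c("none", "up", "up"))
  edges <- differential_communication(cc, verdicts, cg, rmap)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$sender, "S")
  expect_equal(edges$receiver, "R")  # O is enriched but lacks receptor
  # flipping the receiver verdict to none suppresses the edge
  verdicts$verdict <- "none"
  expect_equal(nrow(differential_communication(cc, verdicts, cg,
                                               rmap)), 0L)
})
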