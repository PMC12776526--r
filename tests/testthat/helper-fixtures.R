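# Shared fixture builders and independent oracles. Everything is built
# in code; expensive simulations are cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# tiny hand-built CellCounts: 4 cells, 3 genes, 2 donors
tiny_cells <- function() {
  counts <- matrix(c(1, 2, 0,
                     3, 4, 1,
                     0, 0, 5,
                     2, 2, 2), 4, 3, byrow = TRUE)
  meta <- data.frame(donor = c("D1", "D1", "D2", "D2"),
                     cell_type = "T",
                     condition = c("PBS", "CKA", "PBS", "CKA"),
                     pbs_well = c(1L, NA, 2L, NA),
                     plate_row = 1L)
  CellCounts(counts, meta, c("GA", "GB", "MT-X"))
}

# directly assembled Pseudobulk (bypasses cell-level data) for rule
# tests that only need key-level raw counts
manual_pb <- function(keys, raw, n_cells = NULL, n_expr = NULL) {
  genes <- colnames(raw)
  if (!"pbs_well" %in% names(keys)) keys$pbs_well <- NA_integer_
  structure(list(keys = keys, raw = raw, cpm = cytodict:::cpm_rows(raw),
                 n_cells = n_cells %||% rep(100L, nrow(raw)),
                 n_expr = if (is.null(n_expr)) (raw > 0) * 50 else n_expr,
                 genes = genes),
            class = "Pseudobulk")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a mid-sized screen with planted DEG sets, reused across files
basic_sim <- function() cached("basic_sim", {
  cfg <- sim_config(
    n_donors = 12, n_celltypes = 3, cytokines = paste0("CK", 1:6),
    n_genes = 200, cells_per_group = 20,
    effects = list(
      list(cytokine = "CK1", genes = sprintf("G%03d", 1:10), lfc = 2),
      list(cytokine = "CK2", genes = sprintf("G%03d", 11:20), lfc = -2),
      list(cytokine = "CK3", genes = sprintf("G%03d", 21:30), lfc = 2)),
    seed = 42)
  sim <- simulate_screen(cfg)
  sim$pb <- pseudobulk(sim$cells)
  sim$det <- de_table(sim$pb)
  sim
})

## ---- independent oracles (brute-force, scalar loops) ----

oracle_euclid <- function(v_cyt, v_pbs) {
  s <- 0
  for (i in seq_along(v_cyt))
    s <- s + (log2(v_cyt[[i]] + 1) - log2(v_pbs[[i]] + 1))^2
  sqrt(s)
}

oracle_pw <- function(lfc, padj, clip = 1e-10) {
  s <- 0
  for (i in seq_along(lfc))
    s <- s + abs(lfc[i]) * -log10(max(padj[i], clip))
  s
}

oracle_mraw <- function(raw_fc) {
  s <- 0
  for (x in raw_fc) s <- s + 2^max(abs(log2(unname(x))) - 0.5, 0) - 1
  s
}

oracle_baseline <- function(cpm_d, cpm_med) {
  out <- numeric(length(cpm_d))
  for (i in seq_along(cpm_d))
    out[i] <- log2((cpm_d[i] + 1) / (cpm_med[i] + 1))
  out
}

oracle_delta_stat <- function(xa, xb) {
  (mean(xa) - mean(xb)) / max(sd(xa) + sd(xb), 1e-9)
}

oracle_ratio <- function(well_lfc) {
  m <- mean(well_lfc)
  sd(well_lfc) / (abs(m) + 0.25)
}

oracle_tsi <- function(M, T, floor = 0.05) {
  imax <- which.max(M)
  denom <- max(M[imax] - T[imax] / 2, floor)
  s <- 0
  for (i in seq_along(M)) s <- s + 1 - max(M[i] - T[i] / 2, floor) / denom
  s / (length(M) - 1)
}

oracle_program_activity <- function(z_stim, z_pbs, zbar_by_stim) {
  (mean(z_stim) - mean(z_pbs)) / max(zbar_by_stim)
}

# exhaustive prefix-sum enrichment score, w = 0
oracle_es <- function(delta_ranked, hit) {
  n <- length(hit); k <- sum(hit)
  best <- 0; s <- 0
  for (i in seq_len(n)) {
    s <- s + if (hit[i]) 1 / k else -1 / (n - k)
    if (abs(s) > abs(best)) best <- s
  }
  best
}

# build a cell-level factor dataset with chosen per-donor shifts
cip_fixture <- function(shifts, n_cells = 15, sd = 0.2, seed = 31) {
  set.seed(seed)
  donors <- names(shifts)
  meta <- do.call(rbind, lapply(donors, function(d) {
    pbs <- do.call(rbind, lapply(1:6, function(w)
      data.frame(donor = d, cell_type = "T", condition = "PBS",
                 pbs_well = w)[rep(1, n_cells), ]))
    stim <- data.frame(donor = d, cell_type = "T", condition = "CKA",
                       pbs_well = NA)[rep(1, n_cells), ]
    rbind(pbs, stim)
  }))
  rownames(meta) <- NULL
  z <- rnorm(nrow(meta), 0.5, sd)
  for (d in donors) {
    sel <- meta$donor == d & meta$condition == "CKA"
    z[sel] <- rnorm(sum(sel), 0.5 + shifts[[d]], sd)
  }
  list(fs = factor_scores(cbind(F1 = z), interpretability = 0.9),
       meta = meta)
}


# pooled condition-level cpm, recomputed independently for oracle checks
pooled_cpm_of <- function(pb, ct, cond) {
  rows <- pb$keys$cell_type == ct & pb$keys$condition == cond
  tot <- colSums(pb$raw[rows, , drop = FALSE])
  tot / sum(tot) * 1e6
}
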