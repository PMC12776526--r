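#' Ranked difference statistic between two expression matrices
#'
#' Per gene, the mean difference between conditions normalized by the
#' sum of the within-group standard deviations:
#' `delta_g = (m_a - m_b) / (sd_a + sd_b)` (epsilon guard when both
#' standard deviations vanish). Genes are returned sorted by decreasing
#' delta, ties broken by gene id for a stable order.
#'
#' @param X_a,X_b cells x genes matrices for the two conditions (shared
#'   gene columns).
#' @param eps guard for zero pooled standard deviation (1e-9).
#' @return data.frame (`gene`, `delta`) in rank order.
#' @export
delta_rank <- function(X_a, X_b, eps = 1e-9) {
  genes <- intersect(colnames(X_a), colnames(X_b))
  if (!length(genes)) stop("no shared genes between the two conditions")
  if (!nrow(X_a) || !nrow(X_b)) stop("both groups must be non-empty")
  X_a <- as.matrix(X_a[, genes, drop = FALSE])
  X_b <- as.matrix(X_b[, genes, drop = FALSE])
  m <- colMeans(X_a) - colMeans(X_b)
  s <- apply(X_a, 2, stats::sd) + apply(X_b, 2, stats::sd)
  delta <- m / pmax(s, eps)
  ord <- order(-delta, genes)
  data.frame(gene = genes[ord], delta = delta[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Running-sum enrichment score
#'
#' Walks the ranked gene list, increasing the running sum on gene-set
#' hits (increments proportional to |delta|^w, normalized to total +1)
#' and decreasing it uniformly on misses (total -1). The enrichment
#' score is the signed running-sum value of largest magnitude; gene
#' sets concentrated at either end of the ranking produce a pronounced
#' peak.
#'
#' @param ranked a [delta_rank] result (or data.frame `gene`, `delta`
#'   in rank order).
#' @param gene_set character vector.
#' @param w hit-weight exponent (1; `w = 0` gives the unweighted
#'   Kolmogorov-Smirnov-like statistic).
#' @return list (`es`, `peak` index, `running` the full sum), or
#'   `es = NA` when the set misses the universe entirely.
#' @export
enrichment_score <- function(ranked, gene_set, w = 1) {
  hit <- ranked$gene %in% gene_set
  n <- length(hit); k <- sum(hit)
  if (k == 0) return(list(es = NA_real_, peak = NA_integer_,
                          running = NULL))
  inc <- numeric(n)
  hw <- abs(ranked$delta[hit])^w
  if (sum(hw) == 0) hw <- rep(1, k)  # all-zero deltas: fall back flat
  inc[hit] <- hw / sum(hw)
  if (k < n) inc[!hit] <- -1 / (n - k)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak, running = running)
}

#' Permutation null, p-value and normalized enrichment score
#'
#' Draws `n_perm` random gene sets of the observed size from the ranked
#' universe, recomputes the enrichment score for each, and reports
#' `p = (1 + #{|ES_null| >= |ES_obs|}) / (n_perm + 1)` (two-sided on
#' magnitude; one-sided available) and `NES = ES / mean(|ES_null|)` over
#' null scores of the matching sign (plain mean available).
#'
#' @param ranked a [delta_rank] result.
#' @param gene_set character vector.
#' @param n_perm permutations (20000).
#' @param seed RNG seed.
#' @param w hit-weight exponent (1).
#' @param sided `"two"` (|ES| rule) or `"one"` (same-sign exceedance).
#' @param nes_norm `"signed_mean_abs"` or `"mean"`.
#' @return list (`es`, `nes`, `p`, `n_null`).
#' @export
permutation_null <- function(ranked, gene_set, n_perm = 20000, seed = 1L,
                             w = 1, sided = c("two", "one"),
                             nes_norm = c("signed_mean_abs", "mean")) {
  sided <- match.arg(sided); nes_norm <- match.arg(nes_norm)
  obs <- enrichment_score(ranked, gene_set, w)
  k <- sum(ranked$gene %in% gene_set)
  if (k == 0 || is.na(obs$es))
    return(list(es = NA_real_, nes = NA_real_, p = NA_real_, n_null = 0L))
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    enrichment_score(ranked, sample(ranked$gene, k), w)$es
  }, 0))
  p <- if (sided == "two") {
    (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  } else if (obs$es >= 0) {
    (1 + sum(null_es >= obs$es)) / (n_perm + 1)
  } else {
    (1 + sum(null_es <= obs$es)) / (n_perm + 1)
  }
  nes <- if (nes_norm == "mean") obs$es / mean(null_es) else {
    same <- null_es[sign(null_es) == sign(obs$es)]
    if (!length(same)) NA_real_ else obs$es / mean(abs(same))
  }
  list(es = obs$es, nes = nes, p = p, n_null = length(null_es))
}

#' Build a gene-set library from DEG calls at given thresholds
#'
#' The dictionary's cell type-specific signatures: per (cell type,
#' cytokine, direction), the DEGs whose |log2FC| exceeds `lfc_min` and
#' whose pooled cpm in the signature's cell type reaches `cpm_min`.
#'
#' @param det a [de_table] result.
#' @param pb the matching [pseudobulk] (for the cpm cutoff; the maximum
#'   condition cpm of the gene in the cell type is used).
#' @param lfc_min,cpm_min grid thresholds.
#' @return Named list of gene sets
#'   (`<cell_type>|<cytokine>|<up/down>`).
#' @export
deg_gene_sets <- function(det, pb, lfc_min = 1, cpm_min = 6) {
  sets <- list()
  for (ct in unique(det$cell_type)) {
    conds <- unique(pb$keys$condition[pb$keys$cell_type == ct])
    cpmm <- sapply(conds, function(cond) {
      v <- pooled_cpm(pb, ct, cond)
      if (is.null(v)) rep(NA_real_, length(pb$genes)) else v
    })
    maxcpm <- stats::setNames(apply(cpmm, 1, max, na.rm = TRUE), pb$genes)
    d <- det[det$cell_type == ct & det$is_deg &
             abs(det$log2fc) > lfc_min, ]
    d <- d[maxcpm[d$gene] >= cpm_min, ]
    for (cy in unique(d$cytokine)) for (dir in c("up", "down")) {
      g <- d$gene[d$cytokine == cy & d$direction == dir]
      if (length(g))
        sets[[paste(ct, cy, dir, sep = "|")]] <- g
    }
  }
  sets
}

#' Hyperparameter-grid robustness verdict for one gene-set family
#'
#' Re-derives the gene set over a grid of thresholds (for
#' cytokine-derived sets: five minimum |log2FC| thresholds 0.8-1.2
#' crossed with five expression cutoffs 6-10 cpm; for program-derived
#' sets: the five cpm cutoffs only), runs the permutation enrichment in
#' each valid cell (set size within [`min_genes`, `max_genes`]), and
#' votes: the verdict is up/down only when at least `valid_frac` of the
#' grid was valid, at least `sig_frac` of the valid tests gave
#' p < `p_thresh`, and all significant cells agree in ES sign. In
#' small-panel mode the set must additionally overlap at least
#' `overlap_frac` of its genes with the panel and the validity quota is
#' raised to 1/2.
#'
#' @param ranked a [delta_rank] result for the query contrast.
#' @param set_builder `function(lfc_min, cpm_min)` returning the gene
#'   set for one grid cell (`lfc_min` is NA for program sets).
#' @param lfc_grid,cpm_grid the grids (`c(0.8, 0.9, 1, 1.1, 1.2)`,
#'   `6:10`); pass `lfc_grid = NA` for program sets.
#' @param n_perm,seed,w passed to [permutation_null].
#' @param min_genes,max_genes validity bounds (8, 1000).
#' @param p_thresh per-cell significance (0.1).
#' @param valid_frac,sig_frac vote quotas (1/3, 2/3).
#' @param small_panel small targeted-panel mode (FALSE).
#' @param overlap_frac panel-overlap gate in small-panel mode (0.1).
#' @return list (`verdict`, `n_valid`, `n_cells`, `n_sig`, `results`
#'   data.frame per grid cell).
#' @export
grid_robustness <- function(ranked, set_builder,
                            lfc_grid = c(0.8, 0.9, 1.0, 1.1, 1.2),
                            cpm_grid = 6:10, n_perm = 1000, seed = 1L,
                            w = 1, min_genes = 8, max_genes = 1000,
                            p_thresh = 0.1, valid_frac = 1 / 3,
                            sig_frac = 2 / 3, small_panel = FALSE,
                            overlap_frac = 0.1) {
  if (small_panel) valid_frac <- max(valid_frac, 0.5)
  grid <- expand.grid(lfc = lfc_grid, cpm = cpm_grid)
  cells <- list()
  for (i in seq_len(nrow(grid))) {
    gs <- set_builder(grid$lfc[i], grid$cpm[i])
    in_panel <- intersect(gs, ranked$gene)
    valid <- length(in_panel) >= min_genes &&
      length(in_panel) <= max_genes
    if (small_panel && length(gs) &&
        length(in_panel) / length(gs) < overlap_frac)
      valid <- FALSE
    if (!valid) {
      cells[[i]] <- data.frame(lfc = grid$lfc[i], cpm = grid$cpm[i],
                               size = length(in_panel), valid = FALSE,
                               es = NA_real_, nes = NA_real_,
                               p = NA_real_)
      next
    }
    pn <- permutation_null(ranked, in_panel, n_perm = n_perm,
                           seed = seed + i, w = w)
    cells[[i]] <- data.frame(lfc = grid$lfc[i], cpm = grid$cpm[i],
                             size = length(in_panel), valid = TRUE,
                             es = pn$es, nes = pn$nes, p = pn$p)
  }
  res <- do.call(rbind, cells)
  c(grid_verdict(res, p_thresh = p_thresh, valid_frac = valid_frac,
                 sig_frac = sig_frac), list(results = res))
}

#' Vote a robustness verdict over a grid of enrichment results
#'
#' The three-rule vote applied by [grid_robustness]: at least
#' `valid_frac` of the grid cells valid, at least `sig_frac` of the
#' valid cells with p below `p_thresh`, and all significant cells
#' agreeing in enrichment-score sign.
#'
#' @param res data.frame with columns `valid`, `es`, `p` (one row per
#'   grid cell).
#' @param p_thresh,valid_frac,sig_frac the vote rules (0.1, 1/3, 2/3).
#' @return list (`verdict`, `n_valid`, `n_cells`, `n_sig`).
#' @export
grid_verdict <- function(res, p_thresh = 0.1, valid_frac = 1 / 3,
                         sig_frac = 2 / 3) {
  n_cells <- nrow(res)
  n_valid <- sum(res$valid)
  sig <- res$valid & !is.na(res$p) & res$p < p_thresh
  n_sig <- sum(sig)
  verdict <- "none"
  if (n_valid >= valid_frac * n_cells && n_valid > 0 &&
      n_sig >= sig_frac * n_valid && n_sig > 0) {
    signs <- sign(res$es[sig])
    if (all(signs > 0)) verdict <- "up"
    else if (all(signs < 0)) verdict <- "down"
  }
  list(verdict = verdict, n_valid = n_valid, n_cells = n_cells,
       n_sig = n_sig)
}

#' Differential cell-cell communication in a query dataset
#'
#' Combines enrichment verdicts with expression gates. Senders: per
#' cell type, a one-vs-rest Wilcoxon rank-sum test on cell-level cpm of
#' the cytokine's production-associated genes; a sender requires BH
#' adjusted p < 0.1, positive log2FC and mean expression > 10 cpm.
#' Receivers: a significant "up" enrichment verdict for the cytokine in
#' the cell type and mean receptor expression > 10 cpm (multimeric
#' receptors are gated on their least-expressed subunit gene).
#'
#' @param cc a [CellCounts] query dataset.
#' @param verdicts data.frame (`cell_type`, `cytokine`, `verdict`) of
#'   per-cell-type enrichment verdicts.
#' @param cgmap cytokine gene map (production-associated genes).
#' @param rmap a [receptor_map].
#' @param padj_thresh sender significance (0.1).
#' @param min_cpm expression gate for sender and receiver (10).
#' @return data.frame (`sender`, `cytokine`, `receiver`).
#' @export
differential_communication <- function(cc, verdicts, cgmap, rmap,
                                       padj_thresh = 0.1, min_cpm = 10) {
  cts <- unique(cc$meta$cell_type)
  cellcpm <- cpm_rows(as.matrix(cc$counts))
  colnames(cellcpm) <- cc$genes
  # sender tests: one per (cytokine, cell type), BH within the analysis
  sender_rows <- list()
  for (cy in unique(cgmap$cytokine)) {
    genes <- intersect(cgmap$gene[cgmap$cytokine == cy], cc$genes)
    if (!length(genes)) next
    expr <- rowMeans(cellcpm[, genes, drop = FALSE])
    for (ct in cts) {
      a <- expr[cc$meta$cell_type == ct]
      b <- expr[cc$meta$cell_type != ct]
      if (!length(a) || !length(b)) next
      p <- suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE)$p.value)
      sender_rows[[length(sender_rows) + 1L]] <- data.frame(
        cytokine = cy, cell_type = ct, p = p,
        lfc = log2((mean(a) + 1) / (mean(b) + 1)), mean_cpm = mean(a),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(sender_rows))
    return(data.frame(sender = character(0), cytokine = character(0),
                      receiver = character(0)))
  senders <- do.call(rbind, sender_rows)
  senders$padj <- stats::p.adjust(senders$p, "BH")
  senders$is_sender <- senders$padj < padj_thresh & senders$lfc > 0 &
    senders$mean_cpm > min_cpm
  # receiver gate: verdict up + receptor expression
  edges <- list()
  for (k in which(senders$is_sender)) {
    cy <- senders$cytokine[k]
    recs <- rmap[[cy]]
    if (is.null(recs) ||
        !length(recs <- recs[vapply(recs, length, 0L) > 0])) {
      cd_log("differential_communication: no receptor for %s; suppressed",
             cy)
      next
    }
    for (ct in cts) {
      v <- verdicts$verdict[verdicts$cell_type == ct &
                            verdicts$cytokine == cy]
      if (!length(v) || v[1] != "up") next
      sel <- cc$meta$cell_type == ct
      rec_ok <- any(vapply(recs, function(genes) {
        g <- intersect(genes, cc$genes)
        if (length(g) < length(genes)) return(FALSE)
        # multimeric: gate on the least-expressed subunit
        min(colMeans(cellcpm[sel, g, drop = FALSE])) > min_cpm
      }, NA))
      if (rec_ok)
        edges[[length(edges) + 1L]] <- data.frame(
          sender = senders$cell_type[k], cytokine = cy, receiver = ct,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(edges))
    return(data.frame(sender = character(0), cytokine = character(0),
                      receiver = character(0)))
  unique(do.call(rbind, edges))
}

#' Write / read gene-set libraries in GMT format
#'
#' @param sets named list of character vectors.
#' @param path GMT file.
#' @return `read_gmt`: named list of gene sets.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, "cytodict", sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t")
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, "", 1))
}
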