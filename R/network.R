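#' Read a curated cytokine-to-receptor map
#'
#' TSV schema: columns `cytokine`, `receptor`, `gene` — one row per
#' receptor subunit gene; alternative receptors of a cytokine appear as
#' distinct `receptor` values. Cytokines without a known receptor may
#' appear with an empty gene field.
#'
#' @param path TSV file.
#' @return A `ReceptorMap`: named list cytokine -> list of receptors,
#'   each a character vector of subunit genes.
#' @export
read_receptor_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("cytokine", "receptor", "gene")
  if (length(miss <- setdiff(req, names(df))))
    stop("receptor map missing column(s): ", paste(miss, collapse = ", "))
  receptor_map(df)
}

#' Build a ReceptorMap from a data.frame
#' @param df data.frame with columns `cytokine`, `receptor`, `gene`.
#' @return A `ReceptorMap` list.
#' @export
receptor_map <- function(df) {
  out <- lapply(split(df, df$cytokine), function(d) {
    recs <- split(d$gene, d$receptor)
    lapply(recs, function(g) g[nzchar(g) & !is.na(g)])
  })
  structure(out, class = "ReceptorMap")
}

#' Read a curated cytokine-to-encoding-gene map
#'
#' TSV schema: columns `cytokine`, `gene`, `family` — one row per
#' encoding (subunit) gene.
#'
#' @param path TSV file.
#' @return A `CytokineGeneMap` data.frame.
#' @export
read_cytokine_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("cytokine", "gene", "family")
  if (length(miss <- setdiff(req, names(df))))
    stop("cytokine gene map missing column(s): ",
         paste(miss, collapse = ", "))
  class(df) <- c("CytokineGeneMap", "data.frame")
  df
}

#' Receptor expression per (cytokine, cell type)
#'
#' On PBS pseudobulks: a receptor's expression is the minimum cpm across
#' its subunit genes (all subunits must be present for an active
#' receptor); a cytokine's receptor expression is the maximum across its
#' alternative receptors (any receptor suffices). Relative expression
#' divides by the maximum across cell types.
#'
#' @param pb a [pseudobulk] (PBS keys are used).
#' @param rmap a [receptor_map].
#' @return data.frame (`cytokine`, `cell_type`, `cpm`, `relative`);
#'   cytokines without receptor genes get NA.
#' @export
receptor_expression <- function(pb, rmap) {
  cts <- unique(pb$keys$cell_type)
  cpm_by_ct <- sapply(cts, function(ct) pooled_cpm(pb, ct, "PBS"))
  rows <- list()
  for (cy in names(rmap)) {
    recs <- rmap[[cy]]
    recs <- recs[vapply(recs, length, 0L) > 0]
    vals <- if (!length(recs)) rep(NA_real_, length(cts)) else
      vapply(cts, function(ct) {
        max(vapply(recs, function(genes) {
          g <- intersect(genes, pb$genes)
          if (length(g) < length(genes)) return(NA_real_)
          min(cpm_by_ct[g, ct])
        }, 0))
      }, 0)
    rel <- if (all(is.na(vals)) || max(vals, na.rm = TRUE) == 0)
      rep(NA_real_, length(cts)) else vals / max(vals, na.rm = TRUE)
    rows[[cy]] <- data.frame(cytokine = cy, cell_type = cts, cpm = vals,
                             relative = rel, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify (cytokine, cell type) responses by receptor logic
#'
#' Bands chosen with margin around the empirical ~8 cpm receptor
#' threshold for observable responses: `primary_target` when receptor
#' cpm > 16 and M > 1.5 T; `secondary_candidate` when receptor cpm < 5
#' yet M > 1.5 T (response without receptor — likely mediated by another
#' cell's secretion); `weak_despite_receptor` when receptor cpm > 32 but
#' M < T; otherwise `unclassified`.
#'
#' @param receptor_cpm receptor expression (cpm).
#' @param M normalized response magnitude.
#' @param T strong-impact threshold of the cell type.
#' @return One of the four class labels (vectorised).
#' @export
classify_targets <- function(receptor_cpm, M, T) {
  stopifnot(length(M) == length(receptor_cpm))
  T <- rep_len(T, length(M))
  out <- rep("unclassified", length(M))
  out[receptor_cpm > 16 & M > 1.5 * T] <- "primary_target"
  out[receptor_cpm < 5 & M > 1.5 * T] <- "secondary_candidate"
  out[receptor_cpm > 32 & M < T] <- "weak_despite_receptor"
  out[is.na(receptor_cpm) | is.na(M)] <- NA_character_
  out
}

# mean cpm of a gene set's minimum (multimeric) across the stimulation
# conditions of a cell type; returns mean, max and max total count
cytokine_gene_stats <- function(pb, cell_type, genes) {
  conds <- unique(pb$keys$condition[pb$keys$cell_type == cell_type])
  cpms <- counts <- numeric(0)
  for (cond in conds) {
    v <- pooled_cpm(pb, cell_type, cond)
    if (is.null(v)) next
    rows <- pb_rows(pb, cell_type = cell_type, condition = cond)
    tot <- colSums(pb$raw[rows, , drop = FALSE])
    cpms <- c(cpms, min(v[genes]))        # multimeric: min across subunits
    counts <- c(counts, min(tot[genes]))
  }
  if (!length(cpms)) return(NULL)
  list(mean_cpm = mean(cpms), max_cpm = max(cpms),
       max_count = max(counts))
}

#' Cytokine expression and relative production per cell type
#'
#' A cytokine counts as expressed in a cell type when, across all that
#' cell type's stimulation conditions, its encoding genes reach mean
#' cpm > 4, max cpm > 4 and at least 20 total pseudobulk counts in at
#' least one condition; multimeric cytokines use the minimum across
#' subunit genes throughout. Relative production is the cell type's mean
#' cpm divided by the maximum mean across cell types.
#'
#' @param pb a [pseudobulk] over all conditions.
#' @param cgmap a [read_cytokine_gene_map] table.
#' @param min_mean,min_max,min_count the expression rule (4, 4, 20).
#' @return data.frame (`cytokine`, `cell_type`, `mean_cpm`, `expressed`,
#'   `relative_production`).
#' @export
cytokine_expressed <- function(pb, cgmap, min_mean = 4, min_max = 4,
                               min_count = 20) {
  cts <- unique(pb$keys$cell_type)
  rows <- list()
  for (cy in unique(cgmap$cytokine)) {
    genes <- cgmap$gene[cgmap$cytokine == cy]
    if (!all(genes %in% pb$genes)) {
      warning("cytokine ", cy, " gene(s) absent from panel")
      rows[[cy]] <- data.frame(cytokine = cy, cell_type = cts,
                               mean_cpm = NA_real_, expressed = NA,
                               stringsAsFactors = FALSE)
      next
    }
    st <- lapply(cts, function(ct) cytokine_gene_stats(pb, ct, genes))
    rows[[cy]] <- data.frame(
      cytokine = cy, cell_type = cts,
      mean_cpm = vapply(st, function(s) s$mean_cpm %||% NA_real_, 0),
      expressed = vapply(st, function(s)
        !is.null(s) && s$mean_cpm > min_mean && s$max_cpm > min_max &&
          s$max_count >= min_count, NA),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$relative_production <- NA_real_
  for (cy in unique(out$cytokine)) {
    sel <- out$cytokine == cy
    mx <- suppressWarnings(max(out$mean_cpm[sel & out$expressed %in% TRUE]))
    if (is.finite(mx) && mx > 0)
      out$relative_production[sel] <- out$mean_cpm[sel] / mx
  }
  out
}

#' Cell-cell communication edges
#'
#' An edge (sender cell type, cytokine, receiver cell type) is present
#' when the cytokine is expressed in the sender and has strong impact on
#' the receiver. Sender strength is the sender's mean cpm divided by the
#' maximum across expressing cell types, scored only for cytokines whose
#' mean cpm exceeds `sender_gate` somewhere; receiver sensitivity is the
#' receiver's normalized response magnitude; their product is the
#' interaction score, pruned at `min_score`.
#'
#' @param expr a [cytokine_expressed] table.
#' @param mag a [magnitude_table].
#' @param sender_gate minimum mean cpm in some cell type (10).
#' @param min_score pruning threshold for the pruned list (0.25).
#' @return list: `edges` (all present edges with scores), `pruned`
#'   (score >= `min_score`), `connection_strength` (sender x receiver
#'   matrix of summed scores).
#' @export
communication_edges <- function(expr, mag, sender_gate = 10,
                                min_score = 0.25) {
  mt <- mag$table
  rows <- list()
  for (cy in intersect(unique(expr$cytokine), unique(mt$cytokine))) {
    ex <- expr[expr$cytokine == cy & expr$expressed %in% TRUE, ]
    if (!nrow(ex)) next
    scored <- any(ex$mean_cpm > sender_gate)
    mx <- max(ex$mean_cpm)
    strong <- mt[mt$cytokine == cy & mt$strong_impact %in% TRUE, ]
    if (!nrow(strong)) next
    for (i in seq_len(nrow(ex))) for (j in seq_len(nrow(strong))) {
      ss <- if (scored && mx > 0) ex$mean_cpm[i] / mx else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        sender = ex$cell_type[i], cytokine = cy,
        receiver = strong$cell_type[j], sender_strength = ss,
        receiver_sensitivity = strong$M[j],
        interaction_score = ss * strong$M[j], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sender = character(0), cytokine = character(0),
               receiver = character(0), sender_strength = numeric(0),
               receiver_sensitivity = numeric(0),
               interaction_score = numeric(0))
  pruned <- edges[!is.na(edges$interaction_score) &
                  edges$interaction_score >= min_score, ]
  cs <- NULL
  ok <- edges[!is.na(edges$interaction_score), ]
  if (nrow(ok)) {
    cs <- tapply(ok$interaction_score, list(ok$sender, ok$receiver), sum)
    cs[is.na(cs)] <- 0
  }
  list(edges = edges, pruned = pruned, connection_strength = cs)
}

#' Cytokine-cytokine regulation calls and family roll-ups
#'
#' Per (stimulating cytokine, regulated cytokine, cell type): `"up"`
#' when every encoding gene has padj < 0.05 and log2FC > 1, `"down"`
#' when every gene has padj < 0.05 and log2FC < -1, else `"none"`.
#' Family scores per stimulation net up- against down-regulated member
#' counts (summed over cell types) and divide by the family's maximum
#' up- or down-count.
#'
#' @param det a [de_table] result.
#' @param cgmap a cytokine gene map.
#' @param padj_thresh,lfc_thresh the rule (0.05, 1).
#' @return list: `calls` data.frame and `family_scores` data.frame.
#' @export
regulation_counts <- function(det, cgmap, padj_thresh = 0.05,
                              lfc_thresh = 1) {
  pairs <- unique(det[c("cell_type", "cytokine")])
  rows <- list()
  for (reg in unique(cgmap$cytokine)) {
    genes <- cgmap$gene[cgmap$cytokine == reg]
    for (k in seq_len(nrow(pairs))) {
      d <- det[det$cell_type == pairs$cell_type[k] &
               det$cytokine == pairs$cytokine[k] & det$gene %in% genes, ]
      call <- "none"
      if (nrow(d) == length(genes)) {
        if (all(d$padj < padj_thresh & d$log2fc > lfc_thresh)) call <- "up"
        else if (all(d$padj < padj_thresh & d$log2fc < -lfc_thresh))
          call <- "down"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stim = pairs$cytokine[k], regulated = reg,
        cell_type = pairs$cell_type[k], call = call,
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  fam <- unique(cgmap[c("cytokine", "family")])
  calls$family <- fam$family[match(calls$regulated, fam$cytokine)]
  agg <- stats::aggregate(cbind(up = call == "up", down = call == "down")
                          ~ stim + family, calls, sum)
  fam_max <- pmax(stats::ave(agg$up, agg$family, FUN = max),
                  stats::ave(agg$down, agg$family, FUN = max))
  agg$score <- ifelse(fam_max > 0, (agg$up - agg$down) / fam_max, 0)
  list(calls = calls[c("stim", "regulated", "cell_type", "call",
                       "family")],
       family_scores = agg)
}

#' Infer secondary-cytokine responses
#'
#' A response of cell type Q to primary cytokine X is attributed to a
#' secondary cytokine Y when: Q is a `secondary_candidate` for X (strong
#' response without X's receptor); Y is upregulated under X
#' (log2FC > `prod_lfc`) in at least one of X's primary-target cell
#' types; Q is a `primary_target` for direct stimulation with Y; and the
#' Pearson correlation of Q's log2FC vectors under X and under Y exceeds
#' `min_cor`.
#'
#' @param det a [de_table] result.
#' @param classes data.frame (`cytokine`, `cell_type`, `class`) from
#'   [classify_targets].
#' @param cgmap a cytokine gene map.
#' @param prod_lfc upregulation threshold for the produced cytokine (1).
#' @param min_cor similarity threshold (0.5).
#' @param genes optional gene universe for the correlation (default:
#'   genes shared between the two DE result sets).
#' @return data.frame (`primary`, `secondary`, `cell_type`, `producers`,
#'   `correlation`); zero rows when nothing qualifies.
#' @export
infer_secondary <- function(det, classes, cgmap, prod_lfc = 1,
                            min_cor = 0.5, genes = NULL) {
  out <- list()
  screened <- unique(det$cytokine)
  for (x in unique(classes$cytokine)) {
    prim <- classes$cell_type[classes$cytokine == x &
                              classes$class %in% "primary_target"]
    cand <- classes$cell_type[classes$cytokine == x &
                              classes$class %in% "secondary_candidate"]
    if (!length(prim) || !length(cand)) next
    for (y in setdiff(unique(cgmap$cytokine), x)) {
      ygenes <- cgmap$gene[cgmap$cytokine == y]
      producers <- prim[vapply(prim, function(p) {
        d <- det[det$cell_type == p & det$cytokine == x &
                 det$gene %in% ygenes, ]
        nrow(d) == length(ygenes) && all(d$log2fc > prod_lfc)
      }, NA)]
      if (!length(producers)) next
      if (!y %in% screened) {
        cd_log("infer_secondary: %s never screened directly; skipped", y)
        next
      }
      y_prim <- classes$cell_type[classes$cytokine == y &
                                  classes$class %in% "primary_target"]
      for (q in intersect(cand, y_prim)) {
        dx <- det[det$cell_type == q & det$cytokine == x, ]
        dy <- det[det$cell_type == q & det$cytokine == y, ]
        g <- intersect(dx$gene, dy$gene)
        if (!is.null(genes)) g <- intersect(g, genes)
        if (length(g) < 3) next
        r <- suppressWarnings(stats::cor(
          dx$log2fc[match(g, dx$gene)], dy$log2fc[match(g, dy$gene)]))
        if (!is.na(r) && r > min_cor)
          out[[length(out) + 1L]] <- data.frame(
            primary = x, secondary = y, cell_type = q,
            producers = paste(producers, collapse = ";"),
            correlation = r, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(primary = character(0), secondary = character(0),
                      cell_type = character(0), producers = character(0),
                      correlation = numeric(0)))
  do.call(rbind, out)
}
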