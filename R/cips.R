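#' Latent factor scores container
#'
#' Holds per-cell latent factor values (e.g. from a disentangling
#' autoencoder trained elsewhere) plus per-factor, per-gene
#' interpretability scores. Training the latent model is out of scope;
#' these are an input contract.
#'
#' @param z cells x factors numeric matrix (finite values).
#' @param interpretability factors x genes matrix in [0, 1] (or a
#'   per-factor named vector of maximum scores).
#' @param factor_ids optional factor names (default: columns of `z`).
#' @return An object of class `FactorScores`.
#' @export
factor_scores <- function(z, interpretability, factor_ids = colnames(z)) {
  z <- as.matrix(z)
  if (any(!is.finite(z))) stop("factor values must be finite")
  factor_ids <- factor_ids %||% sprintf("F%03d", seq_len(ncol(z)))
  colnames(z) <- factor_ids
  if (is.null(dim(interpretability))) {
    interpretability <- matrix(interpretability, ncol = 1,
                               dimnames = list(factor_ids, "max"))
  }
  if (any(interpretability < 0 | interpretability > 1, na.rm = TRUE))
    stop("interpretability scores must lie in [0, 1]")
  if (is.null(rownames(interpretability)))
    rownames(interpretability) <- factor_ids
  structure(list(z = z, interpretability = as.matrix(interpretability),
                 factor_ids = factor_ids), class = "FactorScores")
}

#' Read factor scores from a TSV pair
#'
#' `z_path`: cells x factors table (row order must match the cells of
#' the accompanying CellCounts); `interp_path`: factors x genes
#' interpretability table with a `factor` id column.
#'
#' @param z_path,interp_path TSV files.
#' @return A [factor_scores] object.
#' @export
read_factor_scores <- function(z_path, interp_path) {
  z <- as.matrix(utils::read.delim(z_path, check.names = FALSE))
  it <- utils::read.delim(interp_path, check.names = FALSE)
  if (!"factor" %in% names(it))
    stop("interpretability table missing column: factor")
  rn <- it$factor
  it <- as.matrix(it[setdiff(names(it), "factor")])
  rownames(it) <- rn
  factor_scores(z, it[colnames(z), , drop = FALSE])
}

#' Select candidate program factors
#'
#' Keeps factors that are non-vanishing (|z| > `min_abs` in at least one
#' cell) and interpretable (at least one gene with interpretability
#' >= `min_interp`).
#'
#' @param fs a [factor_scores] object.
#' @param min_abs activity gate (1).
#' @param min_interp interpretability gate (0.5).
#' @return Character vector of retained factor ids.
#' @export
select_factors <- function(fs, min_abs = 1, min_interp = 0.5) {
  stopifnot(inherits(fs, "FactorScores"))
  active <- apply(abs(fs$z), 2, max) > min_abs
  interp <- apply(fs$interpretability, 1, max, na.rm = TRUE) >= min_interp
  fs$factor_ids[active & interp[fs$factor_ids]]
}

#' Program activity of one factor in one contrast
#'
#' `Delta = (mean z in the stimulated (donor, cell type) group - mean z
#' in the same donor/cell type's PBS well w) / max over stimulations of
#' the group mean z`. Undefined (NA) when the denominator is zero; for
#' factors whose group means are all negative the denominator can be
#' negative — `use_abs_denominator` switches to max |mean z| instead
#' (off by default; affected factors are better flagged than guessed).
#'
#' @param zbar_stim mean z of the stimulated group.
#' @param zbar_pbs mean z of the PBS-well group.
#' @param zbar_max max over stimulations of the group mean (same donor,
#'   cell type); pass the max of absolute means with
#'   `use_abs_denominator = TRUE`.
#' @param use_abs_denominator see above.
#' @return Delta, or NA.
#' @export
program_activity <- function(zbar_stim, zbar_pbs, zbar_max,
                             use_abs_denominator = FALSE) {
  den <- if (use_abs_denominator) abs(zbar_max) else zbar_max
  if (!is.finite(den) || den == 0) return(NA_real_)
  (zbar_stim - zbar_pbs) / den
}

#' Call cytokine-induced programs
#'
#' For every (factor, cell type, cytokine): each donor runs six Welch
#' t-tests of cell-level factor values against the donor's six PBS
#' wells; p-values are Bonferroni-corrected within the (cell type,
#' cytokine) condition across all retained factors. A donor passes when
#' at least `min_wells` of the six wells jointly give corrected
#' p < `p_thresh` and |Delta| >= `delta_min`. A program is called for
#' the condition when at least `min_donors` donors pass and the
#' up-vs-down donor vote differs by at least `min_vote`; direction is
#' the majority sign.
#'
#' @param fs a [factor_scores] object.
#' @param meta per-cell metadata (`donor`, `cell_type`, `condition`,
#'   `pbs_well`) aligned with the rows of `fs$z`.
#' @param factors factor ids to test (default [select_factors]).
#' @param p_thresh,min_wells,delta_min,min_donors,min_vote the calling
#'   gates (0.001, 4, 0.1, 4, 4).
#' @param n_wells PBS wells per donor (6; with fewer available wells the
#'   well quorum scales as `ceiling(min_wells / n_wells * available)`).
#' @return data.frame of class `CIPCall`: per (factor, cell_type,
#'   cytokine) `direction` (`"up"/"down"/"none"`), `n_pass`, `n_up`,
#'   `n_down`.
#' @export
call_cips <- function(fs, meta, factors = NULL, p_thresh = 0.001,
                      min_wells = 4, delta_min = 0.1, min_donors = 4,
                      min_vote = 4, n_wells = 6) {
  stopifnot(inherits(fs, "FactorScores"), nrow(meta) == nrow(fs$z))
  factors <- factors %||% select_factors(fs)
  n_prog <- length(factors)
  if (!n_prog) stop("no factors to test")
  cyts <- setdiff(unique(meta$condition), "PBS")
  out <- list()
  for (ct in unique(meta$cell_type)) {
    ct_sel <- meta$cell_type == ct
    for (cy in cyts) {
      rows <- vector("list", n_prog)
      names(rows) <- factors
      for (f in factors) rows[[f]] <- c(pass = 0L, up = 0L, down = 0L)
      for (d in unique(meta$donor)) {
        stim <- which(ct_sel & meta$donor == d & meta$condition == cy)
        if (length(stim) < 2) next
        pbs_wells <- lapply(seq_len(n_wells), function(w)
          which(ct_sel & meta$donor == d & meta$condition == "PBS" &
                meta$pbs_well == w))
        avail <- vapply(pbs_wells, function(ix) length(ix) >= 2, NA)
        if (!any(avail)) next
        need <- if (sum(avail) >= n_wells) min_wells else
          ceiling(min_wells / n_wells * sum(avail))
        # max over stimulations of the group-mean z for (d, ct)
        other <- meta$condition != "PBS" & ct_sel & meta$donor == d
        grp <- interaction(meta$condition[other], drop = TRUE)
        for (f in factors) {
          zf <- fs$z[, f]
          zmax <- max(tapply(zf[other], grp, mean))
          deltas <- pvals <- rep(NA_real_, n_wells)
          for (w in which(avail)) {
            ix <- pbs_wells[[w]]
            tt <- tryCatch(stats::t.test(zf[stim], zf[ix])$p.value,
                           error = function(e) NA_real_)
            pvals[w] <- min(tt * n_prog, 1)  # Bonferroni across programs
            deltas[w] <- program_activity(mean(zf[stim]), mean(zf[ix]),
                                          zmax)
          }
          passed <- !is.na(pvals) & pvals < p_thresh &
            !is.na(deltas) & abs(deltas) >= delta_min
          if (sum(passed) >= need) {
            dirn <- sign(stats::median(deltas[passed]))
            rows[[f]]["pass"] <- rows[[f]]["pass"] + 1L
            if (dirn > 0) rows[[f]]["up"] <- rows[[f]]["up"] + 1L
            if (dirn < 0) rows[[f]]["down"] <- rows[[f]]["down"] + 1L
          }
        }
      }
      for (f in factors) {
        v <- rows[[f]]
        call <- if (v["pass"] >= min_donors &&
                    abs(v["up"] - v["down"]) >= min_vote) {
          if (v["up"] > v["down"]) "up" else "down"
        } else "none"
        out[[length(out) + 1L]] <- data.frame(
          factor = f, cell_type = ct, cytokine = cy, direction = call,
          n_pass = unname(v["pass"]), n_up = unname(v["up"]),
          n_down = unname(v["down"]), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("CIPCall", "data.frame")
  res
}
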