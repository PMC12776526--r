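#' Default run configuration
#'
#' All pipeline thresholds surfaced as named keys with the dictionary's
#' default values. Unknown keys in overrides are rejected by name.
#'
#' @param ... overrides, e.g. `deg.padj = 0.01`.
#' @return Named list of class `RunConfig`.
#' @export
run_config <- function(...) {
  cfg <- list(
    input = NULL, output = NULL, seed = 1L,
    qc.min_genes = 400, qc.max_genes = 7000, qc.max_mito = 0.15,
    de.min_cells = 10, de.min_frac = 0.05,
    de.well_padj = 0.1, de.well_lfc = 0.25,
    deg.padj = 0.05, deg.lfc = 0.25, deg.min_wells = 4,
    ratio.thresh = 1, ratio.min_cytokines = 10, ratio.min_celltypes = 5,
    magnitude.winsor = 0.95, magnitude.pctl = 35, magnitude.clip = 1e-10,
    outlier.c1 = 0.35, outlier.c2 = 0.6,
    groups.resolution = 0.5, groups.min_shared = 3, groups.min_r = 0.7,
    network.sender_gate = 10, network.min_score = 0.25,
    cip.p = 0.001, cip.min_wells = 4, cip.delta = 0.1,
    cip.min_donors = 4, cip.min_vote = 4,
    enrich.n_perm = 20000, enrich.w = 1,
    stages = c("de", "magnitude", "donors", "network", "groups",
               "gene_sets"))
  over <- list(...)
  if (length(bad <- setdiff(names(over), names(cfg))))
    stop("unknown config key: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "RunConfig"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return `read_run_config`: a validated [run_config].
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param cfg a [run_config].
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg)[!vapply(cfg, is.null, NA)], path)
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Executes the stages in dependency order on a count triplet directory
#' (or an in-memory [CellCounts]), writing one TSV per stage plus a
#' JSON manifest (seed, stage row counts) to the output directory.
#' Deterministic under the config seed.
#'
#' @param cfg a [run_config] with `input` (triplet directory) and
#'   `output` set.
#' @param cells optional [CellCounts] overriding `cfg$input`.
#' @return The output directory, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg, cells = NULL) {
  stopifnot(inherits(cfg, "RunConfig"))
  if (is.null(cells)) {
    if (is.null(cfg$input)) stop("config needs an input directory")
    cells <- read_counts(cfg$input)
  }
  if (is.null(cfg$output)) stop("config needs an output directory")
  dir.create(cfg$output, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "cytodict",
                   version = as.character(utils::packageVersion("cytodict")),
                   seed = cfg$seed, stages = list())
  emit <- function(name, df) {
    utils::write.table(df, file.path(cfg$output, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$stages[[name]] <<- nrow(df)
  }
  pb <- pseudobulk(cells)
  det <- mag <- NULL
  for (stage in cfg$stages) {
    res <- tryCatch(switch(stage,
      de = {
        det <- de_table(pb, min_cells = cfg$de.min_cells,
                        min_frac = cfg$de.min_frac)
        det <- call_degs(det, cfg$deg.padj, cfg$deg.lfc,
                         cfg$deg.min_wells)
        emit("de", det)
      },
      magnitude = {
        mag <- magnitude_table(pb, det)
        emit("magnitude", mag$table)
        emit("tsi", data.frame(cytokine = names(mag$tsi),
                               tsi = unname(mag$tsi)))
      },
      donors = {
        rows <- list()
        for (ct in unique(det$cell_type))
          for (cy in unique(det$cytokine[det$cell_type == ct])) {
            prof <- donor_profile(pb, det, ct, cy, seed = cfg$seed)
            if (!is.null(prof$outliers)) {
              o <- prof$outliers
              o$cell_type <- ct; o$cytokine <- cy
              rows[[length(rows) + 1L]] <- o
            }
          }
        emit("donor_outliers", if (length(rows)) do.call(rbind, rows)
             else data.frame())
      },
      network = {
        mt <- mag$table
        emit("strong_impact",
             mt[mt$strong_impact %in% TRUE,
                c("cell_type", "cytokine", "M", "threshold")])
      },
      groups = {
        strongs <- split(stats::setNames(mag$table$strong_impact,
                                         mag$table$cytokine),
                         mag$table$cell_type)
        assigns <- list()
        for (ct in unique(det$cell_type)) {
          S <- similarity_matrix(det, pb, ct)
          assigns[[ct]] <- leiden_groups(S, strongs[[ct]],
                                         cfg$groups.resolution,
                                         seed = cfg$seed)
        }
        assigns <- Filter(Negate(is.null), assigns)
        if (length(assigns) >= 2) {
          cons <- consensus_groups(assigns, cfg$groups.resolution,
                                   seed = cfg$seed)
          emit("consensus_groups",
               data.frame(cytokine = names(cons$membership),
                          group = unname(cons$membership)))
        } else emit("consensus_groups", data.frame())
      },
      gene_sets = {
        sets <- deg_gene_sets(det, pb, lfc_min = cfg$deg.lfc,
                              cpm_min = 0)
        if (length(sets))
          write_gmt(sets, file.path(cfg$output, "gene_sets.gmt"))
        manifest$stages[["gene_sets"]] <- length(sets)
      },
      stop("unknown stage: ", stage)),
      error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e)))
  }
  jsonlite::write_json(manifest, file.path(cfg$output, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg$output)
}
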