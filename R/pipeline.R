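# Orchestration: run every analysis stage from file inputs to a bundle of
# TSV/SIF outputs plus a reproducibility manifest.

#' Pipeline configuration
#'
#' @param expression,sample_sheet,sif input paths (required).
#' @param edge_attr optional SIF edge-attribute TSV (FBS per edge).
#' @param go_map optional gene-to-GO map path; when absent the GO-GO
#'   stage is skipped with a warning.
#' @param out_dir output directory (created if needed).
#' @param alpha,plc_high,plc_low,fbs_min,chi_min,o_min,e_min analysis
#'   thresholds (defaults 0.01, 0.75, 0.5, 3, 6.64, 3, 0.5).
#' @param n_perm permutations for the DEL FDR (default 20; 0 skips it).
#' @param n_draws null draws for linkage statistics (default 1000).
#' @param seed RNG seed (required: every stochastic stage derives from it).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, sample_sheet, sif,
                            edge_attr = NULL, go_map = NULL,
                            out_dir = "delink_out",
                            alpha = 0.01, plc_high = 0.75, plc_low = 0.5,
                            fbs_min = 3, chi_min = 6.64, o_min = 3,
                            e_min = 0.5, n_perm = 20, n_draws = 1000,
                            seed) {
  if (missing(seed)) .stopf("pipeline_config requires a seed")
  structure(list(expression = expression, sample_sheet = sample_sheet,
                 sif = sif, edge_attr = edge_attr, go_map = go_map,
                 out_dir = out_dir, alpha = alpha, plc_high = plc_high,
                 plc_low = plc_low, fbs_min = fbs_min, chi_min = chi_min,
                 o_min = o_min, e_min = e_min, n_perm = n_perm,
                 n_draws = n_draws, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: read inputs; per-gene ANOVA and DE calls; DEL detection (plus
#' permutation FDR when `n_perm > 0`); DEL-enriched modules; day-1 linkage
#' statistics; GO-GO meta-flow network (skipped with a warning when no GO
#' map is configured). Each stage writes its TSV/SIF outputs under
#' `out_dir`; a `manifest.json` records parameters, seed, package and R
#' versions and input checksums, which suffices to reproduce the run.
#' A stage failure aborts with a stage-named error.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`dataset`, `network`, `anova`, `de`, `dels`, `fdr`, `modules`,
#'   `linkage`, `gogo`) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    files <<- c(files, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  res <- list()
  stage("input", {
    res$dataset <- read_expression(config$expression, config$sample_sheet)
    res$network <- read_sif(config$sif, config$edge_attr)
  })
  stage("diffexpr", {
    res$anova <- gene_anova(res$dataset)
    res$de <- call_de(res$anova, alpha = config$alpha)
    tab <- res$anova
    tab$de_days <- vapply(res$de$de_days, paste, "", collapse = ",")
    tab$first_de_day <- res$de$first_de_day
    tab$developmental <- res$de$developmental
    write.table(tab, out("gene_anova.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  params <- del_params(plc_high = config$plc_high, plc_low = config$plc_low,
                       alpha = config$alpha, fbs_min = config$fbs_min)
  stage("dels", {
    res$dels <- detect_dels(res$dataset, res$network, params)
    write_dels(res$dels, out("dels.tsv"),
               sif_prefix = file.path(config$out_dir, "dels"))
    if (config$n_perm > 0) {
      res$fdr <- estimate_del_fdr(res$dataset, res$network, params,
                                  n_perm = max(config$n_perm, 20),
                                  seed = config$seed)
    }
  })
  stage("modules", {
    net <- .filter_fbs(restrict_to_measured(res$network, res$dataset),
                       config$fbs_min)
    res$modules <- find_modules(net, res$dels)
    write_modules(res$modules, out("modules.tsv"))
  })
  stage("propagation", {
    net <- restrict_to_measured(res$network, res$dataset)
    res$linkage <- linkage_stats(net, res$de, n_draws = config$n_draws,
                                 seed = config$seed,
                                 fbs_min = config$fbs_min)
    write_linkage_stats(res$linkage, out("linkage_stats.tsv"),
                        out("linkage_per_seed.tsv"))
  })
  if (is.null(config$go_map)) {
    .warnf("no GO map configured; skipping the GO-GO stage")
  } else {
    stage("gogo", {
      go <- read_go_map(config$go_map)
      res$gogo <- build_metaflow(
        restrict_to_measured(res$network, res$dataset), res$de, go,
        gogo_params(chi_min = config$chi_min, o_min = config$o_min,
                    e_min = config$e_min, fbs_min = config$fbs_min))
      write_gogo(res$gogo, file.path(config$out_dir, "gogo"))
      files <- c(files, file.path(config$out_dir,
                                  c("gogo.sif", "gogo_edges.tsv",
                                    "gogo_nodes.tsv")))
    })
  }
  manifest <- list(
    parameters = config[setdiff(names(config),
                                c("expression", "sample_sheet", "sif",
                                  "edge_attr", "go_map", "out_dir"))],
    seed = config$seed,
    package = as.character(packageVersion("delink")),
    r_version = R.version.string,
    inputs = lapply(
      Filter(Negate(is.null),
             config[c("expression", "sample_sheet", "sif", "edge_attr",
                      "go_map")]),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$files <- files
  invisible(res)
}
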