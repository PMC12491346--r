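#' Run the base-case analysis from a configuration file
#'
#' Reads and validates the model configuration, evaluates the base case and
#' writes a report bundle to `out_dir`: `base_case.csv` and `base_case.json`
#' (node values, per-strategy effectiveness, incremental effectiveness,
#' per-lesion costs, ICER/CER — unformatted machine values), a per-modality
#' cost breakdown `cost_breakdown.csv`, and a human-readable
#' `base_case.txt`. Files are written to a staging directory and moved into
#' place together, so a failing stage never leaves partial output.
#'
#' @param config_path Path to a model configuration file
#'   (see [read_model_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The fitted [cea_model], invisibly; written file paths in
#'   attribute `"files"`.
#' @export
run_base_case <- function(config_path, out_dir = ".") {
  cfg <- read_model_config(config_path)
  fit <- cea_model(cfg$nodes, costs = cfg$costs)
  files <- write_staged(out_dir, function(stage) {
    s <- summary(fit)
    utils::write.csv(s$table, file.path(stage, "base_case.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(model = fit$model_id,
           nodes = as.list(fit$nodes$values),
           effectiveness = as.list(fit$effectiveness$eff_by_strategy),
           incremental_effectiveness = fit$effectiveness$incremental,
           cost_per_lesion = as.list(fit$cost_per_lesion),
           ratio_type = fit$ratio_type, ratio = fit$ratio,
           theoretical = fit$theoretical),
      file.path(stage, "base_case.json"), auto_unbox = TRUE, digits = NA)
    breakdown <- do.call(rbind, lapply(names(fit$costs$items_by_modality),
      function(m) cbind(modality = m,
                        as.data.frame(fit$costs$items_by_modality[[m]]))))
    utils::write.csv(breakdown, file.path(stage, "cost_breakdown.csv"),
                     row.names = FALSE)
    con <- file(file.path(stage, "base_case.txt"), "w")
    on.exit(close(con))
    sink(con); print(s); sink()
  })
  message(sprintf("[base] %s: eff %s | %s EUR %s",
                  fit$model_id,
                  paste(format_percent(fit$effectiveness$eff_by_strategy),
                        collapse = "/"),
                  fit$ratio_type, format_eur(fit$ratio)))
  invisible(structure(fit, files = files))
}

#' Run the full pipeline: base case, DSA, PSA, manifest
#'
#' Reproduces every stage of the analysis in one call: the base-case report
#' (as [run_base_case()]), the one-way deterministic sensitivity analysis
#' over the configuration's intervals (`dsa.csv`, tornado-ordered, base
#' values echoed), the Monte Carlo probabilistic sensitivity analysis
#' (`psa_draws.csv`, `psa_summary.csv`, `psa_summary.json`), and a run
#' manifest (`manifest.json`: config file hash, seed, draw count, package
#' version, timestamp, output inventory) written last. Identical
#' configuration and seed give byte-identical draw tables. A failing stage
#' aborts with its name and leaves earlier stages' outputs intact.
#'
#' @param config_path Path to a model configuration file.
#' @param seed Integer seed for the PSA.
#' @param n_draws Number of PSA draws; default from the configuration
#'   (10000). Report tolerances on Monte Carlo summaries scale as
#'   `1/sqrt(n_draws)`.
#' @param out_dir Output directory.
#' @return List with elements `fit`, `dsa`, `psa`, `manifest`, invisibly.
#' @export
run_full <- function(config_path, seed = 1L, n_draws = NULL, out_dir = ".") {
  cfg <- read_model_config(config_path)
  if (is.null(n_draws)) n_draws <- cfg$psa$n_draws
  stage_of <- "base case"
  result <- tryCatch({
    fit <- run_base_case(config_path, out_dir)

    stage_of <- "deterministic sensitivity analysis"
    dsa_tab <- NULL
    if (nrow(cfg$dsa) > 0) {
      dsa_tab <- tornado_table(fit, cfg$dsa)
      write_staged(out_dir, function(stage) {
        out <- as.data.frame(dsa_tab)
        out$base_ratio <- attr(dsa_tab, "base_ratio")
        out$base_eff <- attr(dsa_tab, "base_eff")
        utils::write.csv(out, file.path(stage, "dsa.csv"), row.names = FALSE)
      })
      message(sprintf("[dsa] widest bar %s (ratio range %s-%s EUR)",
                      dsa_tab$node_id[1], format_eur(min(dsa_tab$ratio_low)),
                      format_eur(max(dsa_tab$ratio_high))))
    }

    stage_of <- "probabilistic sensitivity analysis"
    psa_res <- run_psa(fit, psa_config(n_draws = n_draws, seed = seed,
                                       cost_cv = cfg$psa$cost_cv))
    write_staged(out_dir, function(stage) {
      utils::write.csv(psa_res$draws, file.path(stage, "psa_draws.csv"),
                       row.names = FALSE)
      utils::write.csv(psa_res$summary, file.path(stage, "psa_summary.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(summary = psa_res$summary,
             summary_ratio = psa_res$summary_ratio,
             mean_of_ratios = psa_res$mean_of_ratios,
             n_excluded = psa_res$n_excluded,
             n_ratio_excluded = psa_res$n_ratio_excluded),
        file.path(stage, "psa_summary.json"), auto_unbox = TRUE, digits = NA)
    })
    message(sprintf("[psa] %d draws, mean %s EUR %s", n_draws,
                    psa_res$ratio_type, format_eur(psa_res$summary_ratio)))

    stage_of <- "manifest"
    outputs <- c("base_case.csv", "base_case.json", "base_case.txt",
                 "cost_breakdown.csv",
                 if (!is.null(dsa_tab)) "dsa.csv",
                 "psa_draws.csv", "psa_summary.csv", "psa_summary.json")
    manifest <- list(
      config = basename(config_path),
      config_md5 = unname(tools::md5sum(config_path)),
      seed = seed, n_draws = n_draws,
      package_version = as.character(utils::packageVersion("fetcea")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      outputs = outputs
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(fit = fit, dsa = dsa_tab, psa = psa_res, manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed during ", stage_of, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# write outputs atomically: build in a staging dir, then move into out_dir
write_staged <- function(out_dir, writer) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- tempfile("fetcea_stage_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  writer(stage)
  files <- list.files(stage, full.names = TRUE)
  dest <- file.path(out_dir, basename(files))
  ok <- file.copy(files, dest, overwrite = TRUE)
  if (!all(ok)) stop("failed to move report files into ", out_dir, call. = FALSE)
  dest
}
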