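#' Fit a diagnostic decision-tree cost-effectiveness model
#'
#' The central object of the package: combines chance-node probabilities of
#' one of the two decision trees with an imaging cost profile, evaluates the
#' effectiveness (probability of correct identification of treatment-related
#' changes) per strategy, and derives per-lesion costs and the incremental
#' (model 1) or plain (model 2) cost-effectiveness ratio.
#'
#' `nodes` may instead be a lesion-level dataset (data frame), in which case
#' the chance-node probabilities are first estimated from it with
#' [estimate_nodes()] — the package's analogue of fitting a model to data.
#'
#' Strategy cost structure: in model 1 the combined strategy uses one PET and
#' one MRI scan per identification, the reference strategy one MRI scan, and
#' both per-lesion costs carry the scan factor `n_scans / n_lesions`; in
#' model 2 one PET scan. The ICER numerator therefore equals the PET per-scan
#' cost times the scan factor.
#'
#' @param nodes A [node_probs] object, or a lesion dataset to estimate them
#'   from.
#' @param costs A [cost_profile]; defaults to the bundled fee schedules with
#'   the cohort scan totals of the corresponding study fixture (92/83 for
#'   model 1, 22/22 for model 2).
#' @param model_id Required when `nodes` is a dataset; otherwise taken from
#'   `nodes`.
#' @return An object of class `"cea_model"`: list with `model_id`, `nodes`,
#'   `costs`, `effectiveness` (an `effectiveness_result`), `cost_per_lesion`
#'   (named by strategy), `ratio` (ICER for model 1, CER for model 2),
#'   `ratio_type`, and flags `theoretical` and `dominated` (negative
#'   incremental effectiveness).
#' @examples
#' fit <- cea_model(study_fixture("model2"), model_id = "model2")
#' summary(fit)
#' @export
cea_model <- function(nodes, costs = NULL, model_id = NULL) {
  if (is.data.frame(nodes)) {
    if (is.null(model_id)) {
      stop("supply model_id when fitting from a lesion dataset", call. = FALSE)
    }
    data <- nodes
    nodes <- estimate_nodes(data, model_id)
  }
  if (!inherits(nodes, "node_probs")) {
    stop("'nodes' must be a node_probs object or a lesion dataset", call. = FALSE)
  }
  model_id <- nodes$model_id
  if (is.null(costs)) costs <- default_cost_profile(model_id)
  if (!inherits(costs, "cost_profile")) {
    stop("'costs' must be a cost_profile object", call. = FALSE)
  }

  eff <- evaluate_model(nodes)
  factor_sc <- costs$n_scans / costs$n_lesions
  per_scan <- vapply(costs$items_by_modality, scan_cost, numeric(1))

  if (model_id == "model1") {
    if (!all(c("pet", "mri") %in% names(per_scan))) {
      stop("model1 cost profile needs 'pet' and 'mri' fee schedules", call. = FALSE)
    }
    cost_per_lesion <- c(
      combined = per_lesion_cost(per_scan[["pet"]] + per_scan[["mri"]],
                                 costs$n_scans, costs$n_lesions),
      mri = per_lesion_cost(per_scan[["mri"]], costs$n_scans, costs$n_lesions)
    )
    ratio <- icer(cost_per_lesion[["combined"]], cost_per_lesion[["mri"]],
                  eff$incremental)
    ratio_type <- "ICER"
    dominated <- eff$incremental < 0
  } else {
    if (!"pet" %in% names(per_scan)) {
      stop("model2 cost profile needs a 'pet' fee schedule", call. = FALSE)
    }
    cost_per_lesion <- c(
      pet = per_lesion_cost(per_scan[["pet"]], costs$n_scans, costs$n_lesions)
    )
    ratio <- cer(cost_per_lesion[["pet"]], eff$eff_by_strategy[["pet"]])
    ratio_type <- "CER"
    dominated <- FALSE
  }

  structure(
    list(model_id = model_id, nodes = nodes, costs = costs,
         effectiveness = eff, scan_cost = per_scan, scan_factor = factor_sc,
         cost_per_lesion = cost_per_lesion, ratio = ratio,
         ratio_type = ratio_type,
         theoretical = eff$theoretical, dominated = dominated),
    class = "cea_model"
  )
}

# Bundled cost profiles matching the two study cohorts.
default_cost_profile <- function(model_id) {
  if (model_id == "model1") {
    cost_profile(list(pet = default_fee_schedule("pet"),
                      mri = default_fee_schedule("mri")),
                 n_scans = 92, n_lesions = 83)
  } else {
    cost_profile(list(pet = default_fee_schedule("pet")),
                 n_scans = 22, n_lesions = 22)
  }
}

#' @export
print.cea_model <- function(x, ...) {
  cat("Decision-tree cost-effectiveness model (", x$model_id, ")\n", sep = "")
  print(x$effectiveness)
  cat("Per-lesion cost (EUR):",
      paste(sprintf("%s %s", names(x$cost_per_lesion),
                    format_eur(x$cost_per_lesion)), collapse = ", "), "\n")
  cat(sprintf("%s: EUR %s per %scorrectly identified TRC lesion\n",
              x$ratio_type, format_eur(x$ratio),
              if (x$ratio_type == "ICER") "additional " else ""))
  if (x$dominated) cat("note: dominated (negative incremental effectiveness)\n")
  invisible(x)
}

#' @export
summary.cea_model <- function(object, ...) {
  x <- object
  eff <- x$effectiveness$eff_by_strategy
  rows <- data.frame(
    quantity = c(paste0("effectiveness_", names(eff)),
                 if (!is.null(x$effectiveness$incremental)) "incremental_effectiveness",
                 paste0("cost_per_lesion_", names(x$cost_per_lesion)),
                 tolower(x$ratio_type)),
    value = c(unname(eff), x$effectiveness$incremental,
              unname(x$cost_per_lesion), x$ratio),
    stringsAsFactors = FALSE
  )
  rows$display <- c(
    vapply(c(unname(eff), x$effectiveness$incremental), format_percent,
           character(1)),
    format_eur(c(unname(x$cost_per_lesion), x$ratio))
  )
  structure(list(model_id = x$model_id, table = rows,
                 nodes = x$nodes$values, theoretical = x$theoretical),
            class = "summary.cea_model")
}

#' @export
print.summary.cea_model <- function(x, ...) {
  cat("Base case (", x$model_id, ")\n", sep = "")
  cat("Chance nodes:",
      paste(sprintf("%s=%s", names(x$nodes), format_percent(x$nodes)),
            collapse = " "), "\n")
  print(x$table, row.names = FALSE)
  if (x$theoretical) cat("(theoretical values present)\n")
  invisible(x)
}

#' @export
coef.cea_model <- function(object, ...) object$nodes$values
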