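#' Read a model configuration file
#'
#' Parses a YAML (or JSON) model specification with blocks:
#' \describe{
#'   \item{model}{`model1` or `model2`.}
#'   \item{nodes}{Per chance node: `value` (probability; a fraction string
#'     such as `"54/83"` is accepted and kept exact), optional `sd`, optional
#'     `dsa_low`/`dsa_high` interval for the deterministic sensitivity
#'     analysis.}
#'   \item{costs}{Per modality, a list of `{code, label, amount_eur}` fee
#'     items; omitted modalities fall back to the bundled fee schedules.}
#'   \item{cohort}{`n_lesions` and `n_scans` defining the scan factor.}
#'   \item{psa}{Optional defaults: `n_draws`, `cost_cv`.}
#' }
#' The two bundled examples encode the study models:
#' `system.file("extdata", "model1.yaml", package = "fetcea")` and
#' `.../model2.yaml`.
#'
#' @param path Path to the configuration file.
#' @return A list of class `"cea_config"` with elements `model_id`, `nodes`
#'   (a [node_probs] with SDs), `costs` (a [cost_profile]), `dsa` (data frame
#'   `node_id`/`low`/`high`, possibly empty), `psa` (list), `path`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)

  fail <- function(field, why) {
    stop("invalid config '", path, "': field ", field, " ", why, call. = FALSE)
  }
  if (is.null(raw$model)) fail("model", "is missing")
  model_id <- as.character(raw$model)
  if (!model_id %in% c("model1", "model2")) fail("model", "must be model1 or model2")
  ids <- model_node_ids(model_id)

  if (is.null(raw$nodes)) fail("nodes", "is missing")
  for (id in ids) {
    if (is.null(raw$nodes[[id]]) || is.null(raw$nodes[[id]]$value)) {
      fail(paste0("nodes.", id, ".value"), "is missing")
    }
  }
  values <- vapply(ids, function(id) parse_prob(raw$nodes[[id]]$value,
                                                paste0("nodes.", id, ".value")),
                   numeric(1))
  sds <- vapply(ids, function(id) {
    s <- raw$nodes[[id]]$sd
    if (is.null(s)) 0 else as.numeric(s)
  }, numeric(1))
  nodes <- node_probs(model_id, stats::setNames(values, ids),
                      sds = stats::setNames(sds, ids))

  dsa_rows <- lapply(ids, function(id) {
    nd <- raw$nodes[[id]]
    if (is.null(nd$dsa_low) && is.null(nd$dsa_high)) return(NULL)
    if (is.null(nd$dsa_low) || is.null(nd$dsa_high)) {
      fail(paste0("nodes.", id), "needs both dsa_low and dsa_high")
    }
    data.frame(node_id = id,
               low = parse_prob(nd$dsa_low, paste0("nodes.", id, ".dsa_low")),
               high = parse_prob(nd$dsa_high, paste0("nodes.", id, ".dsa_high")),
               stringsAsFactors = FALSE)
  })
  dsa <- do.call(rbind, dsa_rows)
  if (is.null(dsa)) dsa <- data.frame(node_id = character(), low = numeric(),
                                      high = numeric())

  cohort <- raw$cohort
  if (is.null(cohort$n_lesions) || is.null(cohort$n_scans)) {
    fail("cohort", "needs n_lesions and n_scans")
  }
  modalities <- if (model_id == "model1") c("pet", "mri") else "pet"
  items <- lapply(stats::setNames(modalities, modalities), function(m) {
    entries <- raw$costs[[m]]
    if (is.null(entries)) return(default_fee_schedule(m))
    fee_schedule(
      code = vapply(entries, function(e) as.character(e$code), character(1)),
      label = vapply(entries, function(e) as.character(e$label), character(1)),
      amount_eur = vapply(entries, function(e) as.numeric(e$amount_eur),
                          numeric(1))
    )
  })
  costs <- cost_profile(items, n_scans = cohort$n_scans,
                        n_lesions = cohort$n_lesions)

  psa <- raw$psa
  structure(
    list(model_id = model_id, nodes = nodes, costs = costs, dsa = dsa,
         psa = list(
           n_draws = if (is.null(psa$n_draws)) 10000L else as.integer(psa$n_draws),
           cost_cv = if (is.null(psa$cost_cv)) 0.5 else as.numeric(psa$cost_cv)
         ),
         path = normalizePath(path)),
    class = "cea_config"
  )
}

# probabilities in configs may be decimals or exact fraction strings "a/b"
parse_prob <- function(x, field) {
  if (is.character(x) && grepl("^\\s*[0-9.]+\\s*/\\s*[0-9.]+\\s*$", x)) {
    parts <- as.numeric(strsplit(x, "/")[[1]])
    return(parts[1] / parts[2])
  }
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    stop("invalid config: field ", field, " is not a number or fraction",
         call. = FALSE)
  }
  v
}

#' Path to a bundled example model configuration
#'
#' @param model_id `"model1"` or `"model2"`.
#' @return Path to the installed `model1.yaml` / `model2.yaml`.
#' @export
example_config <- function(model_id = c("model1", "model2")) {
  model_id <- match.arg(model_id)
  system.file("extdata", paste0(model_id, ".yaml"), package = "fetcea",
              mustWork = TRUE)
}
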