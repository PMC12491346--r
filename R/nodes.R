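#' Diagnosis labels
#'
#' Every imaging rating and every confirmed diagnosis in this package takes
#' one of exactly two values: `"relapse"` (tumor relapse) or `"trc"`
#' (treatment-related changes, i.e. non-neoplastic post-therapeutic imaging
#' changes that mimic relapse on MRI).
#'
#' @return Character vector of the two valid labels, in canonical order.
#' @export
diagnosis_levels <- function() c("relapse", "trc")

# Node sets per decision tree. Model 1 compares combined PET+MRI against MRI
# alone; model 2 scores PET alone in lesions already suspicious on MRI.
#   model1: N1 = P(rated relapse, combined)   N2 = P(rated relapse, MRI)
#           N3 = P(confirmed relapse | combined rated relapse)
#           N4 = P(confirmed trc     | combined rated trc)
#           N5 = P(confirmed relapse | MRI rated relapse)
#           N6 = P(confirmed trc     | MRI rated trc)
#   model2: N1 = P(rated relapse, PET)
#           N2 = P(confirmed relapse | rated relapse)
#           N3 = P(confirmed trc     | rated trc)
model_node_ids <- function(model_id) {
  switch(model_id,
    model1 = paste0("N", 1:6),
    model2 = paste0("N", 1:3),
    stop("unknown model_id: ", model_id, " (expected 'model1' or 'model2')",
         call. = FALSE)
  )
}

#' Chance-node probabilities of a decision tree
#'
#' Bundles the chance-node probability values of one of the two decision
#' trees, optionally with per-node standard deviations (used by the
#' probabilistic sensitivity analysis).
#'
#' Base-case values must lie in \[0, 1\]. Values outside that range are only
#' meaningful in sensitivity-analysis contexts ("theoretical" values, e.g. a
#' relapse-confirmation probability varied above 100%); pass
#' `allow_theoretical = TRUE` to accept strictly positive values above 1.
#'
#' @param model_id `"model1"` (combined PET+MRI vs MRI alone, nodes N1-N6)
#'   or `"model2"` (PET alone, nodes N1-N3).
#' @param values Named numeric vector of node probabilities; names must be
#'   exactly the node set of `model_id`.
#' @param sds Optional named numeric vector of standard deviations (same
#'   names), all non-negative.
#' @param allow_theoretical Accept node values above 1 (flagged, not
#'   clamped). Default `FALSE`: base-case validation.
#'
#' @return An object of class `"node_probs"`: a list with elements
#'   `model_id`, `values`, `sds` and logical `theoretical` (any value
#'   outside \[0, 1\]).
#' @examples
#' node_probs("model2", c(N1 = 10/22, N2 = 9/10, N3 = 9/12))
#' @export
node_probs <- function(model_id, values, sds = NULL, allow_theoretical = FALSE) {
  model_id <- match.arg(model_id, c("model1", "model2"))
  ids <- model_node_ids(model_id)
  if (!is.numeric(values) || is.null(names(values))) {
    stop("'values' must be a named numeric vector", call. = FALSE)
  }
  if (!setequal(names(values), ids) || anyDuplicated(names(values))) {
    missing <- setdiff(ids, names(values))
    extra <- setdiff(names(values), ids)
    stop("node set must be exactly {", paste(ids, collapse = ", "), "}",
         if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  values <- values[ids]
  if (anyNA(values)) stop("node values must not be NA", call. = FALSE)
  if (any(values < 0)) stop("node values must be positive", call. = FALSE)
  if (any(values > 1) && !allow_theoretical) {
    stop("node value(s) above 1: ",
         paste(ids[values > 1], collapse = ", "),
         " (theoretical values are only allowed in sensitivity analyses;",
         " set allow_theoretical = TRUE)", call. = FALSE)
  }
  if (!is.null(sds)) {
    if (!is.numeric(sds) || is.null(names(sds)) || !setequal(names(sds), ids)) {
      stop("'sds' must be a named numeric vector over the same node set",
           call. = FALSE)
    }
    sds <- sds[ids]
    if (anyNA(sds) || any(sds < 0)) {
      stop("standard deviations must be non-negative and not NA", call. = FALSE)
    }
  }
  structure(
    list(model_id = model_id, values = values, sds = sds,
         theoretical = any(values > 1)),
    class = "node_probs"
  )
}

#' @export
print.node_probs <- function(x, digits = 4, ...) {
  cat("Chance-node probabilities (", x$model_id, ")\n", sep = "")
  tab <- data.frame(value = round(x$values, digits))
  if (!is.null(x$sds)) tab$sd <- round(x$sds, digits)
  print(tab)
  if (x$theoretical) cat("note: contains theoretical values > 1\n")
  invisible(x)
}

#' Estimate chance-node probabilities from a lesion-level dataset
#'
#' Recovers the chance-node probabilities of a decision tree as empirical
#' conditional proportions from per-lesion records. Ratings are lesion-level:
#' repeated scans of a lesion contribute once to node estimation (and
#' `n_scans` times to cost).
#'
#' @param data A lesion dataset as returned by [generate_cohort()] or
#'   [study_fixture()], or any data frame with columns `rating_combined`
#'   (model 1: combined PET+MRI rating; model 2: the PET rating),
#'   `rating_reference` (model 1 only: MRI-alone rating) and `confirmed`,
#'   each taking values `"relapse"`/`"trc"`.
#' @param model_id `"model1"` or `"model2"`.
#' @param nodes Optional character vector of node ids to estimate. By default
#'   all nodes of the model are estimated and returned as a [node_probs]
#'   object; a node whose conditioning subset is empty (e.g. N3 when no
#'   lesion was rated relapse) is then an error. With `nodes` given, only the
#'   requested nodes are computed and returned as a named numeric vector.
#'
#' @return A [node_probs] object (SDs unset), or a named numeric vector when
#'   `nodes` is supplied.
#' @export
estimate_nodes <- function(data, model_id, nodes = NULL) {
  model_id <- match.arg(model_id, c("model1", "model2"))
  data <- as.data.frame(data)
  check_labels <- function(x, what) {
    if (!all(x %in% diagnosis_levels())) {
      stop(what, " must be 'relapse' or 'trc'", call. = FALSE)
    }
  }
  if (nrow(data) == 0L) stop("empty lesion dataset", call. = FALSE)
  if (!"rating_combined" %in% names(data) || anyNA(data$rating_combined)) {
    stop("every record needs a 'rating_combined' rating for ", model_id,
         call. = FALSE)
  }
  check_labels(data$rating_combined, "rating_combined")
  check_labels(data$confirmed, "confirmed")

  cond_prop <- function(event, subset, node) {
    if (!any(subset)) {
      stop("cannot estimate ", node, ": no lesions in its conditioning subset",
           call. = FALSE)
    }
    mean(event[subset])
  }
  rel <- function(x) x == "relapse"
  trc <- function(x) x == "trc"

  if (model_id == "model1") {
    if (!"rating_reference" %in% names(data) || anyNA(data$rating_reference)) {
      stop("model1 needs a 'rating_reference' (MRI-alone) rating on every record",
           call. = FALSE)
    }
    check_labels(data$rating_reference, "rating_reference")
    rc <- data$rating_combined; rr <- data$rating_reference; cf <- data$confirmed
    estimators <- list(
      N1 = function() mean(rel(rc)),
      N2 = function() mean(rel(rr)),
      N3 = function() cond_prop(rel(cf), rel(rc), "N3"),
      N4 = function() cond_prop(trc(cf), trc(rc), "N4"),
      N5 = function() cond_prop(rel(cf), rel(rr), "N5"),
      N6 = function() cond_prop(trc(cf), trc(rr), "N6")
    )
  } else {
    rc <- data$rating_combined; cf <- data$confirmed
    estimators <- list(
      N1 = function() mean(rel(rc)),
      N2 = function() cond_prop(rel(cf), rel(rc), "N2"),
      N3 = function() cond_prop(trc(cf), trc(rc), "N3")
    )
  }
  if (!is.null(nodes)) {
    bad <- setdiff(nodes, names(estimators))
    if (length(bad)) {
      stop("unknown node(s) for ", model_id, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    return(vapply(stats::setNames(nodes, nodes),
                  function(id) estimators[[id]](), numeric(1)))
  }
  node_probs(model_id, vapply(estimators, function(f) f(), numeric(1)))
}
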