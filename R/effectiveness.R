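# Tolerance below which an effectiveness denominator (the confirmed-TRC
# fraction of the cohort) is treated as zero, i.e. effectiveness undefined.
.eff_denom_tol <- 1e-12

#' Probability of correctly identifying treatment-related changes
#'
#' The effectiveness statistic of both decision trees: among lesions whose
#' confirmed diagnosis is treatment-related changes (TRC), the fraction that
#' the imaging strategy rated as TRC. Walking the tree,
#' `(1 - p_rated_relapse) * p_confirm_trc` is the mass of lesions rated TRC
#' and confirmed TRC, while confirmed-TRC lesions arise on two branches:
#' rated relapse but not confirmed (`p_rated_relapse * (1 - p_confirm_relapse)`)
#' and rated TRC and confirmed (`(1 - p_rated_relapse) * p_confirm_trc`), so
#'
#' \deqn{eff = \frac{(1-p_1)\,p_t}{p_1 (1-p_r) + (1-p_1)\,p_t}}
#'
#' with \eqn{p_1} = `p_rated_relapse`, \eqn{p_r} = `p_confirm_relapse`,
#' \eqn{p_t} = `p_confirm_trc`. When every rated-relapse call is confirmed
#' (\eqn{p_r = 1}) the statistic equals 1 for any rating rate: no confirmed
#' TRC lesion can hide in the rated-relapse branch.
#'
#' Arguments may lie outside \[0, 1\] (theoretical sensitivity-analysis
#' values); the result is then itself flagged theoretical by callers, never
#' clamped. All arguments are vectorized.
#'
#' @param p_rated_relapse Probability that a lesion is rated tumor relapse.
#' @param p_confirm_relapse Probability that a rated-relapse lesion is
#'   confirmed as relapse.
#' @param p_confirm_trc Probability that a rated-TRC lesion is confirmed as
#'   treatment-related changes.
#'
#' @return Effectiveness fraction(s). An error is raised if any denominator
#'   is within tolerance of zero (no confirmed-TRC lesions: effectiveness
#'   undefined).
#' @examples
#' trc_identification_rate(10/22, 9/10, 9/12) # 0.90
#' @export
trc_identification_rate <- function(p_rated_relapse, p_confirm_relapse,
                                    p_confirm_trc) {
  num <- (1 - p_rated_relapse) * p_confirm_trc
  den <- p_rated_relapse * (1 - p_confirm_relapse) + num
  if (any(abs(den) < .eff_denom_tol)) {
    stop("undefined effectiveness: the confirmed-TRC fraction of the cohort ",
         "is zero (denominator below tolerance)", call. = FALSE)
  }
  num / den
}

#' Evaluate a decision tree's effectiveness
#'
#' Computes the effectiveness (probability of correct identification of
#' treatment-related changes) per strategy and, for the two-strategy model 1,
#' the incremental effectiveness (combined PET+MRI minus MRI alone).
#'
#' @param nodes A [node_probs] object.
#' @return An object of class `"effectiveness_result"`: list with
#'   `eff_by_strategy` (model 1: `combined`, `mri`; model 2: `pet`),
#'   `incremental` (model 1 only, else `NULL`), and a logical `theoretical`
#'   flag set when any input node or any effectiveness leaves \[0, 1\].
#' @examples
#' evaluate_model(node_probs("model2", c(N1 = 10/22, N2 = 9/10, N3 = 9/12)))
#' @export
evaluate_model <- function(nodes) {
  if (!inherits(nodes, "node_probs")) {
    stop("'nodes' must be a node_probs object", call. = FALSE)
  }
  v <- nodes$values
  if (nodes$model_id == "model1") {
    eff <- c(
      combined = trc_identification_rate(v[["N1"]], v[["N3"]], v[["N4"]]),
      mri      = trc_identification_rate(v[["N2"]], v[["N5"]], v[["N6"]])
    )
    incremental <- unname(eff[["combined"]] - eff[["mri"]])
  } else {
    eff <- c(pet = trc_identification_rate(v[["N1"]], v[["N2"]], v[["N3"]]))
    incremental <- NULL
  }
  structure(
    list(
      model_id = nodes$model_id,
      eff_by_strategy = eff,
      incremental = incremental,
      theoretical = any(v > 1) || any(eff > 1) || any(eff < 0)
    ),
    class = "effectiveness_result"
  )
}

#' @export
print.effectiveness_result <- function(x, ...) {
  cat("Effectiveness (correct identification of treatment-related changes)\n")
  for (s in names(x$eff_by_strategy)) {
    cat(sprintf("  %-9s %s\n", s, format_percent(x$eff_by_strategy[[s]])))
  }
  if (!is.null(x$incremental)) {
    cat(sprintf("  %-9s %s\n", "IE", format_percent(x$incremental)))
  }
  if (x$theoretical) cat("  (theoretical: value(s) outside [0, 1])\n")
  invisible(x)
}

# Display rounding matches the source tables: percentages to whole numbers.
format_percent <- function(x) sprintf("%.0f%%", round(100 * x))
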