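# Euro amounts are carried as integer cents wherever fee items are summed,
# so that itemized totals are exact; division (scan factor, ratios) happens
# in double precision and is rounded to cents only for display.

as_cents <- function(eur) {
  cents <- round(eur * 100)
  if (any(abs(eur * 100 - cents) > 1e-6)) {
    stop("amounts must have at most cent precision", call. = FALSE)
  }
  as.integer(cents)
}

#' Itemized fee schedule for one modality
#'
#' A set of fee-schedule entries (procedure code, label, euro amount) whose
#' sum is the per-scan cost of a modality. Amounts are validated to cent
#' precision and must be non-negative.
#'
#' @param code Character vector of fee-schedule index numbers (the tracer
#'   production entry, which has no index number, uses a sentinel code).
#' @param label Character vector of item descriptions.
#' @param amount_eur Numeric vector of euro amounts, cent precision.
#' @return A data frame of class `"fee_schedule"` with columns `code`,
#'   `label`, `amount_eur`.
#' @export
fee_schedule <- function(code, label, amount_eur) {
  if (length(code) != length(label) || length(code) != length(amount_eur)) {
    stop("code, label and amount_eur must have equal length", call. = FALSE)
  }
  if (any(!nzchar(code))) stop("fee-schedule codes must be non-empty", call. = FALSE)
  if (any(amount_eur < 0)) stop("fee amounts must be non-negative", call. = FALSE)
  as_cents(amount_eur)  # validates cent precision
  structure(
    data.frame(code = as.character(code), label = as.character(label),
               amount_eur = amount_eur, stringsAsFactors = FALSE),
    class = c("fee_schedule", "data.frame")
  )
}

#' Default German fee-schedule items for FET PET and MRI
#'
#' The bundled per-scan cost items from the German "Medical Fee Schedule for
#' Care Outside the Statutory Health Insurance Scheme" (GOÄ) as applied to
#' pediatric CNS tumor follow-up imaging: they sum to EUR 1566.33 per FET PET
#' scan and EUR 987.80 per MRI scan. Users may override any item via the
#' model configuration file.
#'
#' @param modality `"pet"` or `"mri"`.
#' @return A [fee_schedule] data frame.
#' @export
default_fee_schedule <- function(modality = c("pet", "mri")) {
  modality <- match.arg(modality)
  if (modality == "pet") {
    fee_schedule(
      code = c("1", "75", "253", "5430", "5489", "tracer"),
      label = c(
        "Patient consultation",
        "Report on diagnostic findings",
        "Intravenous injection",
        "Scintigraphy of the brain",
        "FET PET with quantitative analysis",
        "Tracer production"
      ),
      amount_eur = c(10.72, 17.43, 9.38, 125.91, 786.89, 616.00)
    )
  } else {
    fee_schedule(
      code = c("1", "5", "75", "346", "3051", "5700", "5731", "5733"),
      label = c(
        "Patient consultation",
        "Physical examination",
        "Report on diagnostic findings",
        "High-pressure intravenous injection",
        "Surcharge for perfusion imaging",
        "MRI with 3D and ADC reconstruction",
        "Additional MRI series with 3D and ADC reconstruction",
        "Surcharge for computer analysis"
      ),
      amount_eur = c(10.72, 10.72, 17.43, 40.23, 75.19, 641.16, 145.72, 46.63)
    )
  }
}

#' Per-scan cost of a modality
#'
#' Exact sum of the fee-schedule amounts, computed in integer cents.
#'
#' @param items A [fee_schedule] data frame (or any data frame with an
#'   `amount_eur` column).
#' @return Per-scan cost in euros, exact to the cent. An empty item list
#'   costs 0.
#' @examples
#' scan_cost(default_fee_schedule("pet")) # 1566.33
#' @export
scan_cost <- function(items) {
  amounts <- if (is.data.frame(items)) items$amount_eur else items
  if (length(amounts) == 0L) return(0)
  if (any(amounts < 0)) stop("fee amounts must be non-negative", call. = FALSE)
  sum(as_cents(amounts)) / 100
}

#' Per-lesion cost from per-scan cost and the scan factor
#'
#' Lesions can be scanned more than once during follow-up; per-lesion imaging
#' cost is the per-scan cost times the scans-per-lesion factor
#' `n_scans / n_lesions` (92/83 in the combined-imaging cohort).
#'
#' @param total_scan_cost Per-scan cost in euros (all modalities of the
#'   strategy summed).
#' @param n_scans Total number of scans performed.
#' @param n_lesions Number of lesions (>= 1).
#' @return Per-lesion cost in euros, full precision (round with
#'   [format_eur()] for display).
#' @examples
#' per_lesion_cost(1566.33 + 987.80, 92, 83) # 2831.08 per lesion
#' @export
per_lesion_cost <- function(total_scan_cost, n_scans, n_lesions) {
  if (n_lesions < 1) stop("n_lesions must be at least 1", call. = FALSE)
  if (n_scans < n_lesions) {
    stop("n_scans must be at least n_lesions (every lesion is scanned)",
         call. = FALSE)
  }
  total_scan_cost * n_scans / n_lesions
}

# Tolerance for an incremental effectiveness treated as zero.
.ratio_tol <- 1e-9

#' Incremental cost-effectiveness ratio
#'
#' Additional cost per additional correctly identified treatment-related
#' change lesion: the per-lesion cost difference between two strategies
#' divided by their incremental effectiveness.
#'
#' @param cost_combined,cost_reference Per-lesion costs (euros) of the
#'   combined and reference strategies.
#' @param incremental_effectiveness Effectiveness difference
#'   (combined minus reference); must not be within tolerance of zero.
#' @return ICER in euros per additional correct identification. Negative
#'   incremental effectiveness is allowed (the combined strategy is then
#'   dominated) and produces a negative ratio; it is the caller's job to
#'   flag it.
#' @export
icer <- function(cost_combined, cost_reference, incremental_effectiveness) {
  if (any(abs(incremental_effectiveness) < .ratio_tol)) {
    stop("undefined ICER: incremental effectiveness is zero", call. = FALSE)
  }
  (cost_combined - cost_reference) / incremental_effectiveness
}

#' Cost-effectiveness ratio of a single strategy
#'
#' @param cost Per-lesion cost in euros.
#' @param effectiveness Effectiveness fraction; must exceed tolerance.
#' @return CER in euros per correctly identified treatment-related-change
#'   lesion.
#' @examples
#' cer(1566.33, 0.90) # 1740.37 per correct identification
#' @export
cer <- function(cost, effectiveness) {
  if (any(effectiveness < .ratio_tol)) {
    stop("undefined CER: effectiveness must be positive", call. = FALSE)
  }
  cost / effectiveness
}

#' Cost profile of a decision-tree model
#'
#' Bundles the itemized per-modality fee schedules with the cohort's scan
#' factor. For model 1 each identification uses one PET and one MRI scan
#' (combined strategy) or one MRI scan (reference strategy); for model 2 one
#' PET scan.
#'
#' @param items_by_modality Named list of [fee_schedule] data frames,
#'   e.g. `list(pet = ..., mri = ...)`.
#' @param n_scans,n_lesions Cohort totals defining the scans-per-lesion
#'   factor (`n_scans >= n_lesions >= 1`).
#' @return An object of class `"cost_profile"`.
#' @export
cost_profile <- function(items_by_modality, n_scans, n_lesions) {
  if (is.null(names(items_by_modality)) || any(!nzchar(names(items_by_modality)))) {
    stop("items_by_modality must be a named list of fee schedules", call. = FALSE)
  }
  if (n_lesions < 1 || n_scans < n_lesions) {
    stop("need n_scans >= n_lesions >= 1", call. = FALSE)
  }
  structure(
    list(items_by_modality = items_by_modality,
         n_scans = as.integer(n_scans), n_lesions = as.integer(n_lesions)),
    class = "cost_profile"
  )
}

#' @export
print.cost_profile <- function(x, ...) {
  cat("Imaging cost profile (scan factor ", x$n_scans, "/", x$n_lesions, ")\n",
      sep = "")
  for (m in names(x$items_by_modality)) {
    cat(sprintf("  %-4s per scan %s, per lesion %s\n", m,
                format_eur(scan_cost(x$items_by_modality[[m]])),
                format_eur(per_lesion_cost(scan_cost(x$items_by_modality[[m]]),
                                           x$n_scans, x$n_lesions))))
  }
  invisible(x)
}

#' Format euros for display
#'
#' Comma thousands separator, two decimals — the display convention used in
#' all reports. Machine outputs stay unformatted; rounding to cents happens
#' exactly once, here.
#'
#' @param x Euro amount(s).
#' @return Character vector like `"3,314.51"`.
#' @export
format_eur <- function(x) {
  formatC(round(x, 2), format = "f", digits = 2, big.mark = ",")
}
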