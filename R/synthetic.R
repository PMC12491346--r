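#' Exact lesion-level study fixtures
#'
#' Reconstructs, as per-lesion records, the two cohorts underlying the
#' decision trees. The integer counts are not published as a table; they are
#' the unique small-integer contingency tables consistent with the rounded
#' chance-node percentages, the headline effectiveness values and the
#' cent-level cost-effectiveness ratios (the reconstruction is re-verified by
#' brute-force search in the test suite). These fixture datasets are
#' synthetic in the sense that per-lesion identities and the cross-tabulation
#' of the two strategies' ratings within a confirmed class are arbitrary;
#' every marginal count the analysis uses is exact.
#'
#' Model 1 (83 lesions, 92 scans, combined PET+MRI vs MRI alone): the
#' combined reading rates 54 lesions relapse (all confirmed relapse) and 29
#' TRC (21 confirmed TRC, 8 relapse); the MRI-alone reading rates 68 relapse
#' (57 confirmed relapse, 11 TRC) and 15 TRC (10 TRC, 5 relapse). Both
#' readings share one confirmed label per lesion (62 relapse, 21 TRC). Nine
#' lesions carry 2 scans and 74 carry 1 (92 total); which lesions are
#' double-scanned is arbitrary — costs depend only on the totals.
#'
#' Model 2 (22 lesions, 1 scan each, PET in MRI-suspicious lesions): 10 rated
#' relapse (9 confirmed relapse, 1 TRC) and 12 rated TRC (9 TRC, 3 relapse).
#'
#' @param model_id `"model1"` or `"model2"`.
#' @return A lesion dataset: data frame with columns `lesion_id`,
#'   `rating_combined` (model 2: the PET rating), `rating_reference`
#'   (model 1 only, else `NA`), `confirmed`, `n_scans`.
#' @examples
#' estimate_nodes(study_fixture("model2"), "model2")
#' @export
study_fixture <- function(model_id) {
  model_id <- match.arg(model_id, c("model1", "model2"))
  if (model_id == "model1") {
    # blocks: (combined rating, MRI rating, confirmed) with counts chosen so
    # every strategy-by-confirmed margin matches the reconstruction
    blocks <- data.frame(
      rating_combined  = c("relapse", "trc",     "trc",     "trc",     "trc"),
      rating_reference = c("relapse", "relapse", "trc",     "relapse", "trc"),
      confirmed        = c("relapse", "relapse", "relapse", "trc",     "trc"),
      n                = c(54L,        3L,        5L,        11L,       10L),
      stringsAsFactors = FALSE
    )
    d <- blocks[rep(seq_len(nrow(blocks)), blocks$n),
                c("rating_combined", "rating_reference", "confirmed")]
    d$n_scans <- rep(1L, nrow(d))
    d$n_scans[seq_len(9L)] <- 2L  # 92 scans over 83 lesions
  } else {
    blocks <- data.frame(
      rating_combined = c("relapse", "relapse", "trc", "trc"),
      confirmed       = c("relapse", "trc",     "trc", "relapse"),
      n               = c(9L,         1L,        9L,    3L),
      stringsAsFactors = FALSE
    )
    d <- blocks[rep(seq_len(nrow(blocks)), blocks$n),
                c("rating_combined", "confirmed")]
    d$rating_reference <- NA_character_
    d$n_scans <- 1L
  }
  d <- d[, c("rating_combined", "rating_reference", "confirmed", "n_scans")]
  rownames(d) <- NULL
  cbind(lesion_id = sprintf("L%03d", seq_len(nrow(d))), d,
        stringsAsFactors = FALSE)
}

#' Specification of a synthetic lesion cohort
#'
#' @param n_lesions Number of lesions to generate (>= 1).
#' @param nodes Generating chance-node probabilities, a [node_probs] object
#'   with all values in \[0, 1\].
#' @param scans_per_lesion Either a single positive integer (every lesion
#'   gets that many scans) or a list `list(values =, prob =)` giving an
#'   integer distribution sampled per lesion.
#' @param seed Integer seed for reproducible generation.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_lesions, nodes, scans_per_lesion = 1L, seed = 1L) {
  if (!inherits(nodes, "node_probs")) {
    stop("'nodes' must be a node_probs object", call. = FALSE)
  }
  if (any(nodes$values > 1)) {
    stop("generating probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_lesions < 1) stop("n_lesions must be at least 1", call. = FALSE)
  if (is.list(scans_per_lesion)) {
    if (!all(c("values", "prob") %in% names(scans_per_lesion)) ||
        any(scans_per_lesion$values < 1)) {
      stop("scans_per_lesion distribution needs positive integer 'values' and 'prob'",
           call. = FALSE)
    }
  } else if (length(scans_per_lesion) != 1L || scans_per_lesion < 1) {
    stop("scans_per_lesion must be a positive integer or a distribution list",
         call. = FALSE)
  }
  structure(
    list(n_lesions = as.integer(n_lesions), nodes = nodes,
         scans_per_lesion = scans_per_lesion, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic lesion cohort
#'
#' Simulates per-lesion records with the statistical structure the decision
#' trees assume, so that [estimate_nodes()] recovers the generating
#' probabilities up to binomial sampling error.
#'
#' For model 2 each lesion's PET rating is Bernoulli in the rated-relapse
#' probability and the confirmed diagnosis is drawn conditionally on the
#' rating from the two confirmation nodes. For model 1 the two strategies
#' rate the *same* lesion, so a shared latent truth is drawn first: the
#' confirmed-TRC prevalence implied by each strategy's nodes must agree (else
#' the joint specification is inconsistent and an error with both implied
#' prevalences is raised), each strategy's rating is then drawn conditionally
#' on truth with sensitivity/specificity back-solved via Bayes' rule, and
#' ratings are conditionally independent given truth. Back-solved
#' conditionals outside \[0, 1\] also raise the inconsistency error.
#'
#' @param spec A [cohort_spec].
#' @return A lesion dataset (same columns as [study_fixture()]).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    stop("'spec' must be a cohort_spec object", call. = FALSE)
  }
  set.seed(spec$seed)
  n <- spec$n_lesions
  v <- spec$nodes$values
  lv <- diagnosis_levels()
  draw <- function(p_relapse) ifelse(stats::runif(n) < p_relapse, lv[1], lv[2])

  if (spec$nodes$model_id == "model2") {
    rating <- draw(v[["N1"]])
    p_conf_rel <- ifelse(rating == "relapse", v[["N2"]], 1 - v[["N3"]])
    confirmed <- draw_given(p_conf_rel)
    d <- data.frame(rating_combined = rating,
                    rating_reference = NA_character_,
                    confirmed = confirmed, stringsAsFactors = FALSE)
  } else {
    prev_comb <- v[["N1"]] * (1 - v[["N3"]]) + (1 - v[["N1"]]) * v[["N4"]]
    prev_ref  <- v[["N2"]] * (1 - v[["N5"]]) + (1 - v[["N2"]]) * v[["N6"]]
    if (abs(prev_comb - prev_ref) > 1e-9) {
      stop(sprintf(paste0(
        "inconsistent joint specification: the confirmed-TRC prevalence ",
        "implied by the combined nodes (%.6f) and the reference nodes (%.6f) ",
        "differ; the two strategies rate the same lesions and must share ",
        "one truth"), prev_comb, prev_ref), call. = FALSE)
    }
    prev_trc <- prev_comb
    # P(rated relapse | truth) per strategy, via Bayes
    rate_given_truth <- function(p_rated, p_conf_rel, p_conf_trc) {
      p_rel_truth <- 1 - prev_trc
      sens <- if (p_rel_truth > 0) p_rated * p_conf_rel / p_rel_truth else 0
      fpr  <- if (prev_trc > 0) p_rated * (1 - p_conf_rel) / prev_trc else 0
      c(sens = sens, fpr = fpr)
    }
    cc <- rate_given_truth(v[["N1"]], v[["N3"]], v[["N4"]])
    cr <- rate_given_truth(v[["N2"]], v[["N5"]], v[["N6"]])
    if (any(c(cc, cr) < -1e-12) || any(c(cc, cr) > 1 + 1e-12)) {
      stop("inconsistent joint specification: back-solved rating ",
           "probabilities given truth fall outside [0, 1]", call. = FALSE)
    }
    cc <- pmin(pmax(cc, 0), 1); cr <- pmin(pmax(cr, 0), 1)
    confirmed <- ifelse(stats::runif(n) < prev_trc, lv[2], lv[1])
    p_rate_comb <- ifelse(confirmed == "relapse", cc[["sens"]], cc[["fpr"]])
    p_rate_ref  <- ifelse(confirmed == "relapse", cr[["sens"]], cr[["fpr"]])
    d <- data.frame(rating_combined = draw_given(p_rate_comb, lv),
                    rating_reference = draw_given(p_rate_ref, lv),
                    confirmed = confirmed, stringsAsFactors = FALSE)
  }
  d$n_scans <- if (is.list(spec$scans_per_lesion)) {
    as.integer(sample(spec$scans_per_lesion$values, n, replace = TRUE,
                      prob = spec$scans_per_lesion$prob))
  } else {
    rep(as.integer(spec$scans_per_lesion), n)
  }
  cbind(lesion_id = sprintf("L%06d", seq_len(n)), d, stringsAsFactors = FALSE)
}

# vectorized Bernoulli draw of a diagnosis label with per-element P(relapse)
draw_given <- function(p_relapse, lv = diagnosis_levels()) {
  ifelse(stats::runif(length(p_relapse)) < p_relapse, lv[1], lv[2])
}

#' Write / read lesion datasets as CSV
#'
#' Plain CSV with columns `lesion_id`, `rating_combined`, `rating_reference`,
#' `confirmed`, `n_scans`; absent ratings are empty fields.
#'
#' @param data A lesion dataset.
#' @param path File path.
#' @return `read_lesion_csv` returns the lesion dataset;
#'   `write_lesion_csv` returns `path` invisibly.
#' @export
write_lesion_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_lesion_csv
#' @export
read_lesion_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(lesion_id = "character"))
  for (col in c("rating_combined", "rating_reference", "confirmed")) {
    if (col %in% names(d)) d[[col]][!nzchar(trimws(as.character(d[[col]])))] <- NA
  }
  if (any(d$n_scans < 1)) stop("n_scans must be >= 1", call. = FALSE)
  d
}
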