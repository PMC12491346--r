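#' One-way deterministic sensitivity analysis of a chance node
#'
#' Re-evaluates the decision tree with one chance node set to the lower and
#' upper end of its interval, all other nodes held at their base values, and
#' recomputes effectiveness and the (incremental) cost-effectiveness ratio at
#' both ends. Endpoints may exceed 1 ("theoretical" values, e.g. varying a
#' relapse-confirmation probability whose base value is already 100%); such
#' rows are computed and flagged, never clamped.
#'
#' For model 1 the reported effectiveness is the incremental effectiveness
#' and the ratio is the ICER; for model 2 the strategy effectiveness and the
#' CER. An endpoint at which effectiveness is undefined (zero confirmed-TRC
#' mass) yields `NA` entries and `undefined = TRUE` rather than an error.
#'
#' @param fit A [cea_model] (the base case).
#' @param node_id Chance node to vary, e.g. `"N3"`.
#' @param low,high Interval endpoints (probabilities; `0 < low <= high`,
#'   values above 1 allowed).
#' @return A one-row data frame of class `"dsa_row"`: `node_id`, `low`,
#'   `high`, `eff_low`, `eff_high`, `ratio_low`, `ratio_high`, `width`
#'   (absolute ratio range), `theoretical`, `undefined`.
#' @export
one_way <- function(fit, node_id, low, high) {
  if (!inherits(fit, "cea_model")) stop("'fit' must be a cea_model", call. = FALSE)
  ids <- model_node_ids(fit$model_id)
  if (!node_id %in% ids) {
    stop("node ", node_id, " does not exist in ", fit$model_id, call. = FALSE)
  }
  if (!(low > 0)) stop("interval lower end must be positive", call. = FALSE)
  if (low > high) stop("interval must satisfy low <= high", call. = FALSE)

  at <- function(value) {
    v <- fit$nodes$values
    v[[node_id]] <- value
    nodes <- node_probs(fit$model_id, v, allow_theoretical = TRUE)
    out <- tryCatch(
      cea_model(nodes, costs = fit$costs),
      error = function(e) NULL
    )
    if (is.null(out)) {
      return(list(eff = NA_real_, ratio = NA_real_, undefined = TRUE,
                  theoretical = any(v > 1)))
    }
    eff <- if (fit$model_id == "model1") out$effectiveness$incremental
           else out$effectiveness$eff_by_strategy[[1]]
    list(eff = eff, ratio = out$ratio, undefined = FALSE,
         theoretical = out$theoretical)
  }
  lo <- at(low); hi <- at(high)
  structure(
    data.frame(
      node_id = node_id, low = low, high = high,
      eff_low = lo$eff, eff_high = hi$eff,
      ratio_low = lo$ratio, ratio_high = hi$ratio,
      width = abs(hi$ratio - lo$ratio),
      theoretical = lo$theoretical || hi$theoretical,
      undefined = lo$undefined || hi$undefined,
      stringsAsFactors = FALSE
    ),
    class = c("dsa_row", "data.frame")
  )
}

#' Tornado table over a set of chance-node intervals
#'
#' Runs [one_way()] for each interval and orders rows by descending ratio
#' range (the bar length of a tornado diagram), ties broken by node id.
#'
#' @param fit A [cea_model].
#' @param intervals Data frame with columns `node_id`, `low`, `high`
#'   (one row per node; duplicates are an error), e.g. the `dsa` element of
#'   [read_model_config()].
#' @return A data frame of class `"dsa_table"` (one [one_way()] row per
#'   interval, tornado-ordered) with the base-case ratio attached as
#'   attribute `base_ratio` and base effectiveness as `base_eff`.
#' @export
tornado_table <- function(fit, intervals) {
  if (!inherits(fit, "cea_model")) stop("'fit' must be a cea_model", call. = FALSE)
  intervals <- as.data.frame(intervals)
  need <- c("node_id", "low", "high")
  if (!all(need %in% names(intervals))) {
    stop("intervals need columns node_id, low, high", call. = FALSE)
  }
  if (anyDuplicated(intervals$node_id)) {
    stop("duplicate node_id in intervals: ",
         paste(unique(intervals$node_id[duplicated(intervals$node_id)]),
               collapse = ", "), call. = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(intervals)), function(i) {
    one_way(fit, intervals$node_id[i], intervals$low[i], intervals$high[i])
  }))
  ord <- order(-rows$width, rows$node_id)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  base_eff <- if (fit$model_id == "model1") fit$effectiveness$incremental
              else fit$effectiveness$eff_by_strategy[[1]]
  structure(rows, class = c("dsa_table", "data.frame"),
            base_ratio = fit$ratio, base_eff = base_eff,
            ratio_type = fit$ratio_type, model_id = fit$model_id)
}

#' Tornado diagram
#'
#' Horizontal bars spanning each node's (incremental) cost-effectiveness
#' ratio range, widest at the top, with a vertical line at the base-case
#' ratio.
#'
#' @param x A `dsa_table` from [tornado_table()].
#' @param y Unused.
#' @param ... Passed to [graphics::plot.default()] (e.g. `main`).
#' @return `x`, invisibly.
#' @export
plot.dsa_table <- function(x, y, ...) {
  base <- attr(x, "base_ratio")
  n <- nrow(x)
  xlim <- range(c(x$ratio_low, x$ratio_high, base), na.rm = TRUE)
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = paste0(attr(x, "ratio_type"), " (EUR)"), ylab = "", ...)
  ypos <- rev(seq_len(n))  # widest bar on top
  graphics::rect(pmin(x$ratio_low, x$ratio_high), ypos - 0.35,
                 pmax(x$ratio_low, x$ratio_high), ypos + 0.35,
                 col = ifelse(x$theoretical, "grey85", "steelblue"),
                 border = "grey30")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = ypos, labels = x$node_id, las = 1)
  invisible(x)
}
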