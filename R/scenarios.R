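#' Standard scenario set for single-species detection comparisons
#'
#' Enumerates the method-by-assumption combinations usually compared for
#' single-species survey planning: metabarcoding at its baseline costs; qPCR
#' under three assay assumptions (`A = 0` validated, `A = 8` published but
#' unvalidated, `A = 85` developed from scratch); and seining at full cost,
#' with environmental costs removed (`E = 0`), and with permitting and
#' environmental costs removed (`P = 0, E = 0`).
#'
#' @return A list of scenario entries; each entry is a list with `method`
#'   (detection-estimate label), `cost` (cost-parameter column name),
#'   `scenario` (label), and `overrides`.
#' @export
default_scenario_set <- function() {
  list(
    list(method = "metabarcode", cost = "goby_metabarcode",
         scenario = "baseline", overrides = list()),
    list(method = "qPCR", cost = "qPCR",
         scenario = "assay_validated", overrides = list(A = 0)),
    list(method = "qPCR", cost = "qPCR",
         scenario = "assay_published", overrides = list(A = 8)),
    list(method = "qPCR", cost = "qPCR",
         scenario = "assay_developed", overrides = list(A = 85)),
    list(method = "seine", cost = "goby_seine",
         scenario = "baseline", overrides = list()),
    list(method = "seine", cost = "goby_seine",
         scenario = "no_environment", overrides = list(E = 0)),
    list(method = "seine", cost = "goby_seine",
         scenario = "no_permit_no_environment",
         overrides = list(P = 0, E = 0))
  )
}

#' Detection-versus-cost curve tables
#'
#' For every scenario entry, location count, and site count, pairs the
#' cumulative detection probability `d = 1 - (1 - gamma)^(n k)` (with its
#' confidence limits, transformed monotonically from the limits on gamma)
#' with the survey cost at that effort. Cost is reported per location (fixed
#' share plus variable cost) and as total program hours across the `L`
#' locations. These tables sit behind the standard three-panel comparison
#' (detection vs effort, cost vs effort, detection vs cost).
#'
#' @param params named list of [cost_params()] (default: the packaged
#'   per-method table).
#' @param estimates a `detection_estimates` data frame with one row per
#'   method named in the scenario set (default: [rare_case_estimates()]).
#' @param scenarios scenario entries as produced by
#'   [default_scenario_set()].
#' @param L location counts to evaluate (fixed costs are shared across
#'   locations).
#' @param k site counts per location.
#' @param n samples per site (detection comparisons conventionally fix
#'   `n = 1` and vary sites, which yield more than replicate samples).
#' @return Data frame of class `curve_points` with columns `method`,
#'   `scenario`, `L`, `k`, `n`, `effort`, `cost_hours_per_location`,
#'   `cost_hours_total`, `response`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' cur <- detection_cost_curves(L = 1, k = 1:10)
#' subset(cur, method == "metabarcode" & k == 5)
detection_cost_curves <- function(params = default_cost_params(),
                                  estimates = rare_case_estimates(),
                                  scenarios = default_scenario_set(),
                                  L = 1, k = 1:25, n = 1) {
  rows <- list()
  for (entry in scenarios) {
    if (!entry$cost %in% names(params)) {
      stop("no cost parameters for method '", entry$cost, "'", call. = FALSE)
    }
    est <- estimates[estimates$method == entry$method, , drop = FALSE]
    if (nrow(est) != 1L) {
      stop("need exactly one detection estimate for method '", entry$method,
           "'", call. = FALSE)
    }
    sc <- cost_scenario(entry$scenario, entry$overrides)
    for (Li in L) {
      for (ki in k) {
        mod <- apply_scenario(params[[entry$cost]],
                              effort_design(L = Li, k = ki, n = n), sc)
        cost_loc <- total_cost(mod$params, mod$design)
        d <- cumulative_detection(est, n = mod$design$n, k = mod$design$k)
        rows[[length(rows) + 1L]] <- data.frame(
          method = entry$method, scenario = entry$scenario,
          L = Li, k = mod$design$k, n = mod$design$n, effort = d$effort,
          cost_hours_per_location = cost_loc,
          cost_hours_total = cost_loc * Li,
          response = d$d, ci_low = d$ci_low, ci_high = d$ci_high
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("curve_points", "data.frame")
  out
}

#' Standard strategies for community richness comparisons
#'
#' Builds the strategy entries compared for community assessment:
#' metabarcoding with one sample per site (`single_barcode`), metabarcoding
#' with two samples per site (`double_barcode`), and seining, each paired
#' with a fitted accumulation model. Seine cost variants (no environmental
#' cost; no permitting or environmental cost) are included when
#' `seine_variants = TRUE`.
#'
#' @param metabarcode_fit,seine_fit [fit_polce_kunin()] results for the two
#'   methods.
#' @param seine_variants include the relaxed seine cost assumptions.
#' @return A list of strategy entries for [richness_cost_curves()].
#' @export
default_richness_strategies <- function(metabarcode_fit, seine_fit,
                                        seine_variants = TRUE) {
  out <- list(
    list(strategy = "single_barcode", method = "metabarcode",
         cost = "fish_metabarcode", fit = metabarcode_fit, n = 1,
         scenario = "baseline", overrides = list()),
    list(strategy = "double_barcode", method = "metabarcode",
         cost = "fish_metabarcode", fit = metabarcode_fit, n = 2,
         scenario = "baseline", overrides = list()),
    list(strategy = "seine", method = "seine", cost = "fish_seine",
         fit = seine_fit, n = 1, scenario = "baseline", overrides = list())
  )
  if (seine_variants) {
    out <- c(out, list(
      list(strategy = "seine", method = "seine", cost = "fish_seine",
           fit = seine_fit, n = 1, scenario = "no_environment",
           overrides = list(E = 0)),
      list(strategy = "seine", method = "seine", cost = "fish_seine",
           fit = seine_fit, n = 1, scenario = "no_permit_no_environment",
           overrides = list(P = 0, E = 0))
    ))
  }
  out
}

#' Richness-versus-cost curve tables
#'
#' Pairs expected species richness from a fitted accumulation model with
#' survey cost at each effort level. Each strategy entry supplies its own
#' fitted model, samples-per-site `n`, cost column, and cost-scenario
#' overrides (see [default_richness_strategies()]). An unconverged or
#' unidentifiable fit is refused with its diagnostics: scenario tables must
#' never be built on silent garbage.
#'
#' @param strategies list of strategy entries.
#' @param params named list of [cost_params()].
#' @param L location counts.
#' @param k site counts per location.
#' @param level confidence level for the delta-method richness band.
#' @return Data frame of class `curve_points` (columns as in
#'   [detection_cost_curves()], plus `strategy`; `response` is expected
#'   species richness).
#' @export
richness_cost_curves <- function(strategies, params = default_cost_params(),
                                 L = 1, k = 1:25, level = 0.95) {
  rows <- list()
  for (entry in strategies) {
    fit <- entry$fit
    if (!inherits(fit, "polce_kunin_fit")) {
      stop("strategy '", entry$strategy, "' has no accumulation fit",
           call. = FALSE)
    }
    if (!isTRUE(fit$converged) || !isTRUE(fit$identifiable)) {
      stop("refusing strategy '", entry$strategy,
           "': accumulation fit did not converge cleanly (converged = ",
           fit$converged, ", identifiable = ", fit$identifiable,
           if (nzchar(fit$message)) paste0("; ", fit$message) else "",
           ")", call. = FALSE)
    }
    if (!entry$cost %in% names(params)) {
      stop("no cost parameters for '", entry$cost, "'", call. = FALSE)
    }
    sc <- cost_scenario(entry$scenario, entry$overrides)
    pred <- predict_richness(fit, n = entry$n, k = k, interval = TRUE,
                             level = level)
    for (Li in L) {
      costs <- vapply(k, function(ki) {
        mod <- apply_scenario(params[[entry$cost]],
                              effort_design(L = Li, k = ki, n = entry$n), sc)
        total_cost(mod$params, mod$design)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = entry$strategy, method = entry$method,
        scenario = entry$scenario, L = Li, k = k, n = entry$n,
        effort = entry$n * k,
        cost_hours_per_location = costs, cost_hours_total = costs * Li,
        response = pred$fit, ci_low = pred$ci_low, ci_high = pred$ci_high
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("curve_points", "data.frame")
  out
}

#' Rank methods by cost at detection thresholds
#'
#' For each location count and detection threshold, finds — per method and
#' scenario — the smallest site count whose cumulative detection reaches the
#' threshold, reports the per-location cost at that effort, and ranks the
#' method/scenario combinations by that cost (rank 1 = cheapest; the
#' `cheapest` flag marks it). Combinations that never reach a threshold get
#' an `NA` cost and no rank.
#'
#' @param curves a `curve_points` table from [detection_cost_curves()].
#' @param thresholds detection probabilities to evaluate; the conventional
#'   "confident detection" threshold 0.99 should always be included.
#' @return Data frame with columns `L`, `threshold`, `method`, `scenario`,
#'   `k_at_threshold`, `cost_at_threshold`, `rank`, `cheapest`.
#' @export
#' @examples
#' cross <- summarize_crossovers(detection_cost_curves(L = c(1, 10)))
#' subset(cross, threshold == 0.99 & cheapest)
summarize_crossovers <- function(curves,
                                 thresholds = c(0.5, 0.9, 0.95, 0.99)) {
  combos <- unique(curves[c("method", "scenario", "L")])
  rows <- list()
  for (Li in unique(combos$L)) {
    for (th in thresholds) {
      part <- list()
      for (i in which(combos$L == Li)) {
        cm <- combos[i, ]
        sub <- curves[curves$method == cm$method &
                        curves$scenario == cm$scenario &
                        curves$L == Li, , drop = FALSE]
        sub <- sub[order(sub$k), , drop = FALSE]
        hit <- which(sub$response >= th)
        part[[length(part) + 1L]] <- data.frame(
          L = Li, threshold = th, method = cm$method, scenario = cm$scenario,
          k_at_threshold = if (length(hit)) sub$k[hit[1]] else NA_integer_,
          cost_at_threshold = if (length(hit))
            sub$cost_hours_per_location[hit[1]] else NA_real_
        )
      }
      part <- do.call(rbind, part)
      part$rank <- rank(part$cost_at_threshold, na.last = "keep",
                        ties.method = "min")
      part$cheapest <- !is.na(part$rank) & part$rank == 1L
      rows[[length(rows) + 1L]] <- part
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
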