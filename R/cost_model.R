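#' Cost-model parameters for one survey method
#'
#' Bundles the per-method investment parameters of the survey cost model. All
#' costs are expressed in technician-hours (monetary costs converted at a
#' stated hourly rate, see [hours_to_dollars()]); `W` is a dimensionless crew
#' multiplier. The total investment per location is
#' \deqn{H = \frac{P+G+A}{L} + B + WV + R \;+\; k\,(v + n\,(tW + E + D + q))}
#' where the first four terms are the fixed cost and the last term the
#' variable cost of visiting `k` sites and taking `n` samples per site.
#'
#' @param P permit acquisition and management, hours.
#' @param B background knowledge (e.g., compiling a plausible species list),
#'   hours.
#' @param G field gear, hours.
#' @param A assay development or validation, hours (0 if the sequencer holds a
#'   validated assay; moderate if published but unvalidated; large if developed
#'   from scratch).
#' @param W number of field workers (crew multiplier, >= 1); crew seniority is
#'   folded in by the caller (e.g., a trained biologist counted as three
#'   technicians).
#' @param V preparation plus travel per location visit, hours.
#' @param v time to reach and set up each new site within a location, hours.
#' @param t field time per sample (seine haul, or water collection plus
#'   filtering), hours.
#' @param E external (environmental-impact) cost per sample, hours-equivalent.
#' @param q sequencing / laboratory analysis per sample, hours-equivalent.
#' @param D data entry and QC per sample, hours.
#' @param R report writing per location, hours.
#' @param r per-technical-replicate cost (qPCR), hours-equivalent. Small
#'   enough to be ignorable in practice; carried for completeness, default 0.
#' @param method_label label for the method this column describes.
#'
#' @return An object of class `cost_params`.
#' @seealso [default_cost_params()] for the packaged per-method defaults,
#'   [fixed_cost()], [variable_cost()], [total_cost()].
#' @export
#' @examples
#' seine <- default_cost_params("goby_seine")
#' total_cost(seine, effort_design(L = 1, k = 1, n = 1))
cost_params <- function(P = 0, B = 0, G = 0, A = 0, W = 1, V = 0, v = 0,
                        t = 0, E = 0, q = 0, D = 0, R = 0, r = 0,
                        method_label = "custom") {
  x <- structure(
    list(P = P, B = B, G = G, A = A, W = W, V = V, v = v, t = t,
         E = E, q = q, D = D, R = R, r = r,
         method_label = as.character(method_label)[1L]),
    class = "cost_params"
  )
  validate_cost_params(x)
  x
}

validate_cost_params <- function(x) {
  num <- setdiff(names(x), "method_label")
  for (f in num) {
    val <- x[[f]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val)) {
      stop("cost parameter '", f, "' must be a single finite number",
           call. = FALSE)
    }
  }
  neg <- num[vapply(num, function(f) x[[f]] < 0, logical(1))]
  if (length(neg)) {
    stop("cost parameters must be non-negative: ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  if (x$W < 1) stop("worker count W must be >= 1", call. = FALSE)
  invisible(x)
}

#' @export
print.cost_params <- function(x, ...) {
  cat("Survey cost parameters (", x$method_label, ")\n", sep = "")
  cat("  fixed components  : P=", x$P, " G=", x$G, " A=", x$A,
      " B=", x$B, " W=", x$W, " V=", x$V, " R=", x$R, "\n", sep = "")
  cat("  per-site / sample : v=", x$v, " t=", x$t, " E=", x$E,
      " D=", x$D, " q=", x$q, " r=", x$r, "\n", sep = "")
  invisible(x)
}

#' Sampling-effort design
#'
#' The effort allocation a survey program chooses: `L` locations per program,
#' `k` sites visited per location, and `n` samples taken per site. Fixed
#' program costs are shared across the `L` locations; variable costs scale
#' with `k` and `n`.
#'
#' @param L number of locations in the sampling program (>= 1).
#' @param k number of sites visited per location (>= 0).
#' @param n number of samples taken per site (>= 0).
#' @return An object of class `effort_design`.
#' @export
effort_design <- function(L = 1, k = 1, n = 1) {
  for (nm in c("L", "k", "n")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) ||
        abs(val - round(val)) > 1e-8) {
      stop("effort component '", nm, "' must be a single whole number",
           call. = FALSE)
    }
  }
  if (L < 1) stop("number of locations L must be >= 1", call. = FALSE)
  if (k < 0 || n < 0) stop("site and sample counts must be >= 0", call. = FALSE)
  structure(list(L = round(L), k = round(k), n = round(n)),
            class = "effort_design")
}

#' @export
print.effort_design <- function(x, ...) {
  cat("Effort design: L =", x$L, "locations, k =", x$k,
      "sites/location, n =", x$n, "samples/site\n")
  invisible(x)
}

#' Fixed, variable, and total survey cost
#'
#' `fixed_cost()` evaluates the per-location fixed investment
#' `(P + G + A)/L + B + W*V + R`: program-level costs (permits, gear, assay)
#' are shared across the `L` locations of the program, while background
#' knowledge, the crewed location visit, and reporting recur at every
#' location. `variable_cost()` evaluates `k * (v + n * (t*W + E + D + q))`,
#' the cost of visiting `k` sites and taking `n` samples at each.
#' `total_cost()` is their sum: the total investment `H` per location
#' sampled, in technician-hours.
#'
#' @param params a [cost_params()] object.
#' @param design an [effort_design()] object.
#' @return Cost in technician-hours (single numeric).
#' @export
#' @examples
#' p <- default_cost_params("goby_seine")
#' d <- effort_design(L = 1, k = 1, n = 1)
#' fixed_cost(p, d)     # 37.0
#' variable_cost(p, d)  # 4.9
#' total_cost(p, d)     # 41.9
fixed_cost <- function(params, design) {
  stopifnot(inherits(params, "cost_params"), inherits(design, "effort_design"))
  (params$P + params$G + params$A) / design$L +
    params$B + params$W * params$V + params$R
}

#' @rdname fixed_cost
#' @export
variable_cost <- function(params, design) {
  stopifnot(inherits(params, "cost_params"), inherits(design, "effort_design"))
  design$k * (params$v +
                design$n * (params$t * params$W + params$E +
                              params$D + params$q))
}

#' @rdname fixed_cost
#' @export
total_cost <- function(params, design) {
  fixed_cost(params, design) + variable_cost(params, design)
}

#' Convert technician-hours to dollars
#'
#' All model arithmetic runs in the common currency of technician-hours; this
#' helper converts for reporting, at a default 2023 technician rate of
#' $30 USD per hour.
#'
#' @param hours numeric vector of technician-hours.
#' @param rate dollars per technician-hour.
#' @return Dollar amounts.
#' @export
hours_to_dollars <- function(hours, rate = 30) hours * rate

#' Cost scenarios: named parameter substitutions
#'
#' A scenario is a labelled set of overrides applied to a [cost_params()]
#' and/or [effort_design()] pair — e.g., a validated assay (`A = 0`), seining
#' with no environmental cost (`E = 0`), or a 100-location program
#' (`L = 100`). `apply_scenario()` returns modified copies; the inputs are
#' never touched.
#'
#' @param label scenario label.
#' @param overrides named list; names must be [cost_params()] fields (other
#'   than `method_label`) or effort fields `L`, `k`, `n`.
#' @return `cost_scenario()`: an object of class `cost_scenario`.
#' @export
#' @examples
#' sc <- cost_scenario("no_environment", list(E = 0))
#' out <- apply_scenario(default_cost_params("goby_seine"),
#'                       effort_design(), sc)
#' out$params$E
cost_scenario <- function(label, overrides = list()) {
  if (length(overrides) && (is.null(names(overrides)) ||
                            any(!nzchar(names(overrides))))) {
    stop("scenario overrides must be a fully named list", call. = FALSE)
  }
  structure(list(label = as.character(label)[1L], overrides = overrides),
            class = "cost_scenario")
}

#' @rdname cost_scenario
#' @param params a [cost_params()] object.
#' @param design an [effort_design()] object.
#' @param scenario a `cost_scenario` object.
#' @return `apply_scenario()`: a list with modified `params` and `design`.
#' @export
apply_scenario <- function(params, design, scenario) {
  stopifnot(inherits(params, "cost_params"),
            inherits(design, "effort_design"),
            inherits(scenario, "cost_scenario"))
  param_fields <- setdiff(names(params), "method_label")
  design_fields <- names(design)
  p <- unclass(params)
  d <- unclass(design)
  for (nm in names(scenario$overrides)) {
    val <- scenario$overrides[[nm]]
    if (nm %in% param_fields) {
      p[[nm]] <- val
    } else if (nm %in% design_fields) {
      d[[nm]] <- val
    } else {
      stop("scenario '", scenario$label, "' overrides unknown field '", nm,
           "'", call. = FALSE)
    }
  }
  list(params = do.call(cost_params, p[c(param_fields, "method_label")]),
       design = do.call(effort_design, d))
}

#' Packaged default cost parameters
#'
#' Per-method cost parameters for a typical single-location estuary visit,
#' shipped with the package so analyses run with no external files. Five
#' method columns are provided: a single-species qPCR assay, single-species
#' and whole-community metabarcoding, and single-species and whole-community
#' seining. The qPCR column stores the published-but-unvalidated assay cost
#' (`A = 8`); scenario overrides set `A` to 0 (validated) or 85 (developed
#' from scratch).
#'
#' @param method one of `"qPCR"`, `"goby_metabarcode"`, `"fish_metabarcode"`,
#'   `"goby_seine"`, `"fish_seine"`, or `NULL` for all five.
#' @return A [cost_params()] object, or a named list of them if
#'   `method = NULL`.
#' @export
default_cost_params <- function(method = NULL) {
  path <- system.file("extdata", "cost_parameters.csv", package = "surveycost")
  read_cost_params(path, method = method)
}

#' Read cost parameters from CSV
#'
#' Expects one row per method with columns `method`, `P`, `B`, `G`, `A`, `W`,
#' `V`, `v`, `t`, `E`, `q`, `D`, `R` and optionally `r`.
#'
#' @param file path to a CSV parameter table.
#' @param method method label to extract, or `NULL` for all rows.
#' @return A [cost_params()] object or named list of them.
#' @export
read_cost_params <- function(file, method = NULL) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("method", "P", "B", "G", "A", "W", "V", "v", "t", "E", "q",
              "D", "R")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("cost parameter file is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"r" %in% names(tab)) tab$r <- 0
  build <- function(row) {
    cost_params(P = row$P, B = row$B, G = row$G, A = row$A, W = row$W,
                V = row$V, v = row$v, t = row$t, E = row$E, q = row$q,
                D = row$D, R = row$R, r = row$r, method_label = row$method)
  }
  if (!is.null(method)) {
    hit <- match(method, tab$method)
    if (is.na(hit)) {
      stop("method '", method, "' not found; available: ",
           paste(tab$method, collapse = ", "), call. = FALSE)
    }
    return(build(tab[hit, , drop = FALSE]))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) build(tab[i, , drop = FALSE]))
  names(out) <- tab$method
  out
}

#' Read a cost scenario from JSON
#'
#' Reads `{"label": ..., "overrides": {field: value}, "design": {L,k,n}}`;
#' the optional `design` block is merged into the overrides.
#'
#' @param file path to a JSON scenario file.
#' @return A [cost_scenario()] object.
#' @export
read_cost_scenario <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  overrides <- as.list(x$overrides %||% list())
  if (!is.null(x$design)) overrides <- c(overrides, as.list(x$design))
  cost_scenario(x$label %||% "scenario", overrides)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
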