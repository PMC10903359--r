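#' Resampled collector's curve over sites and samples
#'
#' Builds a species-accumulation (collector's) curve by repeatedly
#' re-ordering the sampling units at random: at each iteration, `n` samples
#' are drawn without replacement from every site, collapsed to a per-site
#' incidence, and the sites are accumulated in a random order. Cumulative
#' richness is recorded at every site count `k`, and summarised across
#' iterations by the median, mean, and resampling quantiles. The curve
#' starts at the average richness of a single unit and levels off at the
#' total cumulative richness of the matrix.
#'
#' @param x incidence data: a data frame with a `site_id` column plus one
#'   column per species (counts or 0/1; any positive value is a detection),
#'   or a numeric matrix with `site` supplied separately.
#' @param site site identifiers, one per row of `x`, when `x` is a matrix.
#' @param n_values samples-per-site values to evaluate. Defaults to
#'   `1:min(samples per site)` so every site can supply each requested `n`.
#' @param iterations number of random orderings (default 1000).
#' @param seed integer seed; with a fixed seed the curve is bit-reproducible.
#' @param one_per_site if `TRUE`, only `n = 1` is evaluated, with one sample
#'   drawn at random to represent each site at each iteration (the standard
#'   way to compare designs that took replicate samples per site).
#' @return A data frame of class `collector_curve` with columns `n`, `k`,
#'   `median_S`, `mean_S`, `q05`, `q95`; total species count and iteration
#'   count are attached as attributes.
#' @export
#' @examples
#' comm <- simulate_community(pool = 20, k = 6, n = 2, seed = 1)
#' cc <- collector_curve(comm, iterations = 100, seed = 1)
#' head(cc)
collector_curve <- function(x, site = NULL, n_values = NULL,
                            iterations = 1000, seed = NULL,
                            one_per_site = FALSE) {
  if (is.data.frame(x)) {
    if (!"site_id" %in% names(x)) {
      stop("incidence data frame must have a 'site_id' column", call. = FALSE)
    }
    site <- x$site_id
    keep <- setdiff(names(x), c("site_id", "sample_id"))
    x <- as.matrix(x[keep])
  }
  if (is.null(dim(x)) || nrow(x) == 0L || ncol(x) == 0L) {
    stop("incidence matrix is empty", call. = FALSE)
  }
  if (length(site) != nrow(x)) {
    stop("'site' must give one site id per sample row", call. = FALSE)
  }
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  inc <- matrix(as.numeric(x > 0), nrow = nrow(x),
                dimnames = dimnames(x))
  site <- as.character(site)
  site_rows <- split(seq_len(nrow(inc)), site)
  K <- length(site_rows)
  min_per_site <- min(lengths(site_rows))
  if (is.null(n_values)) n_values <- seq_len(min_per_site)
  if (one_per_site) n_values <- 1L
  if (any(n_values < 1 | n_values > min_per_site)) {
    stop("n_values must lie in 1..", min_per_site,
         " (the smallest per-site sample count)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  res <- array(NA_real_, dim = c(iterations, K, length(n_values)))
  for (it in seq_len(iterations)) {
    for (j in seq_along(n_values)) {
      nn <- n_values[j]
      site_inc <- vapply(site_rows, function(rows) {
        pick <- if (length(rows) == 1L) rows else
          rows[sample.int(length(rows), nn)]
        as.numeric(colSums(inc[pick, , drop = FALSE]) > 0)
      }, numeric(ncol(inc)))
      site_inc <- matrix(site_inc, nrow = ncol(inc), ncol = K)
      # site_inc: species x K; accumulate sites in random order
      ord <- sample.int(K)
      seen <- numeric(ncol(inc))
      for (kk in seq_len(K)) {
        seen <- pmax(seen, site_inc[, ord[kk]])
        res[it, kk, j] <- sum(seen)
      }
    }
  }

  out <- do.call(rbind, lapply(seq_along(n_values), function(j) {
    data.frame(
      n = n_values[j],
      k = seq_len(K),
      median_S = apply(res[, , j, drop = FALSE], 2L, stats::median),
      mean_S = apply(res[, , j, drop = FALSE], 2L, mean),
      q05 = apply(res[, , j, drop = FALSE], 2L, stats::quantile,
                  probs = 0.05, names = FALSE),
      q95 = apply(res[, , j, drop = FALSE], 2L, stats::quantile,
                  probs = 0.95, names = FALSE)
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("collector_curve", "data.frame")
  attr(out, "total_species") <- sum(colSums(inc) > 0)
  attr(out, "iterations") <- iterations
  out
}

#' Fit the multi-scale species-accumulation model
#'
#' Fits the two-scale accumulation model
#' \deqn{S(n, k) = \frac{a + k^z n^c}{b + n^c}}
#' to a collector's curve by nonlinear least squares, where `k` is the
#' number of sites, `n` the number of samples per site, `z` grows with beta
#' diversity among sites (the species-area component independent of
#' within-site effort), `c` sets the slope of the within-site collector's
#' curve, and `a`, `b` are constants. Following standard practice for this
#' model, the fit is run on the log scale — `log(S)` against the log of the
#' model prediction (natural logarithm; switchable with `log_fit`) — with
#' all starting values at 1. Levenberg-Marquardt least squares
#' ([minpack.lm::nlsLM()]) is used for robustness on flat or noisy curves.
#'
#' Non-convergence or an unidentifiable fit (e.g., a flat single-site curve)
#' is reported through the `converged`/`identifiable` flags and `message`
#' rather than an exception, so scenario pipelines can refuse such fits
#' explicitly.
#'
#' @param curve a [collector_curve()] result, or any data frame with columns
#'   `n`, `k` and the response column.
#' @param start named starting values for `a`, `b`, `c`, `z` (default all 1).
#' @param response which summary to fit: `"median"` (headline, as is
#'   conventional), `"mean"`, or the name of a column in `curve`.
#' @param log_fit fit on the log scale (default `TRUE`).
#' @return An object of class `polce_kunin_fit`: a list with `coef`, `se`,
#'   `vcov`, `converged`, `identifiable`, `rss` (residual sum of squares on
#'   the fitted scale), `fitted`, `data`, and `message`.
#' @export
#' @examples
#' grid <- expand.grid(n = 1:2, k = 1:10)
#' grid$median_S <- predict_richness(c(a = 1, b = 1, c = 0.8, z = 1.4),
#'                                   n = grid$n, k = grid$k)
#' fit <- fit_polce_kunin(grid)
#' coef(fit)
fit_polce_kunin <- function(curve, start = c(a = 1, b = 1, c = 1, z = 1),
                            response = c("median", "mean"),
                            log_fit = TRUE) {
  if (is.character(response) && length(response) == 1L &&
      response %in% names(curve)) {
    ycol <- response
  } else {
    response <- match.arg(response)
    ycol <- switch(response, median = "median_S", mean = "mean_S")
  }
  if (!all(c("n", "k", ycol) %in% names(curve))) {
    stop("curve must have columns 'n', 'k', and '", ycol, "'", call. = FALSE)
  }
  dat <- data.frame(n = curve$n, k = curve$k, S = curve[[ycol]])
  dat <- dat[is.finite(dat$S) & dat$S > 0, , drop = FALSE]
  if (nrow(unique(dat[c("n", "k")])) < 4L) {
    stop("need at least 4 distinct (n, k) points with positive richness",
         call. = FALSE)
  }
  start <- start[c("a", "b", "c", "z")]
  if (anyNA(start)) stop("start must name a, b, c, z", call. = FALSE)

  form <- if (log_fit) {
    log(S) ~ log((a + k^z * n^c) / (b + n^c))
  } else {
    S ~ (a + k^z * n^c) / (b + n^c)
  }

  fit <- NULL
  msg <- ""
  ok <- TRUE
  withCallingHandlers(
    tryCatch(
      fit <- minpack.lm::nlsLM(
        form, data = dat, start = as.list(start),
        lower = c(a = 0, b = 1e-8, c = -Inf, z = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      ),
      error = function(e) {
        ok <<- FALSE
        msg <<- conditionMessage(e)
      }
    ),
    warning = function(w) {
      msg <<- paste(msg, conditionMessage(w), sep = "; ")
      invokeRestart("muffleWarning")
    }
  )

  if (!ok || is.null(fit)) {
    out <- list(coef = start, se = stats::setNames(rep(NA_real_, 4),
                                                   names(start)),
                vcov = NULL, converged = FALSE, identifiable = FALSE,
                rss = NA_real_, fitted = NULL, data = dat,
                log_fit = log_fit, message = msg)
    class(out) <- "polce_kunin_fit"
    return(out)
  }

  conv <- isTRUE(fit$convInfo$isConv)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  se <- if (is.null(vc)) {
    stats::setNames(rep(NA_real_, 4), names(start))
  } else {
    sqrt(diag(vc))
  }
  identifiable <- conv && !is.null(vc) && all(is.finite(se))
  out <- list(
    coef = stats::coef(fit),
    se = se,
    vcov = vc,
    converged = conv,
    identifiable = identifiable,
    rss = sum(stats::resid(fit)^2),
    fitted = stats::fitted(fit),
    data = dat,
    log_fit = log_fit,
    message = msg
  )
  class(out) <- "polce_kunin_fit"
  out
}

#' @export
coef.polce_kunin_fit <- function(object, ...) object$coef

#' @export
print.polce_kunin_fit <- function(x, ...) {
  cat("Multi-scale species-accumulation fit  S = (a + k^z n^c)/(b + n^c)\n")
  est <- rbind(estimate = x$coef, std.error = x$se)
  print(round(est, 4))
  cat("converged:", x$converged,
      " identifiable:", x$identifiable,
      " RSS:", format(x$rss, digits = 4), "\n")
  if (nzchar(x$message)) cat("notes:", x$message, "\n")
  invisible(x)
}

#' Predicted richness from an accumulation fit
#'
#' Evaluates `S(n, k) = (a + k^z n^c) / (b + n^c)` on the natural scale. For
#' `z > 0` the prediction is non-decreasing in `k`, and as `n` grows at
#' fixed `k` it approaches the among-site asymptote `k^z`. With
#' `interval = TRUE` a delta-method confidence band is added using the
#' parameter covariance of the fit.
#'
#' @param fit a [fit_polce_kunin()] result, or a named vector/list with
#'   elements `a`, `b`, `c`, `z`.
#' @param n samples per site (vectorised).
#' @param k number of sites (vectorised).
#' @param interval add delta-method confidence limits (requires a fit with a
#'   covariance matrix).
#' @param level confidence level.
#' @return Numeric vector of expected species counts, or a data frame with
#'   `fit`, `ci_low`, `ci_high` when `interval = TRUE`.
#' @export
predict_richness <- function(fit, n, k, interval = FALSE, level = 0.95) {
  pars <- if (inherits(fit, "polce_kunin_fit")) fit$coef else unlist(fit)
  if (!all(c("a", "b", "c", "z") %in% names(pars))) {
    stop("fit must provide parameters a, b, c, z", call. = FALSE)
  }
  a <- pars[["a"]]; b <- pars[["b"]]; cc <- pars[["c"]]; z <- pars[["z"]]
  nc <- n^cc
  den <- b + nc
  if (any(den <= 0)) {
    stop("b + n^c must be positive over the prediction domain", call. = FALSE)
  }
  val <- (a + k^z * nc) / den
  if (!interval) return(val)
  if (!inherits(fit, "polce_kunin_fit") || is.null(fit$vcov)) {
    stop("interval = TRUE needs a fitted model with a covariance matrix",
         call. = FALSE)
  }
  # gradient of S wrt (a, b, c, z)
  u <- k^z * nc
  grad <- cbind(
    a = 1 / den,
    b = -(a + u) / den^2,
    c = (k^z * nc * log(n) * den - (a + u) * nc * log(n)) / den^2,
    z = (k^z * log(k) * nc) / den
  )
  grad[!is.finite(grad)] <- 0  # log(0) terms vanish when n or k is 1
  se <- sqrt(pmax(0, rowSums((grad %*% fit$vcov) * grad)))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(fit = val, ci_low = val - zc * se, ci_high = val + zc * se)
}

#' Read a site-by-species incidence table from CSV
#'
#' Rows are samples; columns are species, plus a `site_id` column (and
#' optionally `sample_id`).
#'
#' @param file path to CSV.
#' @return Data frame suitable for [collector_curve()].
#' @export
read_incidence_matrix <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"site_id" %in% names(x)) {
    stop("incidence file must have a 'site_id' column", call. = FALSE)
  }
  x
}
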