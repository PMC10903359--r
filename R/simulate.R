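# Derived sub-seeds keep the generator's random streams separable (sites /
# species / reads), so enlarging one block does not perturb the others.
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + offset * 7919L
}

#' Simulate binary detection records
#'
#' Draws independent Bernoulli detections with cell probability
#' `inverse_logit(site intercept + method effect)`, emulating the data
#' behind a site-by-method logistic detection analysis. Reproducible for a
#' fixed seed.
#'
#' @param sites named numeric vector of site intercepts on the logit scale.
#' @param methods named numeric vector of method effects on the logit scale
#'   (use 0 for the reference method).
#' @param n_per_cell samples per site-by-method cell (scalar, >= 1).
#' @param seed integer seed.
#' @return Data frame of detection records: `site_id`, `method`,
#'   `sample_id`, `detected`. True cell probabilities are attached as
#'   attribute `"truth"`.
#' @export
#' @examples
#' rec <- simulate_detection(c(siteA = 1.08, siteB = 1.08 - 2.2),
#'                           c(qPCR = 0), n_per_cell = 20, seed = 7)
#' aggregate(detected ~ site_id, rec, mean)
simulate_detection <- function(sites, methods = c(method1 = 0),
                               n_per_cell = 20, seed = 1) {
  if (is.null(names(sites)) || is.null(names(methods))) {
    stop("'sites' and 'methods' must be named numeric vectors", call. = FALSE)
  }
  if (!all(is.finite(sites)) || !all(is.finite(methods))) {
    stop("logit coefficients must be finite", call. = FALSE)
  }
  if (n_per_cell < 1) stop("n_per_cell must be >= 1", call. = FALSE)
  grid <- expand.grid(site_id = names(sites), method = names(methods),
                      stringsAsFactors = FALSE)
  grid$p <- inverse_logit(sites[grid$site_id] + methods[grid$method])
  set.seed(seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    data.frame(
      site_id = grid$site_id[i],
      method = grid$method[i],
      sample_id = sprintf("%s_%s_%03d", grid$site_id[i], grid$method[i],
                          seq_len(n_per_cell)),
      detected = stats::rbinom(n_per_cell, 1L, grid$p[i])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- grid
  out
}

#' Simulate a multi-site community incidence matrix
#'
#' Generates species detections with the spatial structure a multi-scale
#' accumulation analysis assumes: species occupy sites, and occupied-site
#' samples detect a species with a within-site probability, so samples from
#' the same site are more similar than samples from different sites. The
#' `turnover` parameter controls beta diversity: each species draws one
#' region-wide occupancy state, and with probability `turnover` a site
#' replaces it with an independent draw. `turnover = 0` gives identical
#' communities at every site; `turnover = 1` gives fully independent sites
#' (maximal among-site turnover, which inflates the accumulation exponent
#' `z`).
#'
#' @param pool regional species pool size.
#' @param occupancy per-species, per-site occupancy probability.
#' @param detection within-site per-sample detection probability for an
#'   occupying species.
#' @param turnover site-turnover (beta-diversity) control in `[0, 1]`.
#' @param k number of sites.
#' @param n samples per site.
#' @param reads if `TRUE`, layer heavy-tailed (log-normal) read counts on
#'   detections, mimicking metabarcoding read tables whose counts span
#'   several orders of magnitude.
#' @param read_meanlog,read_sdlog log-scale location and spread of the read
#'   counts.
#' @param seed integer seed.
#' @return Data frame with `site_id`, `sample_id` and one column per
#'   species (`sp001`, ...); incidence 0/1, or read counts when
#'   `reads = TRUE`. The site-by-species occupancy truth is attached as
#'   attribute `"truth"`.
#' @export
#' @examples
#' comm <- simulate_community(pool = 25, k = 6, n = 2, turnover = 0.5,
#'                            seed = 11)
#' dim(comm)
simulate_community <- function(pool = 40, occupancy = 0.5, detection = 0.7,
                               turnover = 0.5, k = 8, n = 2, reads = FALSE,
                               read_meanlog = 4, read_sdlog = 2, seed = 1) {
  probs <- c(occupancy = occupancy, detection = detection,
             turnover = turnover)
  if (any(probs < 0 | probs > 1)) {
    stop("occupancy, detection and turnover must be probabilities",
         call. = FALSE)
  }
  if (pool < 1 || k < 1 || n < 1) {
    stop("pool, k and n must be >= 1", call. = FALSE)
  }
  species <- sprintf("sp%03d", seq_len(pool))

  set.seed(sub_seed(seed, 1L))  # occupancy stream
  base_occ <- stats::rbinom(pool, 1L, occupancy)
  indep <- matrix(stats::rbinom(pool * k, 1L, occupancy), nrow = pool)
  flip <- matrix(stats::rbinom(pool * k, 1L, turnover), nrow = pool)
  occ <- ifelse(flip == 1L, indep, base_occ)  # pool x k

  set.seed(sub_seed(seed, 2L))  # detection stream
  det <- array(stats::rbinom(pool * k * n, 1L, detection),
               dim = c(pool, k, n))
  inc <- det * array(occ, dim = c(pool, k, n))

  if (reads) {
    set.seed(sub_seed(seed, 3L))  # read-count stream
    counts <- array(1L + floor(stats::rlnorm(pool * k * n, read_meanlog,
                                             read_sdlog)),
                    dim = c(pool, k, n))
    inc <- inc * counts
  }

  rows <- list()
  for (s in seq_len(k)) {
    for (j in seq_len(n)) {
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sprintf("site%02d", s),
        sample_id = sprintf("site%02d_s%02d", s, j),
        t(inc[, s, j])
      )
    }
  }
  out <- do.call(rbind, rows)
  names(out) <- c("site_id", "sample_id", species)
  rownames(out) <- NULL
  attr(out, "truth") <- list(occupancy = occ, species = species)
  out
}

# Small synthetic fish taxonomy: orders x families x genera x species.
synthetic_taxonomy <- function(n_orders = 2, families_per_order = 2,
                               genera_per_family = 3, species_per_genus = 3) {
  rows <- list()
  for (o in seq_len(n_orders)) {
    for (f in seq_len(families_per_order)) {
      for (g in seq_len(genera_per_family)) {
        genus <- sprintf("Genus%d%d%d", o, f, g)
        for (s in seq_len(species_per_genus)) {
          sp <- sprintf("%s species%d", genus, s)
          rows[[length(rows) + 1L]] <- data.frame(
            taxon = sp, class = "Actinopteri",
            order = sprintf("Order%d", o),
            family = sprintf("Family%d%d", o, f),
            genus = genus, species = sp
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate an ASV hit table with ground-truth assignments
#'
#' Generates an ASV table, plausible-species list, and reference taxonomy
#' that jointly exercise every consensus-taxonomy rule: sub-threshold ASVs
#' (one with exactly 7 reads is always included, the read-filter boundary),
#' single plausible species hits, implausible hits needing reassignment to
#' a congener, multi-candidate ties needing a lowest-common-taxon
#' consensus, and taxa flagged as exogenous. The intended consensus outcome
#' for every ASV is embedded in the `truth` element so the assignment
#' procedure can be checked round-trip.
#'
#' @param n_asvs number of ASVs above the read filter.
#' @param implausible_frac fraction of ASVs whose top hit is an implausible
#'   species (a congener absent from the plausible list).
#' @param tie_frac fraction of ASVs with two equally good plausible
#'   candidate hits (consensus falls to their lowest common taxon).
#' @param exogenous_frac fraction of ASVs assigned to a non-estuarine
#'   (exogenous-source) species.
#' @param read_meanlog,read_sdlog log-normal read-count law.
#' @param seed integer seed.
#' @return List with `asvs` (long hit table), `plausible`, `taxonomy`
#'   (reference paths including the implausible species), and `truth` (one
#'   row per ASV: intended consensus taxon, rank, exogenous flag, and
#'   whether the ASV is below the read filter).
#' @export
#' @examples
#' sim <- simulate_asv_table(n_asvs = 10, seed = 3)
#' table(sim$truth$kind)
simulate_asv_table <- function(n_asvs = 30, implausible_frac = 0.2,
                               tie_frac = 0.2, exogenous_frac = 0.1,
                               read_meanlog = 5, read_sdlog = 1.5,
                               seed = 1) {
  fr <- c(implausible_frac, tie_frac, exogenous_frac)
  if (any(fr < 0) || sum(fr) > 1) {
    stop("fractions must be non-negative and sum to at most 1", call. = FALSE)
  }
  if (n_asvs < 1) stop("n_asvs must be >= 1", call. = FALSE)
  taxonomy <- synthetic_taxonomy()

  set.seed(sub_seed(seed, 1L))  # taxon-structure stream
  # plausible list: two species per genus; the third is the "unsequenced
  # relative" kept only in the reference taxonomy
  by_genus <- split(taxonomy, taxonomy$genus)
  plaus <- do.call(rbind, lapply(by_genus, function(g) g[1:2, ]))
  exo_genera <- sample(names(by_genus), 2L)
  plaus$habitat <- ifelse(plaus$genus %in% exo_genera, "marine", "estuarine")
  plaus$previously_reported <- ""
  plaus$sequenced <- TRUE
  rownames(plaus) <- NULL

  kinds <- sample(c(
    rep("implausible", round(n_asvs * implausible_frac)),
    rep("tie", round(n_asvs * tie_frac)),
    rep("exogenous", round(n_asvs * exogenous_frac)),
    rep("clean", n_asvs)
  )[seq_len(n_asvs)])

  set.seed(sub_seed(seed, 2L))  # read-count stream
  reads <- pmax(8L, as.integer(round(stats::rlnorm(n_asvs, read_meanlog,
                                                   read_sdlog))))

  est_plaus <- plaus[plaus$habitat == "estuarine", ]
  exo_plaus <- plaus[plaus$habitat == "marine", ]

  set.seed(sub_seed(seed, 3L))  # hit-assembly stream
  asv_rows <- list()
  truth_rows <- list()
  add_truth <- function(id, taxon, rank, exo, kind, filtered = FALSE) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      asv_id = id, truth_taxon = taxon, truth_rank = rank,
      truth_exogenous = exo, kind = kind, filtered = filtered
    )
  }
  for (i in seq_len(n_asvs)) {
    id <- sprintf("ASV%03d", i)
    kind <- kinds[i]
    if (kind == "clean") {
      sp <- est_plaus$taxon[sample.int(nrow(est_plaus), 1L)]
      asv_rows[[length(asv_rows) + 1L]] <- data.frame(
        asv_id = id, total_reads = reads[i], hit_taxon = sp,
        percent_identity = round(stats::runif(1, 97, 100), 1)
      )
      add_truth(id, sp, "species", FALSE, kind)
    } else if (kind == "exogenous") {
      sp <- exo_plaus$taxon[sample.int(nrow(exo_plaus), 1L)]
      asv_rows[[length(asv_rows) + 1L]] <- data.frame(
        asv_id = id, total_reads = reads[i], hit_taxon = sp,
        percent_identity = round(stats::runif(1, 97, 100), 1)
      )
      add_truth(id, sp, "species", TRUE, kind)
    } else if (kind == "implausible") {
      # hit the genus member missing from the plausible list; truth is its
      # alphabetically-first plausible congener
      g <- sample(setdiff(unique(est_plaus$genus), exo_genera), 1L)
      gtax <- taxonomy[taxonomy$genus == g, ]
      missing_sp <- setdiff(gtax$taxon, plaus$taxon)[1]
      expected <- sort(intersect(gtax$taxon, est_plaus$taxon))[1]
      asv_rows[[length(asv_rows) + 1L]] <- data.frame(
        asv_id = id, total_reads = reads[i], hit_taxon = missing_sp,
        percent_identity = round(stats::runif(1, 92, 97), 1)
      )
      add_truth(id, expected, "species", FALSE, kind)
    } else { # tie: two plausible congeners at identical identity
      g <- sample(setdiff(unique(est_plaus$genus), exo_genera), 1L)
      pair <- est_plaus$taxon[est_plaus$genus == g][1:2]
      ident <- round(stats::runif(1, 95, 99), 1)
      asv_rows[[length(asv_rows) + 1L]] <- data.frame(
        asv_id = id, total_reads = rep(reads[i], 2L), hit_taxon = pair,
        percent_identity = rep(ident, 2L)
      )
      add_truth(id, g, "genus", FALSE, kind)
    }
  }

  # boundary ASV: exactly 7 reads, removed by the read filter
  id7 <- sprintf("ASV%03d", n_asvs + 1L)
  asv_rows[[length(asv_rows) + 1L]] <- data.frame(
    asv_id = id7, total_reads = 7L,
    hit_taxon = est_plaus$taxon[1], percent_identity = 99.5
  )
  add_truth(id7, NA_character_, NA_character_, NA, "subthreshold",
            filtered = TRUE)

  asvs <- do.call(rbind, asv_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(asvs) <- rownames(truth) <- NULL
  list(asvs = asvs, plausible = plaus, taxonomy = taxonomy, truth = truth)
}
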