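#' Filter ASVs by total read count
#'
#' Removes low-confidence amplicon sequence variants: an ASV is retained
#' only if it was observed at least `min_reads` times in total (default 8,
#' i.e., ASVs with fewer than 8 reads are dropped). Idempotent.
#'
#' @param asvs ASV hit table in long format: one row per (ASV, candidate
#'   taxon) with columns `asv_id`, `total_reads`, `hit_taxon`,
#'   `percent_identity`.
#' @param min_reads minimum total read count to retain an ASV.
#' @return The filtered hit table.
#' @export
#' @examples
#' tab <- data.frame(asv_id = c("a", "b"), total_reads = c(7, 8),
#'                   hit_taxon = "x", percent_identity = 99)
#' filter_asvs(tab)$asv_id  # "b"
filter_asvs <- function(asvs, min_reads = 8) {
  need <- c("asv_id", "total_reads")
  missing_cols <- setdiff(need, names(asvs))
  if (length(missing_cols)) {
    stop("ASV table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(asvs$total_reads < 0, na.rm = TRUE)) {
    stop("total_reads must be non-negative", call. = FALSE)
  }
  asvs[asvs$total_reads >= min_reads, , drop = FALSE]
}

taxonomy_ranks <- c("class", "order", "family", "genus", "species")

lookup_path <- function(taxon, taxonomy) {
  i <- match(taxon, taxonomy$taxon)
  if (is.na(i)) return(NULL)
  unlist(taxonomy[i, taxonomy_ranks], use.names = TRUE)
}

# Shared rank-path depth between two species-level paths: number of leading
# ranks (class -> species) on which they agree.
shared_depth <- function(p1, p2) {
  same <- p1 == p2 & !is.na(p1) & !is.na(p2)
  if (!all(same)) {
    d <- which(!same)[1] - 1L
  } else {
    d <- length(same)
  }
  d
}

#' Lowest common taxon of a set of candidates
#'
#' Walks the rank paths of the candidate taxa from species upward and
#' returns the finest rank at which all candidates agree under the supplied
#' taxonomy.
#'
#' @param taxa character vector of taxon names present in `taxonomy`.
#' @param taxonomy taxonomy table (see [read_plausible_list()] for the
#'   format).
#' @return List with `taxon` and `rank` (`NA` if the candidates share no
#'   rank at all).
#' @export
lowest_common_taxon <- function(taxa, taxonomy) {
  paths <- lapply(taxa, lookup_path, taxonomy = taxonomy)
  if (any(vapply(paths, is.null, logical(1)))) {
    stop("taxon without a rank path in the supplied taxonomy: ",
         paste(taxa[vapply(paths, is.null, logical(1))], collapse = ", "),
         call. = FALSE)
  }
  mat <- do.call(rbind, paths)
  for (r in rev(seq_along(taxonomy_ranks))) {
    vals <- mat[, r]
    if (!anyNA(vals) && length(unique(vals)) == 1L) {
      return(list(taxon = vals[1], rank = taxonomy_ranks[r]))
    }
  }
  list(taxon = NA_character_, rank = NA_character_)
}

closest_plausible_relative <- function(taxon, plausible, taxonomy) {
  path <- lookup_path(taxon, taxonomy)
  if (is.null(path)) {
    stop("candidate taxon '", taxon, "' has no rank path in the supplied ",
         "taxonomy", call. = FALSE)
  }
  cand <- plausible$taxon
  depths <- vapply(cand, function(p) {
    shared_depth(path, lookup_path(p, plausible))
  }, numeric(1))
  best <- max(depths)
  if (best == 0) return(NULL)
  hits <- sort(cand[depths == best])  # deterministic alphabetical tie-break
  list(taxon = hits[1], tied = hits)
}

#' Consensus taxonomy for ASVs under a plausible-species list
#'
#' Implements the consensus-assignment procedure for metabarcoding ASVs:
#' \enumerate{
#'   \item only candidate taxa at the maximum percent identity for the ASV
#'     are retained;
#'   \item candidates absent from the plausible-species list are reassigned
#'     to their closest plausible relative, defined as the plausible species
#'     sharing the deepest rank path (class to genus) with the candidate;
#'     ties are broken alphabetically and reported in the `note` column;
#'   \item a single surviving candidate is assigned at species rank; several
#'     surviving candidates are collapsed to their lowest common taxon;
#'   \item assignments whose surviving candidates are all flagged as
#'     non-estuarine on the plausible list are marked `exogenous` — valid
#'     detections whose DNA likely arrived from outside the habitat (e.g.,
#'     bird feces or currents).
#' }
#' A candidate with no resolvable plausible relative yields an `unassigned`
#' row rather than being dropped silently.
#'
#' @param asvs long-format hit table (see [filter_asvs()]); normally already
#'   read-filtered.
#' @param plausible plausible-species list with rank paths and flags (see
#'   [read_plausible_list()]).
#' @param taxonomy reference taxonomy holding rank paths for every candidate
#'   hit (defaults to the plausible list; supply a wider table when hits can
#'   fall outside it).
#' @return Data frame with one row per ASV: `asv_id`, `consensus_taxon`,
#'   `rank`, `exogenous`, `reassigned_from`, `reads`, `note`.
#' @export
#' @examples
#' sim <- simulate_asv_table(n_asvs = 12, seed = 1)
#' consensus_assign(filter_asvs(sim$asvs), sim$plausible, sim$taxonomy)
consensus_assign <- function(asvs, plausible, taxonomy = plausible) {
  need <- c("asv_id", "total_reads", "hit_taxon", "percent_identity")
  missing_cols <- setdiff(need, names(asvs))
  if (length(missing_cols)) {
    stop("ASV table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(asvs$percent_identity < 0 | asvs$percent_identity > 100)) {
    stop("percent_identity must be in [0, 100]", call. = FALSE)
  }
  plaus_flag <- plausible_flags(plausible)

  one_asv <- function(d) {
    reads <- d$total_reads[1]
    top <- d[d$percent_identity == max(d$percent_identity), , drop = FALSE]
    reassigned <- character(0)
    note <- character(0)
    candidates <- character(0)
    for (tx in unique(top$hit_taxon)) {
      if (tx %in% plausible$taxon) {
        candidates <- c(candidates, tx)
      } else {
        rel <- closest_plausible_relative(tx, plausible, taxonomy)
        if (is.null(rel)) {
          note <- c(note, paste0("no plausible relative for '", tx, "'"))
        } else {
          candidates <- c(candidates, rel$taxon)
          reassigned <- c(reassigned, tx)
          if (length(rel$tied) > 1L) {
            note <- c(note, paste0("tie among {",
                                   paste(rel$tied, collapse = ", "),
                                   "} broken alphabetically"))
          }
        }
      }
    }
    candidates <- unique(candidates)
    if (!length(candidates)) {
      return(data.frame(
        asv_id = d$asv_id[1], consensus_taxon = "unassigned",
        rank = NA_character_, exogenous = NA,
        reassigned_from = paste(reassigned, collapse = ";"),
        reads = reads,
        note = paste(note, collapse = "; ")
      ))
    }
    if (length(candidates) == 1L) {
      cons <- list(taxon = candidates, rank = "species")
    } else {
      cons <- lowest_common_taxon(candidates, plausible)
    }
    exo <- all(plaus_flag$exogenous[match(candidates, plausible$taxon)])
    data.frame(
      asv_id = d$asv_id[1], consensus_taxon = cons$taxon, rank = cons$rank,
      exogenous = exo,
      reassigned_from = paste(reassigned, collapse = ";"),
      reads = reads,
      note = paste(note, collapse = "; ")
    )
  }

  pieces <- lapply(split(asvs, asvs$asv_id), one_asv)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$asv_id), , drop = FALSE]
}

plausible_flags <- function(plausible) {
  exo <- if ("habitat" %in% names(plausible)) {
    !(plausible$habitat %in% "estuarine")
  } else {
    rep(FALSE, nrow(plausible))
  }
  list(exogenous = exo)
}

#' Read a plausible-species list / taxonomy table
#'
#' The format is shared by the plausible list and the wider reference
#' taxonomy: one row per taxon with columns `taxon`, `class`, `order`,
#' `family`, `genus`, `species`, and (for the plausible list) flags
#' `previously_reported` (reference keys, possibly empty), `habitat`
#' (`"estuarine"` or another habitat; non-estuarine taxa are treated as
#' exogenous DNA sources), and `sequenced` (present in the reference
#' sequence database). Internal consistency of the rank paths (a species'
#' genus matching its listed genus) is checked on read.
#'
#' @param file path to CSV; defaults to the packaged estuary fish list.
#' @return Data frame.
#' @export
read_plausible_list <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "calleguas_plausible.csv",
                        package = "surveycost")
  }
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("taxon", taxonomy_ranks)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("plausible list is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sp <- !is.na(x$species) & nzchar(x$species)
  bad <- sp & (x$taxon != x$species)
  if (any(bad)) {
    stop("inconsistent rank path for: ",
         paste(x$taxon[bad], collapse = ", "), call. = FALSE)
  }
  x
}

#' Read an ASV hit table from TSV
#'
#' Long format: one row per (ASV, candidate hit) with columns `asv_id`,
#' `total_reads`, `hit_taxon`, `percent_identity`.
#'
#' @param file path to TSV.
#' @return Data frame.
#' @export
read_asv_table <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("asv_id", "total_reads", "hit_taxon", "percent_identity")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("ASV table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x
}

#' Community detection table for an estuary survey
#'
#' Reads a per-taxon community table comparing detection methods: columns
#' `taxon`, `rank` (`species` or a coarser rank for ambiguous ASV
#' assignments), `exogenous` (logical), `previous_refs` (reference keys for
#' earlier reports, empty when unreported), `edna_reads` (read count, `0`,
#' `?` for unknown/possibly subsumed in an ambiguous ASV, or blank), and
#' `seine_count` (count, `Visual` for a sighting during seining, or blank).
#' `read_community_table()` with no argument returns the packaged survey
#' table for the Calleguas Creek estuary.
#'
#' @param file path to CSV, or `NULL` for the packaged table.
#' @return Data frame of class `community_table`.
#' @export
#' @examples
#' tab <- read_community_table()
#' count_species(tab, "edna_all")
read_community_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "calleguas_fishes.csv",
                        package = "surveycost")
  }
  x <- utils::read.csv(file, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("taxon", "rank", "exogenous", "previous_refs", "edna_reads",
            "seine_count")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("community table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$exogenous <- as.logical(x$exogenous)
  class(x) <- c("community_table", "data.frame")
  x
}

# Parse a detection cell into a count or a marker. "" and NA are
# "not detected"; "?" is "unknown"; "Visual" a non-capture sighting.
parse_count_cell <- function(cell, taxon, column) {
  cell <- trimws(cell)
  if (is.na(cell) || cell == "") return(list(kind = "absent", count = 0))
  if (cell == "?") return(list(kind = "unknown", count = NA_real_))
  if (tolower(cell) == "visual") return(list(kind = "visual",
                                             count = NA_real_))
  n <- suppressWarnings(as.numeric(gsub(",", "", cell)))
  if (is.na(n) || n < 0) {
    stop("malformed count '", cell, "' in column '", column, "' for taxon '",
         taxon, "'", call. = FALSE)
  }
  list(kind = "count", count = n)
}

#' Species-count filters on a community table
#'
#' Applies the tallying rules used when comparing detection methods on a
#' community table:
#' \describe{
#'   \item{`edna_all`}{taxa with positive eDNA reads, including
#'     coarser-than-species assignments and exogenous taxa; unknown (`?`)
#'     cells never count.}
#'   \item{`edna_species_rank`}{positive-eDNA taxa resolved to species rank,
#'     excluding exogenous taxa.}
#'   \item{`seine`}{taxa with positive seine capture counts (visual-only
#'     records excluded).}
#'   \item{`edna_new_reports`}{species-rank, non-exogenous eDNA detections
#'     with no previous report for the system.}
#'   \item{`seine_new_reports`}{seine captures of species with no previous
#'     report.}
#' }
#'
#' @param table a [read_community_table()] result.
#' @param mode one of the modes above.
#' @return Integer count.
#' @export
count_species <- function(table, mode = c("edna_all", "edna_species_rank",
                                          "seine", "edna_new_reports",
                                          "seine_new_reports")) {
  mode <- match.arg(mode)
  if (nrow(table) == 0L) return(0L)
  edna <- lapply(seq_len(nrow(table)), function(i) {
    parse_count_cell(table$edna_reads[i], table$taxon[i], "edna_reads")
  })
  seine <- lapply(seq_len(nrow(table)), function(i) {
    parse_count_cell(table$seine_count[i], table$taxon[i], "seine_count")
  })
  edna_pos <- vapply(edna, function(x) x$kind == "count" && x$count > 0,
                     logical(1))
  seine_pos <- vapply(seine, function(x) x$kind == "count" && x$count > 0,
                      logical(1))
  is_species <- table$rank == "species"
  not_exo <- !table$exogenous
  new_rep <- !nzchar(trimws(table$previous_refs))
  sum(switch(mode,
    edna_all = edna_pos,
    edna_species_rank = edna_pos & is_species & not_exo,
    seine = seine_pos,
    edna_new_reports = edna_pos & is_species & not_exo & new_rep,
    seine_new_reports = seine_pos & is_species & not_exo & new_rep
  ))
}
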