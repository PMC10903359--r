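test_that("read filter keeps ASVs observed at least 8 times", {
  tab <- data.frame(asv_id = c("a", "b", "c"), total_reads = c(7, 8, 120),
                    hit_taxon = "x", percent_identity = 99)
  kept <- filter_asvs(tab)
  expect_setequal(kept$asv_id, c("b", "c"))
  expect_identical(filter_asvs(kept), kept)  # idempotent
  empty <- tab[0, ]
  expect_equal(nrow(filter_asvs(empty)), 0L)
})

plaus <- read_plausible_list()
ref_tax <- rbind(
  plaus[c("taxon", "class", "order", "family", "genus", "species")],
  utils::read.csv(system.file("extdata", "calleguas_reference_taxonomy.csv",
                              package = "surveycost"))
)

test_that("implausible hits are reassigned to the closest plausible
           relative", {
  # a Baja congener absent from the plausible list falls back to the local,
  # unsequenced member of its genus
  asv <- data.frame(asv_id = "ASV1", total_reads = 500,
                    hit_taxon = "Fundulus lima", percent_identity = 98)
  out <- consensus_assign(asv, plaus, ref_tax)
  expect_equal(out$consensus_taxon, "Fundulus parvipinnis")
  expect_equal(out$rank, "species")
  expect_false(out$exogenous)
  expect_equal(out$reassigned_from, "Fundulus lima")
})

test_that("multiple surviving candidates collapse to their lowest common
           taxon", {
  asv <- data.frame(asv_id = "ASV2", total_reads = 312,
                    hit_taxon = c("Carassius auratus", "Cyprinus carpio"),
                    percent_identity = c(97.5, 97.5))
  out <- consensus_assign(asv, plaus, ref_tax)
  expect_equal(out$consensus_taxon, "Cyprinidae")
  expect_equal(out$rank, "family")
  expect_false(out$exogenous)

  # congeners collapse to the genus
  asv2 <- data.frame(asv_id = "ASV3", total_reads = 176,
                     hit_taxon = c("Quietula y-cauda", "Ilypnus gilberti"),
                     percent_identity = c(96, 96))
  out2 <- consensus_assign(asv2, plaus, ref_tax)
  expect_equal(out2$rank, "family")
  expect_equal(out2$consensus_taxon, "Gobiidae")
})

test_that("only maximum-identity hits survive; singletons get species rank", {
  asv <- data.frame(asv_id = "ASV4", total_reads = 100,
                    hit_taxon = c("Clevelandia ios", "Gillichthys mirabilis"),
                    percent_identity = c(99.8, 94.0))
  out <- consensus_assign(asv, plaus, ref_tax)
  expect_equal(out$consensus_taxon, "Clevelandia ios")
  expect_equal(out$rank, "species")
})

test_that("plausible-but-marine taxa are retained and flagged exogenous", {
  asv <- data.frame(asv_id = "ASV5", total_reads = 14,
                    hit_taxon = "Engraulis mordax", percent_identity = 99)
  out <- consensus_assign(asv, plaus, ref_tax)
  expect_equal(out$consensus_taxon, "Engraulis mordax")
  expect_true(out$exogenous)
})

test_that("candidates with no resolvable relative become 'unassigned'", {
  lonely <- data.frame(taxon = "Alienus nullus", class = "Chondrichthyes",
                       order = "OrdX", family = "FamX", genus = "Alienus",
                       species = "Alienus nullus")
  asv <- data.frame(asv_id = "ASV6", total_reads = 50,
                    hit_taxon = "Alienus nullus", percent_identity = 91)
  out <- consensus_assign(asv, plaus, rbind(ref_tax, lonely))
  expect_equal(out$consensus_taxon, "unassigned")
  expect_match(out$note, "no plausible relative")
})

test_that("assignment is deterministic and never finer than its
           candidates", {
  sim <- simulate_asv_table(n_asvs = 25, seed = 9)
  kept <- filter_asvs(sim$asvs)
  a <- consensus_assign(kept, sim$plausible, sim$taxonomy)
  b <- consensus_assign(kept, sim$plausible, sim$taxonomy)
  expect_identical(a, b)
  expect_true(all(a$rank %in% c("species", "genus", "family", "order",
                                "class")))
  # ASVs with several distinct surviving candidates cannot sit at species rank
  n_cand <- tapply(kept$hit_taxon, kept$asv_id,
                   function(x) length(unique(x)))
  multi <- names(n_cand)[n_cand > 1]
  expect_true(all(a$rank[a$asv_id %in% multi] != "species"))
})

test_that("community table count filters reproduce the method comparison", {
  tab <- read_community_table()
  expect_equal(count_species(tab, "edna_all"), 16)
  expect_equal(count_species(tab, "seine"), 8)
  expect_equal(count_species(tab, "edna_species_rank"), 12)
  expect_equal(count_species(tab, "edna_new_reports"), 3)
  expect_equal(count_species(tab, "seine_new_reports"), 2)

  empty <- tab[0, ]
  for (m in c("edna_all", "edna_species_rank", "seine", "edna_new_reports",
              "seine_new_reports")) {
    expect_equal(count_species(empty, m), 0L)
  }

  bad <- tab
  bad$edna_reads[2] <- "lots"
  expect_error(count_species(bad, "edna_all"), "Atherinops affinis")
})

test_that("unknown and visual-only cells never count as detections", {
  tab <- read_community_table()
  # taxa marked "?" (possibly subsumed in an ambiguous ASV) are excluded
  unknowns <- tab$taxon[tab$edna_reads == "?"]
  expect_true("Carassius auratus" %in% unknowns)
  base <- count_species(tab, "edna_all")
  tab$edna_reads[tab$taxon == "Carassius auratus"] <- "500"
  expect_equal(count_species(tab, "edna_all"), base + 1)
  # the visually-recorded mullet is not a seine capture
  expect_false("Mugil cephalus" %in%
                 tab$taxon[vapply(tab$seine_count, function(x)
                   !is.na(suppressWarnings(as.numeric(x))) &&
                     as.numeric(x) > 0, logical(1))])
})
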