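toyDegrons <- data.frame(
  substrate_id = "S1",
  degron_class = c("primary", "secondary", "tertiary"),
  start = c(19L, 97L, 150L), end = c(26L, 97L, 200L),
  stringsAsFactors = FALSE)

toyFeature <- function(partner, start, end) {
  data.frame(substrate_id = "S1", partner_id = partner,
             interaction_id = paste0("I", partner), confidence = 0.9,
             feature_kind = "sufficient_binding_region",
             start = start, end = end, stringsAsFactors = FALSE)
}

test_that("a substrate with three partners and one masking gives (3, 1)", {
  feats <- rbind(toyFeature("A", 10L, 40L),       # overlaps primary
                 toyFeature("B", 60L, 70L),       # unrelated
                 toyFeature("C", NA, NA))         # no mapped feature
  cens <- maskingCensus(feats, toyDegrons)$census
  expect_equal(cens$n_partners_total, 3L)
  expect_equal(cens$n_masking_primary, 1L)
  expect_equal(cens$n_masking_secondary, 0L)
})

test_that("partners without mapped features never count as masking", {
  feats <- toyFeature("C", NA, NA)
  cens <- maskingCensus(feats, toyDegrons)$census
  expect_equal(cens$n_partners_total, 1L)
  expect_equal(cens$n_masking_primary + cens$n_masking_secondary +
                 cens$n_masking_tertiary, 0L)
})

test_that("a partner counts once per degron class however many features hit", {
  feats <- rbind(toyFeature("A", 10L, 40L), toyFeature("A", 15L, 30L))
  res <- maskingCensus(feats, toyDegrons)
  expect_equal(res$census$n_masking_primary, 1L)
})

test_that("substrates reach flagged status at ten masking partners", {
  feats <- do.call(rbind, lapply(1:10, function(i)
    toyFeature(sprintf("A%02d", i), 10L, 40L)))
  res <- maskingCensus(feats, toyDegrons)
  expect_true(res$census$flagged)
  res9 <- maskingCensus(feats[1:9, ], toyDegrons)
  expect_false(res9$census$flagged)
})

test_that("census is monotone under added features and removed filters", {
  cfg <- tinyConfig()
  sub <- simulateSubstrates(cfg)
  inter <- simulateInteractions(cfg, sub$substrates, sub$degrons)
  filtered <- filterInteractionRecords(inter$records, 0.3)
  base <- maskingCensus(filtered, sub$degrons)$census
  # removing the confidence filter never decreases any count
  full <- maskingCensus(inter$records, sub$degrons)$census
  shared <- intersect(base$substrate_id, full$substrate_id)
  for (col in c("n_partners_total", "n_masking_primary",
                "n_masking_secondary", "n_masking_tertiary")) {
    expect_true(all(full[match(shared, full$substrate_id), col] >=
                      base[match(shared, base$substrate_id), col]))
  }
  # adding one more masking feature never decreases counts
  extra <- rbind(filtered, data.frame(
    substrate_id = sub$degrons$substrate_id[[1]], partner_id = "NEWP",
    interaction_id = "INEW", confidence = 0.9,
    feature_kind = "sufficient_binding_region",
    start = sub$degrons$start[[1]], end = sub$degrons$end[[1]],
    stringsAsFactors = FALSE))
  grown <- maskingCensus(extra, sub$degrons)$census
  for (col in c("n_partners_total", "n_masking_primary")) {
    expect_true(all(grown[match(base$substrate_id, grown$substrate_id),
                          col] >= base[[col]]))
  }
})

test_that("census recovers exactly the planted recoverable pairs", {
  cfg <- tinyConfig(seed = 9)
  sub <- simulateSubstrates(cfg)
  inter <- simulateInteractions(cfg, sub$substrates, sub$degrons)
  goa <- simulateGoAnnotations(cfg)
  ann <- filterAnnotations(goa$gaf, goa$dag)
  rec <- filterInteractionRecords(inter$records, 0.3)
  kept <- filterUpsPartners(unique(rec$partner_id), ann, goa$blacklist,
                            goa$dag)
  rec <- rec[rec$partner_id %in% kept, ]
  got <- unique(maskingCensus(rec, sub$degrons)$maskingPairs[,
    c("substrate_id", "partner_id")])
  expect_setequal(paste(got$substrate_id, got$partner_id),
                  paste(inter$recoverablePairs$substrate_id,
                        inter$recoverablePairs$partner_id))
})

test_that("masking counts sit inside the binomial band of the planted rate", {
  cfg <- synthConfig(seed = 5, n_substrates = 8,
                     n_partners_per_substrate = 20, masking_fraction = 0.5,
                     low_conf_fraction = 0, ups_fraction = 0)
  sub <- simulateSubstrates(cfg)
  inter <- simulateInteractions(cfg, sub$substrates, sub$degrons)
  cens <- maskingCensus(inter$records, sub$degrons)$census
  masking <- pmax(cens$n_masking_primary,
                  pmax(cens$n_masking_secondary, cens$n_masking_tertiary))
  band <- qbinom(c(0.005, 0.995), 20, 0.5)
  nMask <- vapply(cens$substrate_id, function(s) {
    length(unique(inter$maskingPairs$partner_id[
      inter$maskingPairs$substrate_id == s]))
  }, 1L)
  expect_true(all(nMask >= band[1] & nMask <= band[2]))
  expect_true(all(masking <= cens$n_partners_total))
})

test_that("motif census matches a brute-force recount and handles empties", {
  empty <- motifCategoryCensus(
    data.frame(substrate_id = character(), motif_id = character(),
               category = character(), start = integer(), end = integer()),
    toyDegrons)
  expect_true(all(empty$count == 0L))
  one <- motifCategoryCensus(
    data.frame(substrate_id = "S1", motif_id = "m1", category = "docking",
               start = 20L, end = 24L, stringsAsFactors = FALSE),
    toyDegrons)
  expect_equal(one$count[one$degron_class == "primary" &
                           one$category == "docking"], 1L)
  expect_equal(sum(one$count), 1L)
  # randomized placement vs scalar recount through classifyRegionRelation
  cfg <- tinyConfig(seed = 13)
  sub <- simulateSubstrates(cfg)
  motifs <- simulateMotifs(cfg, sub$substrates, sub$degrons)
  cens <- motifCategoryCensus(motifs, sub$degrons)
  recount <- 0L
  for (i in seq_len(nrow(motifs))) {
    dg <- sub$degrons[sub$degrons$substrate_id == motifs$substrate_id[[i]], ]
    for (cl in unique(dg$degron_class)) {
      dcl <- dg[dg$degron_class == cl, ]
      hit <- any(vapply(seq_len(nrow(dcl)), function(k)
        classifyRegionRelation(c(dcl$start[[k]], dcl$end[[k]]),
                               c(motifs$start[[i]], motifs$end[[i]]))$relation
        != "none", TRUE))
      recount <- recount + as.integer(hit)
    }
  }
  expect_equal(sum(cens$count), recount)
})

test_that("degron-protein counter tallies distinct substrates per class", {
  dg <- data.frame(
    substrate_id = c("A", "A", "B", "C", "C"),
    degron_class = c("primary", "secondary", "primary", "tertiary",
                     "tertiary"),
    start = 1L, end = 10L, stringsAsFactors = FALSE)
  expect_equal(countDegronProteins(dg),
               c(primary = 2L, secondary = 1L, tertiary = 1L))
})
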