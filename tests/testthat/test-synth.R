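test_that("invalid configurations are rejected", {
  expect_error(synthConfig(n_substrates = 0),
               class = "degronon_config_error")
  expect_error(synthConfig(masking_fraction = 1.2),
               class = "degronon_config_error")
  expect_error(synthConfig(e3_ap_fold = 0.5),
               class = "degronon_config_error")
  expect_error(synthConfig(module_size = 1),
               class = "degronon_config_error")
})

test_that("identical seeds give identical outputs, files byte for byte", {
  cfg <- tinyConfig(seed = 77)
  a <- simulateSubstrates(cfg); b <- simulateSubstrates(cfg)
  expect_identical(a, b)
  ia <- simulateInteractions(cfg, a$substrates, a$degrons)
  ib <- simulateInteractions(cfg, b$substrates, b$degrons)
  expect_identical(ia, ib)
  expect_identical(simulateGoAnnotations(cfg), simulateGoAnnotations(cfg))
  expect_identical(simulateCodegradationNetwork(cfg),
                   simulateCodegradationNetwork(cfg))
  d1 <- file.path(tempdir(), "synthA"); d2 <- file.path(tempdir(), "synthB")
  writeDisorderProfiles(a$profiles, d1)
  writeDisorderProfiles(b$profiles, d2)
  f <- list.files(d1)[1]
  expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                   readBin(file.path(d2, f), "raw", 1e6))
  unlink(c(d1, d2), recursive = TRUE)
  # different seed, different data
  expect_false(identical(a, simulateSubstrates(tinyConfig(seed = 78))))
})

test_that("substrates satisfy their construction contracts", {
  cfg <- tinyConfig(seed = 1)
  out <- simulateSubstrates(cfg)
  expect_equal(nrow(out$substrates), cfg$n_substrates)
  expect_true(all(out$substrates$length >= 200 &
                    out$substrates$length <= 800))
  prim <- out$degrons[out$degrons$degron_class == "primary", ]
  expect_true(all(prim$end - prim$start + 1 >= 6 &
                    prim$end - prim$start + 1 <= 14))
  for (i in seq_len(nrow(out$truth))) {
    sid <- out$truth$substrate_id[[i]]
    p <- out$profiles[[sid]]
    expect_true(all(p >= 0 & p <= 1))
    # a qualifying run exists and the recorded truth is the nearest one
    got <- inferTertiaryDegron(p, out$truth$ubsite[[i]])
    expect_equal(got$start, out$truth$start[[i]])
    expect_equal(got$end, out$truth$end[[i]])
    # the Ubsite is a lysine
    seqv <- strsplit(out$substrates$sequence[[i]], "")[[1]]
    expect_equal(seqv[[out$truth$ubsite[[i]]]], "K")
  }
})

test_that("masking fraction zero and one hit their extremes", {
  cfg0 <- tinyConfig(masking_fraction = 0)
  s0 <- simulateSubstrates(cfg0)
  i0 <- simulateInteractions(cfg0, s0$substrates, s0$degrons)
  expect_equal(nrow(i0$maskingPairs), 0L)
  cfg1 <- tinyConfig(masking_fraction = 1, low_conf_fraction = 0,
                     ups_fraction = 0)
  s1 <- simulateSubstrates(cfg1)
  i1 <- simulateInteractions(cfg1, s1$substrates, s1$degrons)
  expect_equal(nrow(i1$maskingPairs),
               cfg1$n_substrates * cfg1$n_partners_per_substrate)
  # full recovery by the census at the standard thresholds
  cens <- maskingCensus(filterInteractionRecords(i1$records, 0.3),
                        s1$degrons)
  got <- unique(cens$maskingPairs[, c("substrate_id", "partner_id")])
  got <- got[!grepl("_E3$", got$partner_id), ]
  expect_setequal(paste(got$substrate_id, got$partner_id),
                  paste(i1$maskingPairs$substrate_id,
                        i1$maskingPairs$partner_id))
})

test_that("below-threshold interactions never reach the recoverable set", {
  cfg <- tinyConfig(seed = 23)
  s <- simulateSubstrates(cfg)
  i <- simulateInteractions(cfg, s$substrates, s$degrons)
  rec <- filterInteractionRecords(i$records, 0.3)
  expect_true(all(rec$confidence >= 0.3))
  expect_false(any(i$records$interaction_id[i$records$confidence < 0.3]
                   %in% rec$interaction_id))
  lowPartners <- i$records$partner_id[i$records$confidence < 0.3]
  expect_false(any(i$recoverablePairs$partner_id %in% lowPartners))
})

test_that("the synthetic ontology is acyclic with module semsim structure", {
  cfg <- tinyConfig()
  goa <- simulateGoAnnotations(cfg)
  expect_true(validObject(goa$dag))
  ann <- filterAnnotations(goa$gaf, goa$dag)
  simFun <- makeGeneSimilarity(ann, goa$dag)
  # identical annotation sets give similarity 1
  g1 <- "M1_P2"; g2 <- "M1_P3"
  if (identical(geneTerms(ann, g1), geneTerms(ann, g2)))
    expect_equal(simFun(g1, g2), 1)
  # within-module mean similarity beats the background mean
  within <- mean(c(simFun("M1_P2", "M1_P3"), simFun("M1_P4", "M1_P5"),
                   simFun("M2_P2", "M2_P3")))
  set.seed(1)
  bgGenes <- sprintf("B%03d", sample(cfg$n_background, 8))
  bgPairs <- utils::combn(bgGenes, 2)
  background <- mean(vapply(seq_len(ncol(bgPairs)), function(k)
    simFun(bgPairs[1, k], bgPairs[2, k]), 1))
  expect_gt(within, background)
})

test_that("abundance latent factor induces substrate-E3 correlation", {
  cfg <- synthConfig(seed = 31, n_datasets = 60, latent_log_sd = 0.3,
                     missing_rate = 0, n_filler = 50)
  roles <- c(S1 = "substrate", E1 = "e3", A1 = "ap")
  datasets <- simulateAbundanceDatasets(cfg, roles)
  mods <- list(regulatoryModule("S1", "E1", "A1"))
  res <- substratePartnerCorrelation(mods, datasets, "per_e3")
  expect_gt(res$r, 0.2)
  expect_equal(res$n, 60L)
})

test_that("planted module half-lives concentrate, background does not", {
  cfg <- synthConfig(seed = 37)
  sim <- simulateCodegradationNetwork(cfg)
  hl <- halfLives(sim$halflives)
  mem <- sim$truth$membership
  ed <- networkEdges(sim$network)
  planted <- mem[ed$a] != "background" & mem[ed$a] == mem[ed$b]
  ratio <- pmin(hl[ed$a], hl[ed$b]) / pmax(hl[ed$a], hl[ed$b])
  expect_gte(mean(ratio[planted] >= 0.8), 0.8)
  # background random pairs sit well below the similar band
  bg <- names(mem)[mem == "background"]
  set.seed(2)
  i1 <- sample(bg, 400, TRUE); i2 <- sample(bg, 400, TRUE)
  ok <- i1 != i2
  bgRatio <- pmin(hl[i1[ok]], hl[i2[ok]]) / pmax(hl[i1[ok]], hl[i2[ok]])
  expect_lt(median(bgRatio), 0.8)
  # planted paths live inside their modules and network is simple
  for (m in seq_along(sim$truth$plantedPaths)) {
    path <- sim$truth$plantedPaths[[m]]
    expect_true(all(mem[path] == sprintf("module%d", m)))
  }
  expect_true(validObject(sim$network))
})
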