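test_that("half-life ratio categories partition (0, 1] at 0.5 and 0.8", {
  expect_equal(halfLifeRatio(10, 10), list(ratio = 1, category = "similar"))
  expect_equal(halfLifeRatio(40, 50),
               list(ratio = 0.8, category = "similar"))
  expect_equal(halfLifeRatio(20, 100),
               list(ratio = 0.2, category = "very_different"))
  expect_equal(halfLifeRatio(50, 100)$category, "different")  # exactly 0.5
  # exhaustive boundary sweep: every ratio lands in exactly one category
  for (r in seq(0.01, 1, by = 0.01)) {
    cat <- halfLifeRatio(r, 1)$category
    want <- if (r >= 0.8) "similar" else if (r >= 0.5) "different" else
      "very_different"
    expect_equal(cat, want)
  }
  expect_error(halfLifeRatio(-1, 5), class = "degronon_input_error")
})

test_that("network constructor enforces canonical simple graphs", {
  expect_error(PpiNetwork("a", "a"), "self-loops")
  expect_error(PpiNetwork(c("a", "b"), c("b", "a")), "duplicate")
  net <- PpiNetwork(c("b", "a"), c("a", "c"), strict = FALSE)
  expect_equal(networkEdges(net)$a, c("a", "a"))
  expect_equal(networkNodes(net), c("a", "b", "c"))
})

test_that("randomization preserves degrees, shares no original edge", {
  cfg <- tinyConfig()
  net <- simulateCodegradationNetwork(cfg)$network
  degOrig <- sort(igraph::degree(asIgraph(net)))
  orig <- paste(networkEdges(net)$a, networkEdges(net)$b)
  for (sd in 1:3) {
    res <- randomizeNetwork(net, seed = sd)
    rnd <- res$network
    expect_equal(res$diagnostics$residual_original_overlap, 0)
    expect_false(any(paste(networkEdges(rnd)$a, networkEdges(rnd)$b) %in%
                       orig))
    expect_equal(nrow(networkEdges(rnd)) + res$diagnostics$n_removed_step3,
                 nrow(networkEdges(net)))
    # node set preserved; degree multiset preserved before pruning
    expect_true(all(networkNodes(rnd) %in% networkNodes(net)))
    expect_true(res$diagnostics$degree_multiset_preserved)
  }
  # determinism
  r1 <- randomizeNetwork(net, seed = 9)
  r2 <- randomizeNetwork(net, seed = 9)
  expect_identical(networkEdges(r1$network), networkEdges(r2$network))
  expect_false(identical(networkEdges(r1$network),
                         networkEdges(randomizeNetwork(net, 10)$network)))
})

test_that("pair records match a hand count on a toy six-edge network", {
  net <- PpiNetwork(c("a", "a", "b", "c", "d", "e"),
                    c("b", "c", "c", "d", "e", "f"))
  hl <- HalfLifeTable(c(a = 100, b = 95, c = 60, d = 20, e = 100, f = 12))
  res <- buildPairRecords(net, hl)
  # hand categories: ab .95 sim, ac .6 diff, bc .63 diff, cd .33 vd,
  # de .2 vd, ef .12 vd
  expect_equal(as.integer(res$groupSizes), c(3L, 2L, 1L))
  expect_equal(names(res$groupSizes),
               c("very_different", "different", "similar"))
  expect_equal(res$pairs$half_life_ratio[res$pairs$a == "a" &
                                           res$pairs$b == "b"], 0.95)
})

test_that("edges missing a half-life drop from ratio analyses", {
  net <- PpiNetwork(c("a", "b"), c("b", "c"))
  hl <- HalfLifeTable(c(a = 10, b = 12))
  res <- buildPairRecords(net, hl)
  expect_equal(nrow(res$pairs), 1L)
  expect_equal(res$pairs$a, "a")
})

test_that("absent annotations give NA fields but keep the pair", {
  net <- PpiNetwork("a", "b")
  hl <- HalfLifeTable(c(a = 10, b = 10))
  sem <- data.frame(a = "a", b = "b", semsim = 0.9)
  res <- buildPairRecords(net, hl, semsim = sem)
  expect_equal(res$pairs$semsim, 0.9)
  expect_true(is.na(res$pairs$coexpression))
})

test_that("uniform half-lives put all ratio mass at 1.0", {
  cfg <- tinyConfig()
  net <- simulateCodegradationNetwork(cfg)$network
  hl <- HalfLifeTable(setNames(rep(5, length(networkNodes(net))),
                               networkNodes(net)))
  dist <- ratioDistributionVsRandom(net, hl, nRandom = 2, seed = 3)
  expect_equal(dist$observed[10], 1)
  expect_equal(sum(dist$observed[1:9]), 0)
})

test_that("distance-1 profile equals the edge pair records", {
  cfg <- tinyConfig(seed = 14)
  sim <- simulateCodegradationNetwork(cfg)
  prof <- shortestPathRatioProfile(sim$network, sim$halflives)
  pr <- buildPairRecords(sim$network, sim$halflives)
  expect_equal(sort(prof$ratios[["1"]]), sort(pr$pairs$half_life_ratio))
})

test_that("star graphs put all leaf pairs at distance two", {
  net <- PpiNetwork(rep("hub", 5), paste0("leaf", 1:5))
  hl <- HalfLifeTable(setNames(runif(6, 10, 20),
                               c("hub", paste0("leaf", 1:5))))
  prof <- shortestPathRatioProfile(net, hl)
  expect_length(prof$ratios[["1"]], 5L)
  expect_length(prof$ratios[["2"]], choose(5, 2))
  expect_length(prof$ratios[["3"]], 0L)
})

test_that("within-module direct pairs out-correlate distant pairs", {
  cfg <- tinyConfig(seed = 15)
  sim <- simulateCodegradationNetwork(cfg)
  prof <- shortestPathRatioProfile(sim$network, sim$halflives)
  expect_gt(median(prof$ratios[["1"]]),
            median(unlist(prof$ratios[c("3", "4", "5", ">=6")])))
})

test_that("half-life shows no degree correlation unless constructed", {
  cfg <- synthConfig(seed = 16, n_modules = 1, module_size = 2,
                     n_background = 400)
  sim <- simulateCodegradationNetwork(cfg)
  res <- degreeHalflifeCorrelation(sim$network, sim$halflives)
  expect_lt(abs(res$degree$r), 0.15)
  # constructed: half-life equal to degree (identical tie pattern) gives
  # a perfect monotone rank correlation
  g <- asIgraph(sim$network)
  hl2 <- HalfLifeTable(igraph::degree(g))
  res2 <- degreeHalflifeCorrelation(sim$network, hl2)
  expect_equal(res2$degree$r, 1)
})

test_that("mean partner abundance matches a manual average on a toy graph", {
  net <- PpiNetwork(c("a", "a", "b"), c("b", "c", "c"))
  hl <- HalfLifeTable(c(a = 10, b = 12, c = 14))
  ab <- c(a = 100, b = 200, c = 300)
  res <- degreeHalflifeCorrelation(net, hl, abundances = ab)
  mpa <- res$partnerAbundance$meanPartnerAbundance
  expect_equal(unname(mpa["a"]), mean(c(200, 300)))
  expect_equal(unname(mpa["b"]), mean(c(100, 300)))
  expect_equal(unname(mpa["c"]), mean(c(100, 200)))
})
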