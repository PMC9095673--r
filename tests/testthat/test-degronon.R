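chainNet <- function(n = 8, prefix = "n") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  PpiNetwork(ids[-n], ids[-1])
}

test_that("a planted chain with perfect similarity is detected intact", {
  net <- chainNet(8)
  ids <- networkNodes(net)
  hl <- HalfLifeTable(setNames(rep(30, 8), ids))
  sem <- function(a, b) 1
  res <- detectDegronons(net, hl, sem, cutoff = 0.6, minLength = 6)
  lens <- vapply(res$degronons, `[[`, 1L, "length")
  expect_true(any(lens == 7))
  full <- res$degronons[[which(lens == 7)[1]]]
  expect_equal(sort(full$members), sort(ids))
  expect_true(all(full$ratioToFirst == 1))
  # reverse paths collapse under reverse-deduplication
  expect_lt(res$nReverseDeduped, res$nOrderedPaths)
})

test_that("one member below the similarity cutoff excludes the path", {
  net <- chainNet(8)
  ids <- networkNodes(net)
  hl <- HalfLifeTable(setNames(rep(30, 8), ids))
  sem <- function(a, b) if ("n04" %in% c(a, b)) 0.59 else 1
  res <- detectDegronons(net, hl, sem, cutoff = 0.6, minLength = 6)
  # every surviving path must avoid n04, and no 6+ path can
  expect_length(res$degronons, 0L)
  # strictness: exactly 0.6 passes
  sem2 <- function(a, b) if ("n04" %in% c(a, b)) 0.6 else 1
  res2 <- detectDegronons(net, hl, sem2, cutoff = 0.6, minLength = 6)
  expect_gt(length(res2$degronons), 0L)
})

test_that("members with missing similarity data exclude the path quietly", {
  net <- chainNet(8)
  ids <- networkNodes(net)
  hl <- HalfLifeTable(setNames(rep(30, 8), ids))
  sem <- function(a, b) if ("n04" %in% c(a, b)) NA_real_ else 1
  res <- detectDegronons(net, hl, sem, cutoff = 0.6, minLength = 6)
  expect_length(res$degronons, 0L)
})

test_that("planted module membership is recovered exactly on synthetic data", {
  cfg <- tinyConfig(seed = 19)
  sim <- simulateCodegradationNetwork(cfg)
  goa <- simulateGoAnnotations(cfg)
  ann <- filterAnnotations(goa$gaf, goa$dag)
  res <- detectDegronons(sim$network, sim$halflives,
                         makeGeneSimilarity(ann, goa$dag))
  det <- unique(unlist(lapply(res$degronons, `[[`, "members")))
  planted <- unique(unlist(sim$truth$plantedPaths))
  expect_gte(mean(planted %in% det), 0.9)   # recall
  expect_gte(mean(det %in% planted), 0.8)   # precision
})

test_that("deterministic tie-break picks the lexicographically smaller path", {
  # two equal-length routes a -> d: via b and via c; BFS must take b
  net <- PpiNetwork(c("a", "a", "b", "c"), c("b", "c", "d", "d"))
  hl <- HalfLifeTable(setNames(rep(10, 4), c("a", "b", "c", "d")))
  res <- detectDegronons(net, hl, function(a, b) 1, minLength = 2)
  paths <- vapply(res$degronons, function(d) paste(d$members,
                                                   collapse = "-"), "")
  expect_true("a-b-d" %in% paths)
  expect_false("a-c-d" %in% paths)
})
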