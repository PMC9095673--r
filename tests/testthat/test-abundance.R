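test_that("synthetic datasets sum to one million within tolerance one", {
  cfg <- tinyConfig()
  roles <- c(S1 = "substrate", E1 = "e3", A1 = "ap", A2 = "ap")
  datasets <- simulateAbundanceDatasets(cfg, roles)
  expect_length(datasets, cfg$n_datasets)
  for (ds in datasets)
    expect_lt(abs(sum(abundances(ds)) - 1e6), 1)
})

test_that("role medians order E3 < substrate < AP with a ~10-fold AP:E3 gap", {
  cfg <- synthConfig(seed = 2, n_datasets = 50, n_filler = 100)
  roles <- c(setNames(rep("substrate", 20), sprintf("S%02d", 1:20)),
             setNames(rep("e3", 20), sprintf("E%02d", 1:20)),
             setNames(rep("ap", 60), sprintf("A%02d", 1:60)))
  datasets <- simulateAbundanceDatasets(cfg, roles)
  modules <- lapply(1:20, function(i)
    regulatoryModule(sprintf("S%02d", i), sprintf("E%02d", i),
                     sprintf("A%02d", (3 * i - 2):(3 * i))))
  comp <- roleAbundanceComparison(datasets, modules)
  expect_true(comp$medians[["e3"]] < comp$medians[["substrate"]])
  expect_true(comp$medians[["substrate"]] < comp$medians[["ap"]])
  fold <- comp$medians[["ap"]] / comp$medians[["e3"]]
  expect_gte(fold, 5); expect_lte(fold, 20)
  p <- setNames(comp$tests$p, comp$tests$comparison)
  expect_lt(p[["e3_vs_ap"]], 1e-6)
  expect_lt(p[["e3_vs_substrate"]], 1e-6)
})

test_that("per-module pooling counts shared proteins once per module", {
  ds <- suppressWarnings(AbundanceDataset(
    "d1", c(S1 = 1e5, S2 = 1e5, K1 = 2e5, E1 = 1e5, E2 = 4e5)))
  mods <- list(regulatoryModule("S1", "E1", "K1"),
               regulatoryModule("S2", "E2", "K1"))   # K1 is AP twice
  per <- roleAbundanceComparison(list(ds), mods, poolPerModule = TRUE)
  once <- roleAbundanceComparison(list(ds), mods, poolPerModule = FALSE)
  expect_equal(per$n[["ap"]], 2L)
  expect_equal(once$n[["ap"]], 1L)
})

test_that("correlations hit +/- 1 on monotone pairs and handle ties", {
  mkds <- function(i, s, e) suppressWarnings(
    AbundanceDataset(paste0("d", i), c(S = s, E = e)))
  mods <- list(regulatoryModule("S", "E", "A"))
  up <- lapply(1:5, function(i) mkds(i, i * 10, i * 20))
  expect_equal(substratePartnerCorrelation(mods, up, "per_e3")$r, 1)
  down <- lapply(1:5, function(i) mkds(i, i * 10, 100 - i * 10))
  expect_equal(substratePartnerCorrelation(mods, down, "per_e3")$r, -1)
  # 5-point table with one tie in y: hand-computed average-rank Spearman
  xs <- c(1, 2, 3, 4, 5); ys <- c(10, 20, 20, 40, 50)
  tied <- lapply(1:5, function(i) mkds(i, xs[i], ys[i]))
  got <- substratePartnerCorrelation(mods, tied, "per_e3")
  rx <- rank(xs); ry <- rank(ys)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$r, hand, tolerance = 1e-12)
  expect_equal(got$n, 5L)
})

test_that("summed-AP mode requires every AP present in the dataset", {
  mods <- list(regulatoryModule("S", "E", c("A1", "A2")))
  full <- suppressWarnings(AbundanceDataset(
    "d1", c(S = 1e5, A1 = 2e5, A2 = 7e5)))
  partial <- suppressWarnings(AbundanceDataset(
    "d2", c(S = 1e5, A1 = 9e5)))
  res <- substratePartnerCorrelation(mods, list(full, partial),
                                     "summed_aps")
  expect_equal(res$n, 1L)
  expect_equal(res$points$y, 9e5)
  expect_true(is.na(res$r))   # fewer than 3 points: undefined
})

test_that("rank heatmap marks missing proteins and matches rankBins", {
  ds1 <- suppressWarnings(AbundanceDataset(
    "d1", setNames(c(5e5, 3e5, 2e5), c("S", "E", "A"))))
  ds2 <- suppressWarnings(AbundanceDataset(
    "d2", setNames(c(6e5, 4e5), c("S", "A"))))
  mods <- list(regulatoryModule("S", "E", "A"))
  heat <- moduleRankHeatmap(mods, list(ds1, ds2))
  expect_true(is.na(heat["E", "d2"]))
  expect_false(any(heat == 100, na.rm = TRUE))  # absent is NA, never bin 100
  b1 <- rankBins(ds1); b2 <- rankBins(ds2)
  expect_equal(heat["S", "d1"], b1[["S"]])
  expect_equal(heat["A", "d2"], b2[["A"]])
  expect_equal(rownames(heat), c("S", "E", "A"))
})

test_that("ppm and rank-bin comparisons agree in direction", {
  cfg <- tinyConfig(seed = 6)
  roles <- c(setNames(rep("substrate", 5), sprintf("S%d", 1:5)),
             setNames(rep("e3", 5), sprintf("E%d", 1:5)),
             setNames(rep("ap", 5), sprintf("A%d", 1:5)))
  datasets <- simulateAbundanceDatasets(cfg, roles)
  pooledPpm <- list(e3 = numeric(), ap = numeric())
  pooledBin <- list(e3 = numeric(), ap = numeric())
  for (ds in datasets) {
    ab <- abundances(ds); bins <- rankBins(ds)
    for (role in c("e3", "ap")) {
      ids <- intersect(names(roles)[roles == role], names(ab))
      pooledPpm[[role]] <- c(pooledPpm[[role]], ab[ids])
      pooledBin[[role]] <- c(pooledBin[[role]], bins[ids])
    }
  }
  # higher ppm = lower bin: the two views must point the same way
  expect_gt(median(pooledPpm$ap), median(pooledPpm$e3))
  expect_lt(median(pooledBin$ap), median(pooledBin$e3))
})
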