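## Abundance competition: rank-bin conversion of ppm datasets, role-wise
## comparisons (substrates vs E3 ligases vs alternate partners), pairwise
## abundance correlations and the module rank heatmap.

#' Convert a ppm dataset into 100 equally populated rank bins
#'
#' Proteins are sorted from highest to lowest ppm (ties broken by
#' descending ppm then lexicographic protein id, so the assignment is
#' deterministic) and mapped onto a 100-bin grid:
#' `bin = 1 + floor(100 * (rank - 1) / N)`. Bin 1 holds the most abundant
#' proteins (the top 1% in a full-size dataset); occupancies never differ
#' by more than one, and the top-ranked protein lands in bin 1 for every
#' dataset size.
#'
#' @param ds an [AbundanceDataset-class] object.
#' @return named integer vector, protein -> bin in 1..100.
#' @export
rankBins <- function(ds) {
  ab <- abundances(ds)
  n <- length(ab)
  if (n == 0) stopInput("dataset %s is empty", datasetId(ds))
  ord <- order(-ab, names(ab))
  bins <- 1L + as.integer(floor(100 * (seq_len(n) - 1) / n))
  setNames(bins, names(ab)[ord])[names(ab)]
}

#' Define a degradation regulatory module
#'
#' A substrate together with its E3 ligase(s) (or adaptor subunits) and the
#' degron-masking alternate partners (APs) recruited to degron-overlapping
#' sites. The three sets must be pairwise disjoint.
#'
#' @param substrate substrate identifier.
#' @param e3s character vector of E3 (or adaptor) identifiers.
#' @param aps character vector of alternate-partner identifiers.
#' @return a classed list (`degronon_module`).
#' @export
regulatoryModule <- function(substrate, e3s, aps) {
  e3s <- unique(as.character(e3s)); aps <- unique(as.character(aps))
  substrate <- as.character(substrate)
  if (substrate %in% e3s || substrate %in% aps || length(intersect(e3s, aps)))
    stopInput("substrate, e3s and aps must be pairwise disjoint (module %s)",
              substrate)
  structure(list(substrate = substrate, e3s = e3s, aps = aps),
            class = "degronon_module")
}

#' Compare pooled abundances of substrates, E3s and alternate partners
#'
#' Pools ppm values per role across datasets: each (protein, dataset)
#' occurrence contributes one observation per module role occurrence (set
#' `poolPerModule = FALSE` to count a protein once per dataset even when it
#' serves the same role in several modules). Roles are compared pairwise
#' with the two-sided Mann-Whitney U-test.
#'
#' @param datasets list of [AbundanceDataset-class] objects.
#' @param modules list of [regulatoryModule()] definitions.
#' @param poolPerModule logical (default TRUE); see above.
#' @return list with `values` (named list of pooled ppm vectors per role),
#'   `n`, `medians`, and `tests` (data.frame comparison/U/p; roles with no
#'   data are reported absent and not tested).
#' @export
roleAbundanceComparison <- function(datasets, modules, poolPerModule = TRUE) {
  roster <- do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    data.frame(module = i,
               protein = c(m$substrate, m$e3s, m$aps),
               role = c("substrate", rep("e3", length(m$e3s)),
                        rep("ap", length(m$aps))),
               stringsAsFactors = FALSE)
  }))
  if (!poolPerModule)
    roster <- roster[!duplicated(paste(roster$protein, roster$role)), ,
                     drop = FALSE]
  values <- list(substrate = numeric(), e3 = numeric(), ap = numeric())
  for (ds in datasets) {
    ab <- abundances(ds)
    hit <- roster[roster$protein %in% names(ab), , drop = FALSE]
    for (role in names(values)) {
      v <- ab[hit$protein[hit$role == role]]
      values[[role]] <- c(values[[role]], unname(v))
    }
  }
  n <- vapply(values, length, 1L)
  medians <- vapply(values, function(v) if (length(v)) median(v) else
    NA_real_, 1)
  combos <- list(c("e3", "substrate"), c("e3", "ap"), c("substrate", "ap"))
  tests <- do.call(rbind, lapply(combos, function(cc) {
    x <- values[[cc[1]]]; y <- values[[cc[2]]]
    if (!length(x) || !length(y))
      return(data.frame(comparison = paste(cc, collapse = "_vs_"),
                        U = NA_real_, p = NA_real_))
    tt <- twoGroupTest(x, y)
    data.frame(comparison = paste(cc, collapse = "_vs_"), U = tt$U, p = tt$p)
  }))
  rownames(tests) <- NULL
  list(values = values, n = n, medians = medians, tests = tests)
}

#' Substrate-partner abundance correlation across datasets
#'
#' For `mode = "per_e3"`, each data point is one (substrate, E3) pair in
#' one dataset where both proteins were measured. For
#' `mode = "summed_aps"`, each point is a substrate's ppm against the sum
#' of all its alternate partners' ppm, only in datasets where every AP of
#' that substrate was measured. Association is Spearman's rank correlation
#' (average ranks for ties, large-sample P).
#'
#' @param modules list of [regulatoryModule()] definitions.
#' @param datasets list of [AbundanceDataset-class] objects.
#' @param mode `"per_e3"` or `"summed_aps"`.
#' @return list with `r` (Spearman rho), `p`, `n`, and the point table
#'   `points` (substrate value `x`, partner value `y`); `r`/`p` are `NA`
#'   when fewer than 3 points exist.
#' @export
substratePartnerCorrelation <- function(modules, datasets,
                                        mode = c("per_e3", "summed_aps")) {
  mode <- match.arg(mode)
  pts <- list()
  for (ds in datasets) {
    ab <- abundances(ds)
    for (m in modules) {
      if (!m$substrate %in% names(ab)) next
      sx <- ab[[m$substrate]]
      if (mode == "per_e3") {
        for (e3 in m$e3s) {
          if (e3 %in% names(ab))
            pts[[length(pts) + 1L]] <- c(sx, ab[[e3]])
        }
      } else {
        if (length(m$aps) && all(m$aps %in% names(ab)))
          pts[[length(pts) + 1L]] <- c(sx, sum(ab[m$aps]))
      }
    }
  }
  points <- if (length(pts)) {
    as.data.frame(do.call(rbind, pts)) |> setNames(c("x", "y"))
  } else data.frame(x = numeric(), y = numeric())
  n <- nrow(points)
  if (n < 3)
    return(list(r = NA_real_, p = NA_real_, n = n, points = points))
  ct <- suppressWarnings(cor.test(points$x, points$y, method = "spearman",
                                  exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = n, points = points)
}

#' Rank-bin heatmap matrix for module components across datasets
#'
#' Builds the protein x dataset matrix of rank bins (1..100) underlying a
#' module-abundance heatmap. Cells for proteins missing from a dataset are
#' `NA` (explicit missing marker, never bin 100). Rows follow module
#' definition order (substrate, E3s, APs per module, first occurrence
#' kept); columns follow the dataset list order.
#'
#' @param modules list of [regulatoryModule()] definitions.
#' @param datasets list of [AbundanceDataset-class] objects.
#' @return integer matrix with protein rownames, dataset-id colnames and a
#'   `categories` attribute giving each dataset's category.
#' @export
moduleRankHeatmap <- function(modules, datasets) {
  proteins <- unique(unlist(lapply(modules, function(m)
    c(m$substrate, m$e3s, m$aps)), use.names = FALSE))
  ids <- vapply(datasets, datasetId, "")
  mat <- matrix(NA_integer_, length(proteins), length(datasets),
                dimnames = list(proteins, ids))
  for (j in seq_along(datasets)) {
    bins <- rankBins(datasets[[j]])
    hit <- intersect(proteins, names(bins))
    mat[hit, j] <- bins[hit]
  }
  attr(mat, "categories") <- vapply(datasets, datasetCategory, "")
  mat
}

#' Two-sided Mann-Whitney U-test
#'
#' Wraps [stats::wilcox.test()]: the exact two-sided P-value is used for
#' small samples (both groups <= 8, no ties), otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with `U` (the Mann-Whitney U statistic for `x`) and `p`.
#' @examples
#' twoGroupTest(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
twoGroupTest <- function(x, y) {
  if (!length(x) || !length(y)) stopInput("both groups must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopInput("non-finite values in input")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 8 && length(y) <= 8
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}
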