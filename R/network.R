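## Network co-degradation: half-life ratio statistics on interaction
## networks, degree-preserving randomization, shortest-path profiles and
## degronon detection.

#' Half-life ratio and similarity category of a protein pair
#'
#' The ratio is min/max of the two half-lives (both from the same dataset),
#' so it lies in (0, 1\]. Categories: very different \[0, 0.5), different
#' \[0.5, 0.8), similar \[0.8, 1.0\]; a ratio landing exactly on a boundary
#' goes to the upper category.
#'
#' @param t1,t2 positive half-lives from one [HalfLifeTable-class].
#' @return list with `ratio` and `category`.
#' @examples
#' halfLifeRatio(40, 50)   # 0.8, similar
#' halfLifeRatio(20, 100)  # 0.2, very_different
#' @export
halfLifeRatio <- function(t1, t2) {
  if (!is.finite(t1) || !is.finite(t2) || t1 <= 0 || t2 <= 0)
    stopInput("half-lives must be positive (got %s, %s)", t1, t2)
  ratio <- min(t1, t2) / max(t1, t2)
  list(ratio = ratio, category = .ratioCategory(ratio))
}

.ratioCategory <- function(ratio) {
  ifelse(ratio >= 0.8, "similar",
         ifelse(ratio >= 0.5, "different", "very_different"))
}

#' Degree-preserving randomization of a PPI network
#'
#' Three-step null-model construction: (1) shuffle edges with a
#' degree-preserving generator that forbids self-loops and multi-edges
#' (igraph's `sample_degseq`); (2) permute node labels by sampling without
#' replacement; (3) delete any remaining edges that also occur in the
#' original network, so the result shares no edge with the input.
#' The node set and the degree multiset are preserved exactly by steps
#' 1-2; step 3 removes typically well under 1% of edges on sparse graphs.
#'
#' @param net a [PpiNetwork-class] object.
#' @param seed integer seed; the same seed reproduces the same network.
#' @param maxRetries bounded retries when the degree-sequence sampler
#'   fails (default 20).
#' @return list with `network` (the randomized [PpiNetwork-class]) and
#'   `diagnostics` (`n_edges_input`, `n_removed_step3`,
#'   `residual_original_overlap` -- always 0,
#'   `degree_multiset_preserved` -- the steps-1-2 contract, checked
#'   empirically, `seed`).
#' @export
randomizeNetwork <- function(net, seed, maxRetries = 20) {
  nodes <- networkNodes(net)
  ed <- networkEdges(net)
  origKey <- paste(ed$a, ed$b, sep = "\r")
  g <- asIgraph(net)
  deg <- igraph::degree(g)
  withStream(seed, "randomize", {
    g2 <- NULL
    for (i in seq_len(maxRetries)) {
      g2 <- tryCatch(
        igraph::sample_degseq(unname(deg), method = "fast.heur.simple"),
        error = function(e) NULL)
      if (!is.null(g2)) break
    }
    if (is.null(g2))
      stopInternal("degree-preserving shuffle failed after %d retries (seed %d)",
                   maxRetries, seed)
    ## step 2: node-label permutation (without replacement)
    labels <- sample(names(deg))
    el <- igraph::as_edgelist(g2, names = FALSE)
    a <- labels[el[, 1]]; b <- labels[el[, 2]]
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(lo, hi, sep = "\r")
    ## step 3: drop edges also present in the original network
    keep <- !(key %in% origKey)
    out <- new("PpiNetwork",
               edges = {
                 df <- data.frame(a = lo[keep], b = hi[keep],
                                  stringsAsFactors = FALSE)
                 df <- df[order(df$a, df$b), , drop = FALSE]
                 rownames(df) <- NULL
                 df
               })
    residual <- sum(paste(out@edges$a, out@edges$b, sep = "\r") %in% origKey)
    preDeg <- sort(as.integer(table(factor(c(lo, hi), levels = nodes))))
    list(network = out,
         diagnostics = list(n_edges_input = nrow(ed),
                            n_removed_step3 = sum(!keep),
                            residual_original_overlap = residual,
                            degree_multiset_preserved =
                              identical(preDeg,
                                        sort(as.integer(unname(deg)))),
                            seed = seed))
  })
}

#' Build pairwise property records for every network edge
#'
#' One record per edge whose two proteins both have half-lives in the
#' table; the record carries the half-life ratio and its category, plus
#' semantic similarity, co-expression and abundance ratio where available
#' (absent annotations give `NA`; such pairs stay in ratio analyses but
#' drop out of the specific property grouping).
#'
#' @param net a [PpiNetwork-class] object.
#' @param halflives a [HalfLifeTable-class] object.
#' @param semsim optional pair table `data.frame(a, b, semsim)` (unordered
#'   pairs) or a `function(g1, g2)`.
#' @param coexpression optional pair table `data.frame(a, b, r)` or
#'   function, Pearson correlation of expression profiles.
#' @param abundances optional named ppm vector or
#'   [AbundanceDataset-class]; contributes `abundance_ratio` (min/max).
#' @return list with `pairs` (the record data.frame) and `groupSizes`
#'   (category counts).
#' @export
buildPairRecords <- function(net, halflives, semsim = NULL,
                             coexpression = NULL, abundances = NULL) {
  ed <- networkEdges(net)
  hl <- halfLives(halflives)
  both <- ed$a %in% names(hl) & ed$b %in% names(hl)
  ed <- ed[both, , drop = FALSE]
  t1 <- hl[ed$a]; t2 <- hl[ed$b]
  ratio <- pmin(t1, t2) / pmax(t1, t2)
  semLookup <- .pairLookup(semsim, valueCol = "semsim")
  coxLookup <- .pairLookup(coexpression, valueCol = "r")
  ab <- if (is(abundances, "AbundanceDataset")) abundances(abundances) else
    abundances
  abRatio <- if (is.null(ab)) rep(NA_real_, nrow(ed)) else {
    a1 <- ab[ed$a]; a2 <- ab[ed$b]
    unname(pmin(a1, a2) / pmax(a1, a2))
  }
  pairs <- data.frame(
    a = ed$a, b = ed$b,
    half_life_ratio = unname(ratio),
    category = .ratioCategory(unname(ratio)),
    semsim = semLookup(ed$a, ed$b),
    coexpression = coxLookup(ed$a, ed$b),
    abundance_ratio = abRatio,
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  sizes <- table(factor(pairs$category,
                        c("very_different", "different", "similar")))
  list(pairs = pairs, groupSizes = sizes)
}

## normalize a pair annotation source (data.frame, function, or NULL) to a
## vectorized lookup over (a, b)
.pairLookup <- function(src, valueCol) {
  if (is.null(src))
    return(function(a, b) rep(NA_real_, length(a)))
  if (is.function(src))
    return(function(a, b) mapply(function(x, y) {
      v <- src(x, y); if (is.null(v)) NA_real_ else as.numeric(v)
    }, a, b, USE.NAMES = FALSE))
  if (is.data.frame(src)) {
    cols <- names(src)
    vc <- if (valueCol %in% cols) valueCol else cols[[3L]]
    lo <- pmin(src[[1L]], src[[2L]]); hi <- pmax(src[[1L]], src[[2L]])
    key <- paste(lo, hi, sep = "\r")
    vals <- setNames(src[[vc]], key)
    return(function(a, b) {
      unname(vals[paste(pmin(a, b), pmax(a, b), sep = "\r")])
    })
  }
  stopInput("unsupported pair annotation source")
}

#' Edge half-life ratio distribution against randomized networks
#'
#' Histograms the half-life ratios of real network edges and of the edges
#' of `nRandom` degree-preserving randomized networks, returning the
#' per-bin mean +/- 1 sd envelope across the random networks, along with
#' similarity-category fractions (observed vs random envelope).
#'
#' @param net a [PpiNetwork-class] object.
#' @param halflives a [HalfLifeTable-class] object.
#' @param nRandom number of random networks (default 10).
#' @param seed integer; random network i uses `seed + i`.
#' @param breaks histogram breaks over (0, 1\] (default 10 bins of 0.1).
#' @return list with `breaks`, `observed` (per-bin proportions),
#'   `randomMean`, `randomSd`, `categoryFractions` (observed),
#'   `randomCategoryMean`, `randomCategorySd`, and `nPairs`.
#' @export
ratioDistributionVsRandom <- function(net, halflives, nRandom = 10, seed = 1,
                                      breaks = seq(0, 1, by = 0.1)) {
  binProps <- function(network) {
    pr <- buildPairRecords(network, halflives)$pairs
    cnt <- tabulate(cut(pr$half_life_ratio, breaks, labels = FALSE,
                        include.lowest = TRUE),
                    nbins = length(breaks) - 1L)
    list(props = cnt / max(1L, length(pr$half_life_ratio)),
         cats = as.numeric(table(factor(pr$category,
                                        c("very_different", "different",
                                          "similar")))) /
           max(1L, nrow(pr)))
  }
  obs <- binProps(net)
  rnd <- lapply(seq_len(nRandom), function(i)
    binProps(randomizeNetwork(net, seed + i)$network))
  propMat <- do.call(rbind, lapply(rnd, `[[`, "props"))
  catMat <- do.call(rbind, lapply(rnd, `[[`, "cats"))
  catNames <- c("very_different", "different", "similar")
  list(breaks = breaks,
       observed = obs$props,
       randomMean = colMeans(propMat),
       randomSd = apply(propMat, 2, sd),
       categoryFractions = setNames(obs$cats, catNames),
       randomCategoryMean = setNames(colMeans(catMat), catNames),
       randomCategorySd = setNames(apply(catMat, 2, sd), catNames),
       nPairs = sum(networkEdges(net)$a %in% names(halfLives(halflives)) &
                      networkEdges(net)$b %in% names(halfLives(halflives))))
}

#' Half-life ratios as a function of network distance
#'
#' Buckets every unordered, mutually reachable node pair by its
#' shortest-path distance (1, 2, ..., maxLen-1, >= maxLen) and collects
#' the half-life ratio per pair. The distance-1 bucket equals the edge
#' pair-record ratios.
#'
#' @param net a [PpiNetwork-class] object.
#' @param halflives a [HalfLifeTable-class] object.
#' @param maxLen distances >= `maxLen` are pooled (default 6).
#' @return list with `ratios` (named list of numeric vectors per distance
#'   label) and `medians`.
#' @export
shortestPathRatioProfile <- function(net, halflives, maxLen = 6) {
  hl <- halfLives(halflives)
  g <- asIgraph(net)
  nodes <- intersect(networkNodes(net), names(hl))
  d <- igraph::distances(g, v = nodes, to = nodes)
  labels <- c(as.character(seq_len(maxLen - 1)), paste0(">=", maxLen))
  ratios <- setNames(vector("list", length(labels)), labels)
  iu <- which(upper.tri(d) & is.finite(d) & d >= 1, arr.ind = TRUE)
  if (nrow(iu)) {
    t1 <- hl[nodes[iu[, 1]]]; t2 <- hl[nodes[iu[, 2]]]
    rr <- unname(pmin(t1, t2) / pmax(t1, t2))
    dist <- pmin(d[iu], maxLen)
    lab <- ifelse(dist >= maxLen, paste0(">=", maxLen), as.character(dist))
    sp <- split(rr, lab)
    for (nm in names(sp)) ratios[[nm]] <- sp[[nm]]
  }
  for (nm in labels) if (is.null(ratios[[nm]])) ratios[[nm]] <- numeric()
  list(ratios = ratios,
       medians = vapply(ratios, function(v) if (length(v)) median(v) else
         NA_real_, 1))
}

## Deterministic BFS parents from one source: neighbors are expanded in
## lexicographic order, so each node's parent is the lexicographically
## smallest next-node choice and the induced shortest path is unique.
.bfsParents <- function(adj, sourceIdx, n) {
  parent <- integer(n)     # 0 = unvisited
  depth <- rep(NA_integer_, n)
  parent[sourceIdx] <- -1L
  depth[sourceIdx] <- 0L
  queue <- integer(n); qh <- 1L; qt <- 1L
  queue[qt] <- sourceIdx
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    for (w in adj[[v]]) {
      if (parent[w] == 0L) {
        parent[w] <- v
        depth[w] <- depth[v] + 1L
        qt <- qt + 1L
        queue[qt] <- w
      }
    }
  }
  list(parent = parent, depth = depth)
}

#' Detect degronons: functionally coherent, half-life-correlated paths
#'
#' Enumerates one deterministic shortest path per ordered node pair (BFS
#' expanding neighbors in lexicographic order) and retains paths in which
#' every member has semantic similarity >= `cutoff` to the first (source)
#' protein. Paths containing a member with no similarity data are excluded
#' from the high-similarity subset (not treated as failing). Retained
#' paths of length >= `minLength` hops are the degronons; paths identical
#' as ordered member lists are deduplicated, and the count after also
#' merging reverse duplicates is reported.
#'
#' @param net a [PpiNetwork-class] object.
#' @param halflives a [HalfLifeTable-class] object.
#' @param semsim similarity source: pair table `data.frame(a, b, semsim)`
#'   or `function(g1, g2)` (e.g. [makeGeneSimilarity()]).
#' @param cutoff similarity threshold (default 0.6, strict `>=`).
#' @param minLength minimum degronon path length in hops (default 6).
#' @param maxLen pooling bound for the per-length ratio report (default 6).
#' @return list with
#'   \describe{
#'     \item{degronons}{list of degronons; each has `members` (ordered),
#'       `length` (hops), `semsimToFirst`, `ratioToFirst`.}
#'     \item{allPathRatios, highSemsimRatios}{named lists of first-vs-member
#'       half-life ratios per path-length bin (1 .. >=maxLen), over all
#'       ordered paths and the high-similarity subset.}
#'     \item{nOrderedPaths, nReverseDeduped}{degronon counts before/after
#'       merging reverse duplicates.}
#'   }
#' @export
detectDegronons <- function(net, halflives, semsim, cutoff = 0.6,
                            minLength = 6, maxLen = 6) {
  hl <- halfLives(halflives)
  nodes <- networkNodes(net)          # sorted: index order = lexicographic
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  ed <- networkEdges(net)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  ai <- idx[ed$a]; bi <- idx[ed$b]
  for (k in seq_along(ai)) {
    adj[[ai[k]]] <- c(adj[[ai[k]]], bi[k])
    adj[[bi[k]]] <- c(adj[[bi[k]]], ai[k])
  }
  adj <- lapply(adj, sort)

  simFun <- if (is.function(semsim)) semsim else {
    lk <- .pairLookup(semsim, "semsim")
    function(a, b) lk(a, b)
  }
  simCache <- new.env(parent = emptyenv())
  simOK <- function(a, b) {
    key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    v <- simCache[[key]]
    if (is.null(v)) {
      s <- simFun(a, b)
      v <- !is.na(s) && is.finite(s) && s >= cutoff
      simCache[[key]] <- v
    }
    v
  }

  labels <- c(as.character(seq_len(maxLen - 1)), paste0(">=", maxLen))
  binOf <- function(dep) as.integer(if (dep >= maxLen) maxLen else dep)
  allR <- lapply(seq_len(maxLen), function(i) numeric())
  highR <- lapply(seq_len(maxLen), function(i) numeric())
  degronons <- list()

  for (s in seq_len(n)) {
    src <- nodes[[s]]
    if (!src %in% names(hl)) next
    bfs <- .bfsParents(adj, s, n)
    reach <- which(!is.na(bfs$depth) & bfs$depth >= 1L)
    if (!length(reach)) next
    ## all-paths report: ratio(first, target) by depth
    tHl <- hl[nodes[reach]]
    okT <- !is.na(tHl)
    rr <- unname(pmin(hl[[src]], tHl[okT]) / pmax(hl[[src]], tHl[okT]))
    dd <- vapply(bfs$depth[reach][okT], binOf, 1L)
    for (b in unique(dd))
      allR[[b]] <- c(allR[[b]], rr[dd == b])
    ## high-semsim subset: walk the BFS tree, pruning at the first member
    ## that fails (or lacks) similarity to the source
    children <- split(seq_len(n)[bfs$parent > 0L],
                      bfs$parent[bfs$parent > 0L])
    stack <- list(list(node = s, path = s))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      v <- top$node
      if (v != s && !simOK(src, nodes[[v]])) next
      if (v != s) {
        tv <- hl[nodes[[v]]]
        dep <- bfs$depth[[v]]
        if (!is.na(tv)) {
          b <- binOf(dep)
          highR[[b]] <- c(highR[[b]],
                          unname(pmin(hl[[src]], tv) / pmax(hl[[src]], tv)))
        }
        if (dep >= minLength) {
          members <- nodes[top$path]
          degronons[[length(degronons) + 1L]] <- list(
            members = members,
            length = dep,
            semsimToFirst = vapply(members[-1], function(m) {
              v <- simFun(src, m); if (is.null(v)) NA_real_ else
                as.numeric(v)
            }, 1),
            ratioToFirst = unname(pmin(hl[[src]], hl[members[-1]]) /
                                    pmax(hl[[src]], hl[members[-1]])))
        }
      }
      for (w in children[[as.character(v)]])
        stack[[length(stack) + 1L]] <- list(node = w, path = c(top$path, w))
    }
  }
  names(allR) <- labels
  names(highR) <- labels
  keyFwd <- vapply(degronons, function(d) paste(d$members, collapse = "|"),
                   "")
  degronons <- degronons[!duplicated(keyFwd)]
  keyFwd <- keyFwd[!duplicated(keyFwd)]
  keyBoth <- vapply(degronons, function(d) {
    m <- d$members
    if (m[[1L]] <= m[[length(m)]]) paste(m, collapse = "|") else
      paste(rev(m), collapse = "|")
  }, "")
  list(degronons = degronons,
       allPathRatios = allR,
       highSemsimRatios = highR,
       nOrderedPaths = length(degronons),
       nReverseDeduped = length(unique(keyBoth)))
}

#' Half-life vs degree and vs mean partner abundance
#'
#' Spearman correlations of each protein's half-life against its number of
#' interaction partners, and against the mean abundance of its partners.
#' An absence of correlation indicates that stabilization is not a generic
#' consequence of being highly connected.
#'
#' @param net a [PpiNetwork-class] object.
#' @param halflives a [HalfLifeTable-class] object.
#' @param abundances optional named ppm vector or
#'   [AbundanceDataset-class] for the partner-abundance correlation.
#' @return list with `degree` (`r`, `p`, `n`) and, when abundances are
#'   given, `partnerAbundance` (`r`, `p`, `n`, and the per-node
#'   `meanPartnerAbundance` vector).
#' @export
degreeHalflifeCorrelation <- function(net, halflives, abundances = NULL) {
  hl <- halfLives(halflives)
  g <- asIgraph(net)
  nodes <- intersect(networkNodes(net), names(hl))
  deg <- igraph::degree(g)[nodes]
  spear <- function(x, y) {
    if (length(x) < 3) return(list(r = NA_real_, p = NA_real_,
                                   n = length(x)))
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
  }
  out <- list(degree = spear(hl[nodes], unname(deg)))
  ab <- if (is(abundances, "AbundanceDataset")) abundances(abundances) else
    abundances
  if (!is.null(ab)) {
    adjList <- igraph::adjacent_vertices(g, v = nodes)
    mpa <- vapply(adjList, function(vs) {
      vals <- ab[names(vs)]
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }, 1)
    names(mpa) <- nodes
    ok <- !is.na(mpa)
    res <- spear(hl[nodes][ok], unname(mpa[ok]))
    res$meanPartnerAbundance <- mpa
    out$partnerAbundance <- res
  }
  out
}
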