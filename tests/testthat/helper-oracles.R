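# Independent oracles used by the unit and acceptance tests. They share no
# code with the implementation paths they check.

# --- residue-set oracle for interval relations ------------------------------
# Represents each interval as a residue membership vector; overlap is set
# intersection, and adjacency at distance w is tested by dilating one set by
# w residues (a set operation realized as shifted ORs) and intersecting.

# all intervals (s <= e <= maxCoord) as a logical membership matrix, padded
# so dilation never clips
intervalMatrix <- function(maxCoord, pad = 15) {
  iv <- do.call(rbind, lapply(seq_len(maxCoord), function(s)
    cbind(s = s, e = s:maxCoord)))
  m <- matrix(FALSE, nrow(iv), maxCoord + pad)
  for (i in seq_len(nrow(iv))) m[i, iv[i, "s"]:iv[i, "e"]] <- TRUE
  list(intervals = iv, members = m)
}

dilateMembers <- function(m, w) {
  out <- m
  nc <- ncol(m)
  for (k in seq_len(w)) {
    out <- out |
      cbind(m[, -(1:k), drop = FALSE],
            matrix(FALSE, nrow(m), k)) |           # shift left by k
      cbind(matrix(FALSE, nrow(m), k),
            m[, seq_len(nc - k), drop = FALSE])    # shift right by k
  }
  out
}

# per-pair scalar oracle (residue sets, no interval arithmetic)
oracleRelation <- function(d, s, window = 10) {
  A <- d[1]:d[2]; B <- s[1]:s[2]
  ov <- length(intersect(A, B))
  if (ov > 0) return(list(relation = "overlap", overlap_length = ov,
                          gap = NA_integer_))
  gap <- min(abs(outer(A, B, "-"))) - 1L
  list(relation = if (gap <= window) "adjacent" else "none",
       overlap_length = 0L, gap = as.integer(gap))
}

# --- disorder-run scan oracle ----------------------------------------------
oracleTertiary <- function(profile, ubsite, minRun = 20, threshold = 0.5) {
  runs <- list()
  i <- 1L; n <- length(profile)
  while (i <= n) {
    if (profile[i] >= threshold) {
      j <- i
      while (j < n && profile[j + 1L] >= threshold) j <- j + 1L
      if (j - i + 1L >= minRun) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(NULL)
  best <- NULL; bestDist <- Inf
  for (r in runs) {
    d <- if (ubsite >= r[1] && ubsite <= r[2]) 0L else
      min(abs(r[1] - ubsite), abs(r[2] - ubsite))
    if (d < bestDist || (d == bestDist && r[1] < best[1])) {
      best <- r; bestDist <- d
    }
  }
  list(start = best[1], end = best[2])
}

# --- Wang measure: memo-free recursive path-product oracle ------------------
# S_t(a) = max over directed paths t -> a of the product of edge weights,
# found by exhaustive depth-first path enumeration (no memoization, no
# topological order).
oracleSValues <- function(term, dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  ed <- goEdges(dag)
  best <- new.env(parent = emptyenv())
  dfs <- function(node, val) {
    cur <- best[[node]]
    if (is.null(cur) || val > cur) best[[node]] <- val
    rows <- which(ed$child == node)
    for (k in rows) dfs(ed$parent[[k]], val * weights[[ed$relation[[k]]]])
  }
  dfs(term, 1)
  vals <- unlist(as.list(best))
  vals
}

oracleTermSim <- function(t1, t2, dag,
                          weights = c(is_a = 0.8, part_of = 0.6)) {
  s1 <- oracleSValues(t1, dag, weights)
  s2 <- oracleSValues(t2, dag, weights)
  common <- intersect(names(s1), names(s2))
  if (!length(common)) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# random DAG: term i attaches to 1-2 earlier terms; ~30% get two parents
randomDag <- function(nTerms, seed) {
  set.seed(seed)
  terms <- sprintf("T%02d", seq_len(nTerms))
  edges <- list()
  for (i in 2:nTerms) {
    nPar <- if (i > 2 && runif(1) < 0.3) 2L else 1L
    parents <- sample(seq_len(i - 1L), nPar)
    for (p in parents)
      edges[[length(edges) + 1L]] <- data.frame(
        child = terms[[i]], parent = terms[[p]],
        relation = sample(c("is_a", "part_of"), 1, prob = c(0.8, 0.2)),
        stringsAsFactors = FALSE)
  }
  new("GoDag", terms = terms,
      termNames = setNames(terms, terms),
      namespace = setNames(rep("biological_process", nTerms), terms),
      edges = do.call(rbind, edges), obsolete = character())
}

# --- rank-bin fair-division oracle ------------------------------------------
# derives bins the other way round: cumulative-rounding fair division hands
# each of the 100 bins its block of consecutive sorted ranks
oracleRankBins <- function(ppm) {
  n <- length(ppm)
  ord <- order(-ppm, names(ppm))
  cuts <- ceiling(seq_len(100) * n / 100)   # cumulative ranks per bin
  perBin <- diff(c(0L, cuts))
  bins <- rep(seq_len(100L), perBin)        # rank r -> its bin
  setNames(bins[order(ord)], names(ppm))    # order(ord) inverts the perm
}

# --- shared tiny fixtures ---------------------------------------------------
tinyConfig <- function(seed = 42, ...) {
  synthConfig(seed = seed, n_substrates = 5, n_partners_per_substrate = 10,
              n_datasets = 8, n_modules = 2, module_size = 8,
              n_background = 60, n_filler = 60, ...)
}

chainDag <- function() degronon:::.chainDag()
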