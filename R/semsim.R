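## Wang graph-based GO semantic similarity, implemented from the measure's
## recursion: the semantic contribution S of a term to itself is 1 and
## decays multiplicatively along each edge toward the root (is_a weight
## 0.8, part_of weight 0.6 by default), taking the maximum over paths.
## Term similarity aggregates S-values over common ancestors; gene
## similarity combines term similarities by best-match averaging.

#' Default Wang measure parameters
#'
#' @param weights named numeric edge weights per relation, each strictly in
#'   (0, 1). Defaults are the measure's conventional values: `is_a` 0.8,
#'   `part_of` 0.6.
#' @param combine gene-level combination rule; only
#'   `"best_match_average"` is implemented.
#' @return validated parameter list.
#' @export
semSimParams <- function(weights = c(is_a = 0.8, part_of = 0.6),
                         combine = "best_match_average") {
  if (!all(c("is_a", "part_of") %in% names(weights)))
    stopConfig("weights must name is_a and part_of")
  if (any(weights <= 0 | weights >= 1))
    stopConfig("edge weights must be strictly between 0 and 1")
  combine <- match.arg(combine, "best_match_average")
  list(weights = weights, combine = combine)
}

## ancestor closure of a term (including the term itself)
termAncestorClosure <- function(dag, term) {
  edges <- goEdges(dag)
  byChild <- split(edges$parent, edges$child)
  seen <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(unlist(byChild[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Ancestors of a term
#'
#' @param dag a [GoDag-class] object.
#' @param term term identifier.
#' @param includeSelf include the term itself (default FALSE).
#' @return character vector of ancestor term ids.
#' @export
termAncestors <- function(dag, term, includeSelf = FALSE) {
  if (!term %in% goTerms(dag)) stopInput("unknown term '%s'", term)
  cl <- termAncestorClosure(dag, term)
  if (includeSelf) cl else setdiff(cl, term)
}

#' Descendant closure of a set of terms
#'
#' Returns the given terms together with every term below them in the DAG
#' (following `is_a` and `part_of` child edges). Used for GO-blacklist
#' expansion in [filterUpsPartners()].
#'
#' @param dag a [GoDag-class] object.
#' @param terms character vector of term ids.
#' @return character vector including `terms` and all descendants.
#' @export
termDescendants <- function(dag, terms) {
  unknown <- setdiff(terms, goTerms(dag))
  if (length(unknown)) stopInput("unknown term(s): %s",
                                 paste(unknown, collapse = ", "))
  edges <- goEdges(dag)
  byParent <- split(edges$child, edges$parent)
  seen <- terms
  frontier <- terms
  while (length(frontier)) {
    nxt <- unique(unlist(byParent[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Semantic contribution (S-) values of a term's ancestor closure
#'
#' S(t) = 1 for the term itself; for each ancestor a,
#' S(a) = max over edges c -> a within the closure of w(relation) * S(c).
#' Values are therefore in (0, 1\] and non-increasing along any path away
#' from the term.
#'
#' @param term term identifier.
#' @param dag a [GoDag-class] object.
#' @param params parameters from [semSimParams()].
#' @return named numeric vector, ancestor (incl. `term`) -> S-value.
#' @export
computeSValues <- function(term, dag, params = semSimParams()) {
  if (!term %in% goTerms(dag)) stopInput("unknown term '%s'", term)
  closure <- termAncestorClosure(dag, term)
  edges <- goEdges(dag)
  edges <- edges[edges$child %in% closure & edges$parent %in% closure, ,
                 drop = FALSE]
  ## topological order over the closure (children before parents)
  order <- .topoOrder(closure, edges)
  s <- setNames(numeric(length(closure)), closure)
  s[[term]] <- 1
  w <- params$weights
  byParent <- split(seq_len(nrow(edges)), edges$parent)
  for (node in order) {
    if (node == term) next
    idx <- byParent[[node]]
    s[[node]] <- max(w[edges$relation[idx]] * s[edges$child[idx]])
  }
  s
}

## Kahn topological order of `nodes` under child -> parent edges
.topoOrder <- function(nodes, edges) {
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  byChild <- split(edges$parent, edges$child)
  queue <- sort(names(indeg)[indeg == 0L])
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (p in byChild[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(out) != length(nodes)) stopInternal("cycle in ancestor closure")
  out
}

#' Wang semantic similarity between two terms
#'
#' sim(t1, t2) = sum over common ancestors a of (S_t1(a) + S_t2(a)),
#' divided by (SV(t1) + SV(t2)) where SV is the sum of all S-values of a
#' term. Symmetric, with sim(t, t) = 1.
#'
#' @param t1,t2 term identifiers (must share a namespace).
#' @inheritParams computeSValues
#' @return similarity in \[0, 1\].
#' @export
termSimilarity <- function(t1, t2, dag, params = semSimParams()) {
  ns <- goNamespace(dag)
  if (!is.na(ns[t1]) && !is.na(ns[t2]) && ns[[t1]] != ns[[t2]])
    stopInput("terms %s and %s are in different namespaces", t1, t2)
  s1 <- computeSValues(t1, dag, params)
  s2 <- computeSValues(t2, dag, params)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  unname(sum(s1[common] + s2[common]) / (sum(s1) + sum(s2)))
}

#' Gene-level semantic similarity (best-match average)
#'
#' Computes all term-pair similarities between two genes' term sets and
#' combines them as the arithmetic mean of (mean of row maxima, mean of
#' column maxima). Symmetric; identical term sets give 1.
#'
#' @param g1,g2 gene identifiers.
#' @param annotations a [GeneAnnotation-class] object.
#' @inheritParams computeSValues
#' @param termSimCache optional environment used to memoize term-pair
#'   similarities across calls (see [makeGeneSimilarity()]).
#' @return similarity in \[0, 1\], or `NA` when either gene has no retained
#'   annotation (such genes are excluded from downstream groupings).
#' @export
geneSimilarity <- function(g1, g2, annotations, dag,
                           params = semSimParams(), termSimCache = NULL) {
  t1 <- geneTerms(annotations, g1)
  t2 <- geneTerms(annotations, g2)
  if (is.null(t1) || is.null(t2) || !length(t1) || !length(t2))
    return(NA_real_)
  sim <- function(a, b) {
    if (is.null(termSimCache)) return(termSimilarity(a, b, dag, params))
    key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    val <- termSimCache[[key]]
    if (is.null(val)) {
      val <- termSimilarity(a, b, dag, params)
      termSimCache[[key]] <- val
    }
    val
  }
  m <- matrix(0, length(t1), length(t2))
  for (i in seq_along(t1))
    for (j in seq_along(t2))
      m[i, j] <- sim(t1[[i]], t2[[j]])
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

#' Memoized gene-similarity function
#'
#' Returns a `function(g1, g2)` closed over shared term-pair and gene-pair
#' caches, suitable as the semantic-similarity source for
#' [detectDegronons()] where the same pairs recur along many paths.
#'
#' @inheritParams geneSimilarity
#' @return a function of two gene ids returning similarity or `NA`.
#' @export
makeGeneSimilarity <- function(annotations, dag, params = semSimParams()) {
  termCache <- new.env(parent = emptyenv())
  geneCache <- new.env(parent = emptyenv())
  function(g1, g2) {
    key <- if (g1 <= g2) paste(g1, g2, sep = "\r") else
      paste(g2, g1, sep = "\r")
    val <- geneCache[[key]]
    if (is.null(val)) {
      val <- geneSimilarity(g1, g2, annotations, dag, params,
                            termSimCache = termCache)
      geneCache[[key]] <- val
    }
    val
  }
}

#' Evidence- and namespace-filter raw gene annotations
#'
#' Keeps only records with retained evidence codes (default IDA: inferred
#' from direct assay; IPI: inferred from physical interaction) whose terms
#' belong to the requested namespace of the ontology. Records pointing at
#' obsolete or unknown terms are dropped with a warning; genes losing all
#' terms are reported in `attr(, "unannotated")`.
#'
#' @param records data.frame with columns `gene`, `term`, `evidence_code`.
#' @param dag a [GoDag-class] object providing namespaces and obsolete ids.
#' @param codes retained evidence codes (default `c("IDA", "IPI")`).
#' @param namespace retained namespace (default `"biological_process"`).
#' @return a [GeneAnnotation-class] object.
#' @export
filterAnnotations <- function(records, dag, codes = c("IDA", "IPI"),
                              namespace = "biological_process") {
  need <- c("gene", "term", "evidence_code")
  if (!all(need %in% names(records)))
    stopInput("records need columns %s", paste(need, collapse = ", "))
  obs <- records$term %in% dag@obsolete
  if (any(obs)) {
    warning(sprintf("dropping %d annotation(s) to obsolete terms", sum(obs)))
    records <- records[!obs, , drop = FALSE]
  }
  unknown <- !(records$term %in% goTerms(dag))
  if (any(unknown)) {
    warning(sprintf("dropping %d annotation(s) to unknown terms",
                    sum(unknown)))
    records <- records[!unknown, , drop = FALSE]
  }
  genesBefore <- unique(records$gene)
  ns <- goNamespace(dag)
  keep <- records$evidence_code %in% codes & ns[records$term] == namespace
  records <- records[keep, , drop = FALSE]
  ann <- lapply(split(records$term, records$gene), function(t) sort(unique(t)))
  lost <- setdiff(genesBefore, names(ann))
  out <- new("GeneAnnotation", annotations = ann,
             evidenceCodes = codes, namespace = namespace)
  attr(out, "unannotated") <- lost
  out
}

## tiny demo DAG used in examples/tests: b -is_a-> a -is_a-> root
.chainDag <- function() {
  new("GoDag",
      terms = c("root", "a", "b"),
      termNames = c(root = "root", a = "a", b = "b"),
      namespace = c(root = "biological_process", a = "biological_process",
                    b = "biological_process"),
      edges = data.frame(child = c("b", "a"), parent = c("a", "root"),
                         relation = c("is_a", "is_a"),
                         stringsAsFactors = FALSE),
      obsolete = character())
}
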