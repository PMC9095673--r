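## Central S4 containers. Plain data.frames are used for row-oriented tables
## (degron annotations, binding features, motifs, pair records); the classes
## below hold the objects with non-trivial invariants.

#' GoDag: a typed Gene Ontology-style directed acyclic graph
#'
#' Holds terms, their namespaces and typed child-to-parent edges
#' (`is_a`, `part_of`). Validity enforces acyclicity and referential
#' integrity; every non-root term must reach a root.
#'
#' @slot terms character vector of term identifiers.
#' @slot termNames named character, human-readable name per term.
#' @slot namespace named character, namespace per term (e.g.
#'   `"biological_process"`).
#' @slot edges data.frame with columns `child`, `parent`, `relation`.
#' @slot obsolete character vector of obsolete term identifiers (kept so
#'   annotation filtering can warn on them; never part of `terms`).
#'
#' @seealso [readObo()], [termAncestors()], [termSimilarity()]
#' @export
setClass("GoDag", representation(
  terms = "character",
  termNames = "character",
  namespace = "character",
  edges = "data.frame",
  obsolete = "character"
))

.validGoDag <- function(object) {
  msg <- character()
  ed <- object@edges
  if (!all(c("child", "parent", "relation") %in% names(ed)))
    msg <- c(msg, "edges must have columns child, parent, relation")
  else {
    if (!all(ed$relation %in% c("is_a", "part_of")))
      msg <- c(msg, "edge relations must be is_a or part_of")
    if (!all(c(ed$child, ed$parent) %in% object@terms))
      msg <- c(msg, "edges reference unknown terms")
    if (any(ed$child == ed$parent))
      msg <- c(msg, "self-edges are not allowed")
  }
  if (is.null(names(object@namespace)) && length(object@namespace) > 0)
    msg <- c(msg, "namespace must be named by term")
  if (length(msg) == 0 && nrow(ed) > 0) {
    ## acyclicity by Kahn peeling (child -> parent digraph)
    if (!.dagIsAcyclic(object@terms, ed))
      msg <- c(msg, "graph contains a cycle")
  }
  if (length(msg)) msg else TRUE
}
setValidity("GoDag", .validGoDag)

.dagIsAcyclic <- function(terms, edges) {
  indeg <- setNames(integer(length(terms)), terms)
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  byChild <- split(edges$parent, edges$child)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (p in byChild[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  seen == length(terms)
}

#' GeneAnnotation: evidence-filtered gene-to-term sets
#'
#' @slot annotations named list; each element a character vector of term ids
#'   annotated to that gene.
#' @slot evidenceCodes character, the evidence codes retained by the filter.
#' @slot namespace single character, the namespace the terms belong to.
#'
#' @seealso [filterAnnotations()], [geneSimilarity()]
#' @export
setClass("GeneAnnotation", representation(
  annotations = "list",
  evidenceCodes = "character",
  namespace = "character"
))

setValidity("GeneAnnotation", function(object) {
  if (length(object@annotations) && is.null(names(object@annotations)))
    return("annotations must be named by gene")
  if (any(vapply(object@annotations, length, 1L) == 0L))
    return("genes with empty term sets must be dropped, not stored")
  TRUE
})

#' AbundanceDataset: one PaxDb-style proteome abundance snapshot
#'
#' Abundances are parts per million (ppm) of the expressed proteome, so a
#' complete dataset sums to ~1e6. The constructor warns when the total is
#' outside \[0.9, 1.1\] x 1e6 (real files deviate slightly).
#'
#' @slot datasetId single character identifier.
#' @slot category one of `integrated`, `whole_organism`, `tissue`,
#'   `cell_line`.
#' @slot abundances named numeric, protein -> ppm (> 0, no duplicates).
#'
#' @seealso [readPaxdb()], [rankBins()]
#' @export
setClass("AbundanceDataset", representation(
  datasetId = "character",
  category = "character",
  abundances = "numeric"
))

setValidity("AbundanceDataset", function(object) {
  msg <- character()
  if (length(object@datasetId) != 1L) msg <- c(msg, "datasetId must be scalar")
  if (!object@category %in% c("integrated", "whole_organism", "tissue", "cell_line"))
    msg <- c(msg, "unknown dataset category")
  ab <- object@abundances
  if (length(ab)) {
    if (is.null(names(ab)) || anyDuplicated(names(ab)))
      msg <- c(msg, "abundances must be uniquely named by protein")
    if (any(!is.finite(ab)) || any(ab <= 0))
      msg <- c(msg, "abundances must be positive and finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceDataset
#'
#' @param datasetId dataset identifier.
#' @param abundances named numeric vector of ppm values.
#' @param category dataset category tag.
#' @return an [AbundanceDataset-class] object.
#' @examples
#' ds <- AbundanceDataset("demo", c(p1 = 6e5, p2 = 4e5))
#' rankBins(ds)
#' @export
AbundanceDataset <- function(datasetId, abundances,
                             category = c("integrated", "whole_organism",
                                          "tissue", "cell_line")) {
  category <- match.arg(category)
  obj <- new("AbundanceDataset", datasetId = as.character(datasetId),
             category = category, abundances = abundances)
  tot <- sum(abundances)
  if (length(abundances) && (tot < 0.9e6 || tot > 1.1e6))
    warning(sprintf("dataset %s: ppm total %.4g outside [0.9, 1.1] x 1e6",
                    datasetId, tot))
  obj
}

#' PpiNetwork: an undirected protein-protein interaction network
#'
#' Stored as a canonical edge table (lexicographically smaller id first).
#' Validity forbids self-loops and duplicate edges.
#'
#' @slot edges data.frame with character columns `a`, `b`.
#'
#' @seealso [readEdgeList()], [randomizeNetwork()], [detectDegronons()]
#' @export
setClass("PpiNetwork", representation(edges = "data.frame"))

setValidity("PpiNetwork", function(object) {
  ed <- object@edges
  msg <- character()
  if (!all(c("a", "b") %in% names(ed)))
    return("edges must have columns a, b")
  if (nrow(ed)) {
    if (any(ed$a == ed$b)) msg <- c(msg, "self-loops are not allowed")
    if (any(ed$a > ed$b)) msg <- c(msg, "edges must be canonical (a < b)")
    if (anyDuplicated(paste(ed$a, ed$b, sep = "\r")))
      msg <- c(msg, "duplicate edges are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PpiNetwork from an edge table
#'
#' Canonicalizes each unordered pair (smaller id first). With
#' `strict = TRUE` (default) duplicate edges or self-loops are an error;
#' with `strict = FALSE` self-loops and duplicates are dropped with a
#' message, which is convenient when ingesting raw database exports.
#'
#' @param a,b character vectors of interactor identifiers, one edge per
#'   position.
#' @param strict logical; error (TRUE) or clean (FALSE) on invalid edges.
#' @return a [PpiNetwork-class] object.
#' @examples
#' net <- PpiNetwork(c("yA", "yB"), c("yB", "yC"))
#' networkNodes(net)
#' @export
PpiNetwork <- function(a, b, strict = TRUE) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == length(b))
  lo <- pmin(a, b); hi <- pmax(a, b)
  ed <- data.frame(a = lo, b = hi, stringsAsFactors = FALSE)
  if (!strict) {
    loops <- ed$a == ed$b
    dups <- duplicated(paste(ed$a, ed$b, sep = "\r"))
    drop <- loops | dups
    if (any(drop))
      message(sprintf("dropping %d self-loop(s) and %d duplicate edge(s)",
                      sum(loops), sum(dups & !loops)))
    ed <- ed[!drop, , drop = FALSE]
  }
  ed <- ed[order(ed$a, ed$b), , drop = FALSE]
  rownames(ed) <- NULL
  new("PpiNetwork", edges = ed)
}

#' HalfLifeTable: protein half-lives from a single dataset
#'
#' Ratios are only meaningful within one dataset, so the table carries its
#' unit convention and a dataset tag; mixing tables is the caller's error.
#'
#' @slot values named numeric, protein -> half-life (> 0).
#' @slot units `"relative"` (growth-normalized relative half-life) or
#'   `"minutes"`.
#' @slot datasetTag single character label for provenance.
#'
#' @seealso [readHalfLives()], [halfLifeRatio()]
#' @export
setClass("HalfLifeTable", representation(
  values = "numeric",
  units = "character",
  datasetTag = "character"
))

setValidity("HalfLifeTable", function(object) {
  msg <- character()
  if (!object@units %in% c("relative", "minutes"))
    msg <- c(msg, "units must be 'relative' or 'minutes'")
  v <- object@values
  if (length(v)) {
    if (is.null(names(v)) || anyDuplicated(names(v)))
      msg <- c(msg, "values must be uniquely named by protein")
    if (any(!is.finite(v)) || any(v <= 0))
      msg <- c(msg, "half-lives must be positive and finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a HalfLifeTable
#'
#' @param values named numeric vector of half-lives.
#' @param units unit convention, `"relative"` or `"minutes"`.
#' @param datasetTag provenance label.
#' @return a [HalfLifeTable-class] object.
#' @export
HalfLifeTable <- function(values, units = c("relative", "minutes"),
                          datasetTag = "unnamed") {
  units <- match.arg(units)
  new("HalfLifeTable", values = values, units = units,
      datasetTag = as.character(datasetTag))
}
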