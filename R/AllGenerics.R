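## Accessors and show methods.

#' @describeIn GoDag-class term identifiers
#' @param x,object a `GoDag`
#' @export
setGeneric("goTerms", function(x) standardGeneric("goTerms"))
#' @export
setMethod("goTerms", "GoDag", function(x) x@terms)

#' @describeIn GoDag-class typed edge table (child, parent, relation)
#' @export
setGeneric("goEdges", function(x) standardGeneric("goEdges"))
#' @export
setMethod("goEdges", "GoDag", function(x) x@edges)

#' @describeIn GoDag-class namespace per term
#' @export
setGeneric("goNamespace", function(x) standardGeneric("goNamespace"))
#' @export
setMethod("goNamespace", "GoDag", function(x) x@namespace)

setMethod("show", "GoDag", function(object) {
  cat(sprintf("GoDag with %d terms, %d edges (%s)\n",
              length(object@terms), nrow(object@edges),
              paste(unique(object@namespace), collapse = ", ")))
  roots <- setdiff(object@terms, object@edges$child)
  cat(sprintf("  roots: %s\n", paste(head(roots, 5), collapse = ", ")))
})

#' @describeIn GeneAnnotation-class genes with at least one retained term
#' @param x,object a `GeneAnnotation`
#' @export
setGeneric("annotatedGenes", function(x) standardGeneric("annotatedGenes"))
#' @export
setMethod("annotatedGenes", "GeneAnnotation", function(x) names(x@annotations))

#' @describeIn GeneAnnotation-class term set for one gene (NULL if absent)
#' @param gene gene identifier
#' @export
setGeneric("geneTerms", function(x, gene) standardGeneric("geneTerms"))
#' @export
setMethod("geneTerms", "GeneAnnotation", function(x, gene) {
  x@annotations[[gene]]
})

setMethod("show", "GeneAnnotation", function(object) {
  cat(sprintf("GeneAnnotation: %d genes, evidence {%s}, namespace %s\n",
              length(object@annotations),
              paste(object@evidenceCodes, collapse = ","),
              object@namespace))
})

#' @describeIn AbundanceDataset-class named ppm vector
#' @param x,object an `AbundanceDataset`
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @export
setMethod("abundances", "AbundanceDataset", function(x) x@abundances)

#' @describeIn AbundanceDataset-class dataset identifier
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))
#' @export
setMethod("datasetId", "AbundanceDataset", function(x) x@datasetId)

#' @describeIn AbundanceDataset-class dataset category tag
#' @export
setGeneric("datasetCategory", function(x) standardGeneric("datasetCategory"))
#' @export
setMethod("datasetCategory", "AbundanceDataset", function(x) x@category)

setMethod("show", "AbundanceDataset", function(object) {
  cat(sprintf("AbundanceDataset '%s' (%s): %d proteins, ppm total %.4g\n",
              object@datasetId, object@category, length(object@abundances),
              sum(object@abundances)))
})

#' @describeIn PpiNetwork-class node identifiers (sorted)
#' @param x,object a `PpiNetwork`
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @export
setMethod("networkNodes", "PpiNetwork", function(x) {
  sort(unique(c(x@edges$a, x@edges$b)))
})

#' @describeIn PpiNetwork-class canonical edge table
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @export
setMethod("networkEdges", "PpiNetwork", function(x) x@edges)

#' @describeIn PpiNetwork-class convert to an igraph object (named vertices)
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
#' @export
setMethod("asIgraph", "PpiNetwork", function(x) {
  igraph::graph_from_data_frame(x@edges, directed = FALSE,
                                vertices = networkNodes(x))
})

setMethod("show", "PpiNetwork", function(object) {
  cat(sprintf("PpiNetwork: %d nodes, %d edges\n",
              length(networkNodes(object)), nrow(object@edges)))
})

#' @describeIn HalfLifeTable-class named half-life vector
#' @param x,object a `HalfLifeTable`
#' @export
setGeneric("halfLives", function(x) standardGeneric("halfLives"))
#' @export
setMethod("halfLives", "HalfLifeTable", function(x) x@values)

#' @describeIn HalfLifeTable-class unit convention
#' @export
setGeneric("halfLifeUnits", function(x) standardGeneric("halfLifeUnits"))
#' @export
setMethod("halfLifeUnits", "HalfLifeTable", function(x) x@units)

setMethod("show", "HalfLifeTable", function(object) {
  cat(sprintf("HalfLifeTable '%s': %d proteins (%s)\n",
              object@datasetTag, length(object@values), object@units))
})
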