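## Degron masking: interval relations, record filters, tertiary degron
## inference, and the masking / motif census tables.
##
## Coordinates are 1-based inclusive throughout (UniProt convention). For
## disjoint intervals the gap is the number of residues strictly between
## them (later.start - earlier.end - 1); "adjacent" means gap <= window,
## including gap 0 for contiguous intervals.

#' Classify the positional relation between a degron and a binding site
#'
#' Computes the residue overlap between two regions on the same protein and
#' classifies the pair as `overlap` (>= 1 shared residue), `adjacent`
#' (disjoint, but separated by at most `window` residues) or `none`.
#'
#' @param degron,site regions: either numeric `c(start, end)` or a list with
#'   `start`, `end` and optionally `protein_id` (1-based inclusive).
#' @param window adjacency window in residues (default 10: a site whose
#'   boundary lies within 10 amino acids of a degron counts as adjacent).
#' @return list with `relation` (`"overlap"`, `"adjacent"`, `"none"`),
#'   `overlap_length` (residues shared, >= 0) and `gap` (residues strictly
#'   between disjoint regions; `NA` when overlapping).
#' @examples
#' classifyRegionRelation(c(19, 26), c(10, 40))  # overlap
#' classifyRegionRelation(c(19, 26), c(30, 50))  # adjacent, gap 3
#' classifyRegionRelation(c(19, 26), c(40, 50))  # none, gap 13
#' @export
classifyRegionRelation <- function(degron, site, window = 10) {
  d <- .asRegion(degron); s <- .asRegion(site)
  if (!is.null(d$protein_id) && !is.null(s$protein_id) &&
      !identical(d$protein_id, s$protein_id))
    stopInput("regions are on different proteins (%s vs %s)",
              d$protein_id, s$protein_id)
  res <- .relationVec(d$start, d$end, s$start, s$end, window)
  list(relation = res$relation, overlap_length = res$overlap_length,
       gap = res$gap)
}

.asRegion <- function(r) {
  if (is.numeric(r) && length(r) == 2L)
    r <- list(start = r[[1L]], end = r[[2L]])
  if (is.null(r$start) || is.null(r$end))
    stopInput("region must provide start and end")
  if (!is.finite(r$start) || !is.finite(r$end) || r$start < 1 ||
      r$start > r$end)
    stopInput("invalid region coordinates [%s, %s]", r$start, r$end)
  r
}

## vectorized core shared by the censuses
.relationVec <- function(ds, de, ss, se, window) {
  ov <- pmax(0L, pmin(de, se) - pmax(ds, ss) + 1L)
  gap <- ifelse(ov > 0L, NA_integer_,
                pmax(ss - de, ds - se) - 1L)
  relation <- ifelse(ov > 0L, "overlap",
                     ifelse(gap <= window, "adjacent", "none"))
  list(relation = relation, overlap_length = as.integer(ov),
       gap = as.integer(gap))
}

#' Filter interaction records by confidence score
#'
#' Retention is per interaction: when an interaction falls below the cutoff
#' every feature row belonging to it is dropped. Rows with an unparseable
#' (missing) confidence are dropped with a warning.
#'
#' @param records data.frame of interaction/feature rows with at least
#'   `interaction_id` and `confidence` columns (one confidence per
#'   interaction; feature coordinates may be `NA` for partners without
#'   mapped binding regions).
#' @param minConfidence minimum retained score (default 0.3).
#' @return the retained subset of `records`.
#' @export
filterInteractionRecords <- function(records, minConfidence = 0.3) {
  if (!all(c("interaction_id", "confidence") %in% names(records)))
    stopInput("records need interaction_id and confidence columns")
  bad <- is.na(records$confidence)
  if (any(bad)) {
    warning(sprintf("dropping %d record(s) with unparseable confidence (%s)",
                    sum(bad),
                    paste(head(unique(records$interaction_id[bad]), 3),
                          collapse = ", ")))
    records <- records[!bad, , drop = FALSE]
  }
  keep <- records$confidence >= minConfidence
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove UPS-related partners based on GO annotations
#'
#' A partner is removed iff it is annotated (in `annotations`) with any
#' blacklist term or any descendant of a blacklist term in the ontology.
#' This strips E3 ligases, proteasome subunits and other degradation
#' machinery so the remaining partners are bona fide stability-modulating
#' alternate partners.
#'
#' @param partners character vector of partner identifiers.
#' @param annotations a [GeneAnnotation-class] object.
#' @param blacklist character vector of term ids rooting the UPS branch;
#'   every term must exist in `dag`.
#' @param dag a [GoDag-class] object.
#' @return the retained partners; removed ids are attached as
#'   `attr(, "removed")`.
#' @export
filterUpsPartners <- function(partners, annotations, blacklist, dag) {
  missing <- setdiff(blacklist, goTerms(dag))
  if (length(missing))
    stopConfig("blacklist term(s) not in ontology: %s",
               paste(missing, collapse = ", "))
  banned <- termDescendants(dag, blacklist)
  isUps <- vapply(partners, function(p) {
    terms <- geneTerms(annotations, p)
    length(terms) > 0 && any(terms %in% banned)
  }, logical(1))
  kept <- partners[!isUps]
  attr(kept, "removed") <- partners[isUps]
  kept
}

#' Infer the tertiary degron from a per-residue disorder profile
#'
#' The tertiary degron is taken as the intrinsically disordered region
#' nearest in sequence to the ubiquitination site that contains at least
#' `minRun` consecutive residues with disorder score >= `threshold`.
#' Distance to a run is 0 when the run contains the Ubsite; equidistant
#' runs are broken toward the upstream (lower-coordinate) run.
#'
#' @param profile numeric vector of per-residue disorder scores in \[0, 1\]
#'   covering the protein (position i = residue i).
#' @param ubsite residue index of the ubiquitination site.
#' @param minRun minimum run length (default 20 residues).
#' @param threshold disorder cutoff (default 0.5).
#' @return list with `start`, `end` of the selected region, or `NULL` when
#'   no qualifying run exists.
#' @export
inferTertiaryDegron <- function(profile, ubsite, minRun = 20, threshold = 0.5) {
  if (!is.numeric(profile) || length(profile) == 0)
    stopInput("profile must be a non-empty numeric vector")
  if (!isCount(ubsite) || ubsite > length(profile))
    stopInput("ubsite %s outside profile of length %d", ubsite,
              length(profile))
  runs <- .disorderRuns(profile, threshold)
  runs <- runs[runs$end - runs$start + 1L >= minRun, , drop = FALSE]
  if (nrow(runs) == 0) return(NULL)
  dist <- ifelse(ubsite >= runs$start & ubsite <= runs$end, 0L,
                 pmin(abs(runs$start - ubsite), abs(runs$end - ubsite)))
  best <- which(dist == min(dist))
  pick <- best[which.min(runs$start[best])]  # upstream tie-break
  list(start = runs$start[[pick]], end = runs$end[[pick]])
}

## maximal runs with score >= threshold, as a data.frame(start, end)
.disorderRuns <- function(profile, threshold) {
  above <- profile >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Per-substrate census of degron-masking partners
#'
#' For each substrate, counts the total number of interaction partners and,
#' per degron class, the partners with at least one binding feature that
#' overlaps (or lies adjacent to) a degron of that class. A partner is
#' counted once per (substrate, degron class) however many features or
#' degrons support it. Partners whose interactions carry no mapped feature
#' contribute to the totals but can never be masking.
#'
#' @param features data.frame of (already filtered) binding features with
#'   columns `substrate_id`, `partner_id`, `feature_kind`, `start`, `end`
#'   (`NA` coordinates = interaction without a mapped region).
#' @param degrons data.frame of degron annotations with columns
#'   `substrate_id`, `degron_class` (`primary`/`secondary`/`tertiary`),
#'   `start`, `end`.
#' @param window adjacency window in residues (default 10).
#' @param countAdjacent logical; count adjacent (as well as strictly
#'   overlapping) features as masking (default TRUE). Set FALSE to restrict
#'   to strict overlap; the per-pair relation table reports both either way.
#' @param flagThreshold substrates with at least this many masking partners
#'   in any class are flagged in the output (default 10).
#' @return list with
#'   \describe{
#'     \item{census}{per-substrate data.frame: `n_partners_total`,
#'       `n_masking_primary`, `n_masking_secondary`, `n_masking_tertiary`,
#'       `flagged`.}
#'     \item{maskingPairs}{data.frame of (substrate_id, partner_id,
#'       degron_class, relation) for every masking partner-class pair.}
#'     \item{segmentLengths}{integer lengths (residues) of the binding
#'       segments that mask at least one degron.}
#'   }
#' @export
maskingCensus <- function(features, degrons, window = 10,
                          countAdjacent = TRUE, flagThreshold = 10) {
  need <- c("substrate_id", "partner_id", "start", "end")
  if (!all(need %in% names(features)))
    stopInput("features need columns %s", paste(need, collapse = ", "))
  classes <- c("primary", "secondary", "tertiary")
  substrates <- sort(unique(features$substrate_id))
  nTotal <- vapply(split(features$partner_id, features$substrate_id),
                   function(p) length(unique(p)), 1L)

  withCoords <- features[!is.na(features$start) & !is.na(features$end), ,
                         drop = FALSE]
  rel <- .featureDegronRelations(withCoords, degrons, window)
  okRel <- if (countAdjacent) c("overlap", "adjacent") else "overlap"
  masking <- rel[rel$relation %in% okRel, , drop = FALSE]

  pairKey <- paste(masking$substrate_id, masking$partner_id,
                   masking$degron_class, sep = "\r")
  maskingPairs <- masking[!duplicated(pairKey),
                          c("substrate_id", "partner_id", "degron_class",
                            "relation")]
  rownames(maskingPairs) <- NULL

  census <- data.frame(substrate_id = substrates,
                       n_partners_total = as.integer(nTotal[substrates]),
                       stringsAsFactors = FALSE)
  for (cl in classes) {
    sub <- maskingPairs[maskingPairs$degron_class == cl, , drop = FALSE]
    cnt <- vapply(split(sub$partner_id, sub$substrate_id),
                  function(p) length(unique(p)), 1L)
    col <- paste0("n_masking_", cl)
    census[[col]] <- as.integer(ifelse(is.na(cnt[census$substrate_id]), 0L,
                                       cnt[census$substrate_id]))
  }
  census$flagged <- census$n_masking_primary >= flagThreshold |
    census$n_masking_secondary >= flagThreshold |
    census$n_masking_tertiary >= flagThreshold

  segKey <- paste(masking$substrate_id, masking$partner_id, masking$start,
                  masking$end, sep = "\r")
  seg <- masking[!duplicated(segKey), , drop = FALSE]
  segmentLengths <- as.integer(seg$end - seg$start + 1L)

  list(census = census, maskingPairs = maskingPairs,
       segmentLengths = segmentLengths)
}

## cross every feature with every degron of the same substrate
.featureDegronRelations <- function(features, degrons, window) {
  if (nrow(features) == 0 || nrow(degrons) == 0)
    return(data.frame(substrate_id = character(), partner_id = character(),
                      degron_class = character(), relation = character(),
                      overlap_length = integer(), gap = integer(),
                      start = integer(), end = integer()))
  degBySub <- split(seq_len(nrow(degrons)), degrons$substrate_id)
  idx <- lapply(seq_len(nrow(features)), function(i) {
    d <- degBySub[[features$substrate_id[[i]]]]
    if (is.null(d)) return(NULL)
    cbind(f = i, d = d)
  })
  idx <- do.call(rbind, idx)
  if (is.null(idx))
    return(.featureDegronRelations(features[0, , drop = FALSE], degrons,
                                   window))
  f <- features[idx[, "f"], , drop = FALSE]
  d <- degrons[idx[, "d"], , drop = FALSE]
  r <- .relationVec(d$start, d$end, f$start, f$end, window)
  out <- data.frame(substrate_id = f$substrate_id,
                    partner_id = f$partner_id,
                    degron_class = d$degron_class,
                    relation = r$relation,
                    overlap_length = r$overlap_length,
                    gap = r$gap,
                    start = f$start, end = f$end,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Census of linear motifs overlapping or adjacent to degrons
#'
#' Counts motif annotations by (degron class x functional category), using
#' the same interval classifier and adjacency window as the binding-feature
#' census. Motifs with no positional relation to any degron are excluded.
#'
#' @param motifs data.frame with columns `substrate_id`, `motif_id`,
#'   `category` (one of `modification`, `docking`, `ligand_binding`,
#'   `targeting`, `cleavage`), `start`, `end`.
#' @param degrons degron annotation data.frame (see [maskingCensus()]).
#' @param window adjacency window (default 10).
#' @param countAdjacent include adjacent motifs (default TRUE).
#' @return data.frame over the full class x category grid with an integer
#'   `count` column (a motif counts once per degron class it touches).
#' @export
motifCategoryCensus <- function(motifs, degrons, window = 10,
                                countAdjacent = TRUE) {
  classes <- c("primary", "secondary", "tertiary")
  categories <- c("modification", "docking", "ligand_binding", "targeting",
                  "cleavage")
  grid <- expand.grid(degron_class = classes, category = categories,
                      stringsAsFactors = FALSE)
  grid$count <- 0L
  if (nrow(motifs)) {
    if (!all(motifs$category %in% categories))
      stopInput("unknown motif category: %s",
                paste(setdiff(motifs$category, categories), collapse = ", "))
    mf <- data.frame(substrate_id = motifs$substrate_id,
                     partner_id = motifs$motif_id,
                     start = motifs$start, end = motifs$end,
                     category = motifs$category, stringsAsFactors = FALSE)
    rel <- .featureDegronRelations(mf, degrons, window)
    okRel <- if (countAdjacent) c("overlap", "adjacent") else "overlap"
    rel <- rel[rel$relation %in% okRel, , drop = FALSE]
    rel$category <- mf$category[match(paste(rel$substrate_id, rel$partner_id),
                                      paste(mf$substrate_id, mf$partner_id))]
    key <- paste(rel$substrate_id, rel$partner_id, rel$degron_class,
                 sep = "\r")
    rel <- rel[!duplicated(key), , drop = FALSE]
    tab <- table(factor(rel$degron_class, classes),
                 factor(rel$category, categories))
    grid$count <- as.integer(tab[cbind(grid$degron_class, grid$category)])
  }
  grid
}

#' Count proteins per degron class in a degron annotation table
#'
#' Convenience counter for supplementary-style degron datasets: the number
#' of distinct substrate proteins annotated with at least one degron of
#' each class.
#'
#' @param degrons degron annotation data.frame (see [maskingCensus()]).
#' @return named integer vector over `primary`, `secondary`, `tertiary`.
#' @export
countDegronProteins <- function(degrons) {
  classes <- c("primary", "secondary", "tertiary")
  vapply(classes, function(cl) {
    length(unique(degrons$substrate_id[degrons$degron_class == cl]))
  }, integer(1))
}
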