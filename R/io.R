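## Readers and writers for the plain-text exchange formats: degron tables,
## a PSI-MITAB 2.7 subset, disorder profiles, OBO v1.2, GAF-like
## annotations, PaxDb-style abundances, edge lists, half-life tables and
## co-expression pair tables. Writers are deterministic (no timestamps).

.writeTsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(cm, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname degronTableIO
#' @param degrons degron annotation data.frame.
#' @export
writeDegronTable <- function(degrons, path) {
  .writeTsv(degrons, path)
}

#' Read/write degron annotation tables
#'
#' TSV with columns `substrate_id`, `degron_class` (accepts `class`),
#' `start`, `end`, `sequence`, and optionally `ubsite`, `provenance`.
#'
#' @param path file path.
#' @return `readDegronTable`: the degron data.frame.
#' @name degronTableIO
#' @export
readDegronTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if ("class" %in% names(df) && !"degron_class" %in% names(df))
    names(df)[names(df) == "class"] <- "degron_class"
  need <- c("substrate_id", "degron_class", "start", "end")
  if (!all(need %in% names(df)))
    stopInput("%s: degron table needs columns %s", path,
              paste(need, collapse = ", "))
  bad <- !df$degron_class %in% c("primary", "secondary", "tertiary")
  if (any(bad)) stopInput("%s: unknown degron class %s", path,
                          paste(unique(df$degron_class[bad]), collapse = ","))
  df
}

## PSI-MITAB feature-kind text <-> internal enum
.mitabKindText <- c(
  sufficient_binding_region = "sufficient binding region",
  binding_associated_region = "binding-associated region",
  necessary_binding_region = "necessary binding region",
  mutation_evidence = "mutation decreasing interaction")
.mitabMutationHeadings <- c(
  "mutation decreasing interaction", "mutation disrupting interaction",
  "mutation disrupting interaction strength",
  "mutation decreasing interaction strength",
  "mutation disrupting interaction rate", "mutation increasing interaction",
  "mutation increasing interaction strength")

#' @rdname mitabIO
#' @param records interaction/feature data.frame as produced by
#'   [simulateInteractions()].
#' @export
writeMitab <- function(records, path) {
  key <- paste(records$substrate_id, records$partner_id,
               records$interaction_id, sep = "\r")
  first <- !duplicated(key)
  feats <- vapply(which(first), function(i) {
    rows <- records[key == key[[i]] & !is.na(records$start), , drop = FALSE]
    if (nrow(rows) == 0) return("-")
    paste(sprintf("%s:%d-%d", .mitabKindText[rows$feature_kind], rows$start,
                  rows$end), collapse = "|")
  }, "")
  df <- data.frame(
    id_a = records$substrate_id[first],
    id_b = records$partner_id[first],
    interaction_id = records$interaction_id[first],
    confidence = sprintf("intact-miscore:%s", records$confidence[first]),
    features_a = feats,
    features_b = "-",
    stringsAsFactors = FALSE)
  .writeTsv(df, path,
            "# PSI-MITAB 2.7 subset: idA idB interaction confidence featuresA featuresB")
}

#' Read/write a PSI-MITAB 2.7 subset
#'
#' Tab-separated records with interactor A/B identifiers, an interaction
#' identifier, an `intact-miscore:<x>` confidence and a features column
#' (`<kind>:<start>-<end>`, `|`-separated; `-` for none). Feature kinds
#' cover sufficient/associated/necessary binding regions and the
#' mutation-evidence headings (all mapped to `mutation_evidence`).
#' Features with undetermined positions (`?` or `n`) are skipped with a
#' warning; unparseable confidences yield `NA` (dropped later, with a
#' warning, by [filterInteractionRecords()]).
#'
#' @param path file path.
#' @return `readMitab`: long data.frame with one row per feature (or per
#'   featureless interaction): `substrate_id`, `partner_id`,
#'   `interaction_id`, `confidence`, `feature_kind`, `start`, `end`.
#' @name mitabIO
#' @export
readMitab <- function(path) {
  df <- read.delim(path, comment.char = "#", header = TRUE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 6) stopInput("%s: expected >= 6 MITAB columns", path)
  conf <- suppressWarnings(as.numeric(sub("^intact-miscore:", "",
                                          df$confidence)))
  out <- list()
  for (i in seq_len(nrow(df))) {
    base <- data.frame(substrate_id = df$id_a[[i]],
                       partner_id = df$id_b[[i]],
                       interaction_id = df$interaction_id[[i]],
                       confidence = conf[[i]], stringsAsFactors = FALSE)
    fstr <- df$features_a[[i]]
    if (is.na(fstr) || fstr == "-" || fstr == "") {
      out[[length(out) + 1L]] <- cbind(base, feature_kind = NA_character_,
                                       start = NA_integer_,
                                       end = NA_integer_)
      next
    }
    any <- FALSE
    for (f in strsplit(fstr, "|", fixed = TRUE)[[1]]) {
      m <- regmatches(f, regexec("^(.*):([0-9?n]+)-([0-9?n]+)$", f))[[1]]
      if (length(m) != 4 || grepl("[?n]", m[[3]]) || grepl("[?n]", m[[4]])) {
        warning(sprintf("%s: skipping feature with undetermined range: %s",
                        basename(path), f))
        next
      }
      kindTxt <- m[[2]]
      kind <- names(.mitabKindText)[match(kindTxt, .mitabKindText)]
      if (is.na(kind) && kindTxt %in% .mitabMutationHeadings)
        kind <- "mutation_evidence"
      if (is.na(kind)) {
        warning(sprintf("%s: skipping unknown feature kind '%s'",
                        basename(path), kindTxt))
        next
      }
      out[[length(out) + 1L]] <- cbind(
        base, feature_kind = kind, start = as.integer(m[[3]]),
        end = as.integer(m[[4]]))
      any <- TRUE
    }
    if (!any)  # every feature skipped: keep the interaction, featureless
      out[[length(out) + 1L]] <- cbind(base, feature_kind = NA_character_,
                                       start = NA_integer_,
                                       end = NA_integer_)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname disorderIO
#' @param profiles named list of numeric score vectors.
#' @param dir directory to hold one `<protein>.tsv` per profile.
#' @export
writeDisorderProfiles <- function(profiles, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(profiles)) {
    p <- profiles[[id]]
    .writeTsv(data.frame(position = seq_along(p), score = p),
              file.path(dir, paste0(id, ".tsv")))
  }
  invisible(dir)
}

#' Read/write per-residue disorder profiles
#'
#' One TSV per protein with columns `position`, `score` (scores in
#' \[0, 1\]; positions must be 1..L).
#'
#' @return `readDisorderProfiles`: named list of numeric vectors.
#' @name disorderIO
#' @export
readDisorderProfiles <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  out <- lapply(files, function(f) {
    df <- read.delim(f, stringsAsFactors = FALSE)
    if (!all(df$position == seq_len(nrow(df))))
      stopInput("%s: positions must be contiguous from 1", f)
    df$score
  })
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}

#' @rdname oboIO
#' @param dag a [GoDag-class] object.
#' @export
writeObo <- function(dag, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  ed <- goEdges(dag)
  ns <- goNamespace(dag)
  nm <- dag@termNames
  for (t in goTerms(dag)) {
    writeLines("[Term]", con)
    writeLines(sprintf("id: %s", t), con)
    writeLines(sprintf("name: %s", nm[[t]]), con)
    writeLines(sprintf("namespace: %s", ns[[t]]), con)
    e <- ed[ed$child == t, , drop = FALSE]
    for (k in seq_len(nrow(e))) {
      if (e$relation[[k]] == "is_a")
        writeLines(sprintf("is_a: %s ! %s", e$parent[[k]], nm[[e$parent[[k]]]]),
                   con)
      else
        writeLines(sprintf("relationship: part_of %s ! %s", e$parent[[k]],
                           nm[[e$parent[[k]]]]), con)
    }
    writeLines("", con)
  }
  for (t in dag@obsolete) {
    writeLines(c("[Term]", sprintf("id: %s", t),
                 sprintf("name: obsolete %s", t), "is_obsolete: true", ""),
               con)
  }
  invisible(path)
}

#' Read/write OBO v1.2 ontologies
#'
#' Minimal OBO v1.2 support: `[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a`, `relationship: part_of` and `is_obsolete`.
#' Other relationship types and tags are ignored.
#'
#' @param path file path.
#' @return `readObo`: a [GoDag-class] object.
#' @name oboIO
#' @export
readObo <- function(path) {
  lines <- readLines(path)
  terms <- character(); nm <- character(); ns <- character()
  obsolete <- character()
  edges <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || is.null(cur$id)) return()
    if (isTRUE(cur$obsolete)) {
      obsolete <<- c(obsolete, cur$id)
    } else {
      terms <<- c(terms, cur$id)
      nm[cur$id] <<- if (is.null(cur$name)) cur$id else cur$name
      ns[cur$id] <<- if (is.null(cur$namespace)) "biological_process" else
        cur$namespace
      for (p in cur$is_a)
        edges[[length(edges) + 1L]] <<- data.frame(
          child = cur$id, parent = p, relation = "is_a",
          stringsAsFactors = FALSE)
      for (p in cur$part_of)
        edges[[length(edges) + 1L]] <<- data.frame(
          child = cur$id, parent = p, relation = "part_of",
          stringsAsFactors = FALSE)
    }
  }
  inTerm <- FALSE
  for (ln in lines) {
    if (ln == "[Term]") { flush(); cur <- list(); inTerm <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; inTerm <- FALSE; next }
    if (!inTerm || ln == "") next
    kv <- regmatches(ln, regexec("^([a-z_]+): (.*)$", ln))[[1]]
    if (length(kv) != 3) next
    key <- kv[[2]]; val <- sub(" !.*$", "", kv[[3]])
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- kv[[3]]
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, val)
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (key == "relationship") {
      rv <- strsplit(val, " +")[[1]]
      if (length(rv) >= 2 && rv[[1]] == "part_of")
        cur$part_of <- c(cur$part_of, rv[[2]])
    }
  }
  flush()
  ed <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(),
               relation = character())
  new("GoDag", terms = terms, termNames = nm[terms], namespace = ns[terms],
      edges = ed, obsolete = obsolete)
}

#' @rdname gafIO
#' @param gaf data.frame with columns `gene`, `term`, `evidence_code`.
#' @export
writeGaf <- function(gaf, path) {
  .writeTsv(gaf, path, "!gaf-like: gene term evidence_code")
}

#' Read/write GAF-like annotation tables
#'
#' Three tab-separated columns: `gene`, `term`, `evidence_code`; `!`
#' comment lines are skipped, malformed rows dropped with a warning.
#'
#' @param path file path.
#' @return `readGaf`: the annotation data.frame.
#' @name gafIO
#' @export
readGaf <- function(path) {
  df <- read.delim(path, comment.char = "!", stringsAsFactors = FALSE)
  need <- c("gene", "term", "evidence_code")
  if (!all(need %in% names(df)))
    stopInput("%s: GAF-like table needs columns %s", path,
              paste(need, collapse = ", "))
  bad <- is.na(df$gene) | is.na(df$term) | df$gene == "" | df$term == ""
  if (any(bad)) {
    warning(sprintf("%s: dropping %d malformed record(s)", basename(path),
                    sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  df
}

#' @rdname paxdbIO
#' @param ds an [AbundanceDataset-class] object.
#' @export
writePaxdb <- function(ds, path) {
  organ <- switch(datasetCategory(ds),
                  integrated = "WHOLE_ORGANISM",
                  whole_organism = "WHOLE_ORGANISM",
                  tissue = "TISSUE", cell_line = "CELL_LINE")
  ab <- abundances(ds)
  .writeTsv(data.frame(string_id = names(ab), abundance_ppm = unname(ab)),
            path,
            c(sprintf("#name: %s", datasetId(ds)),
              sprintf("#organ: %s", organ),
              sprintf("#integrated: %s",
                      tolower(datasetCategory(ds) == "integrated"))))
}

#' Read/write PaxDb-style abundance files
#'
#' Tab-separated `string_id`, `abundance_ppm` with `#organ` and
#' `#integrated` descriptor comments that determine the dataset category.
#'
#' @param path file path (`readPaxdbDir`: a directory of such files).
#' @return an [AbundanceDataset-class] (or list thereof).
#' @name paxdbIO
#' @export
readPaxdb <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getField <- function(key) {
    h <- hdr[startsWith(hdr, paste0("#", key, ":"))]
    if (!length(h)) return(NA_character_)
    trimws(sub(paste0("^#", key, ":"), "", h[[1]]))
  }
  name <- getField("name")
  if (is.na(name)) name <- sub("\\.[^.]*$", "", basename(path))
  organ <- getField("organ")
  integrated <- identical(getField("integrated"), "true")
  category <- if (integrated) "integrated"
  else if (identical(organ, "CELL_LINE")) "cell_line"
  else if (identical(organ, "WHOLE_ORGANISM")) "whole_organism"
  else "tissue"
  df <- read.delim(textConnection(lines[!startsWith(lines, "#")]),
                   stringsAsFactors = FALSE)
  AbundanceDataset(name, setNames(df[[2]], df[[1]]), category = category)
}

#' @rdname paxdbIO
#' @param dir directory containing PaxDb-style files.
#' @export
readPaxdbDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  lapply(files, readPaxdb)
}

#' @rdname edgeListIO
#' @param net a [PpiNetwork-class] object.
#' @export
writeEdgeList <- function(net, path) {
  .writeTsv(networkEdges(net), path)
}

#' Read/write undirected edge lists
#'
#' Two tab-separated identifier columns; self-loops and duplicate edges in
#' the input are dropped with a message on read.
#'
#' @param path file path.
#' @return `readEdgeList`: a [PpiNetwork-class] object.
#' @name edgeListIO
#' @export
readEdgeList <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopInput("%s: edge list needs two columns", path)
  PpiNetwork(df[[1]], df[[2]], strict = FALSE)
}

#' @rdname halfLifeIO
#' @param hlt a [HalfLifeTable-class] object.
#' @export
writeHalfLives <- function(hlt, path) {
  v <- halfLives(hlt)
  .writeTsv(data.frame(protein = names(v), half_life = unname(v)), path,
            c(sprintf("#units: %s", halfLifeUnits(hlt)),
              sprintf("#dataset: %s", hlt@datasetTag)))
}

#' Read/write half-life tables
#'
#' Tab-separated `protein`, `half_life` with `#units` (relative/minutes)
#' and `#dataset` comments.
#'
#' @param path file path.
#' @return `readHalfLives`: a [HalfLifeTable-class] object.
#' @name halfLifeIO
#' @export
readHalfLives <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  units <- "relative"; tag <- sub("\\.[^.]*$", "", basename(path))
  for (h in hdr) {
    if (startsWith(h, "#units:")) units <- trimws(sub("^#units:", "", h))
    if (startsWith(h, "#dataset:")) tag <- trimws(sub("^#dataset:", "", h))
  }
  df <- read.delim(textConnection(lines[!startsWith(lines, "#")]),
                   stringsAsFactors = FALSE)
  HalfLifeTable(setNames(df[[2]], df[[1]]), units = units, datasetTag = tag)
}

#' @rdname coexpressionIO
#' @param coexpr data.frame with columns `a`, `b`, `r`.
#' @export
writeCoexpression <- function(coexpr, path) {
  .writeTsv(setNames(coexpr[, 1:3], c("id_a", "id_b", "pearson_r")), path)
}

#' Read/write pairwise co-expression tables
#'
#' Tab-separated `id_a`, `id_b`, `pearson_r` (Pearson correlation of the
#' two genes' mRNA expression profiles).
#'
#' @param path file path.
#' @return `readCoexpression`: data.frame with columns `a`, `b`, `r`.
#' @name coexpressionIO
#' @export
readCoexpression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df[, 1:3], c("a", "b", "r"))
}

#' @rdname motifTableIO
#' @param motifs data.frame with columns `substrate_id`, `motif_id`,
#'   `category`, `start`, `end`.
#' @export
writeMotifTable <- function(motifs, path) {
  .writeTsv(motifs, path)
}

#' Read/write ELM-style motif tables
#'
#' Tab-separated `substrate_id`, `motif_id`, `category` (one of
#' modification/docking/ligand_binding/targeting/cleavage), `start`,
#' `end`.
#'
#' @param path file path.
#' @return `readMotifTable`: the motif data.frame.
#' @name motifTableIO
#' @export
readMotifTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("substrate_id", "motif_id", "category", "start", "end")
  if (!all(need %in% names(df)))
    stopInput("%s: motif table needs columns %s", path,
              paste(need, collapse = ", "))
  df
}

#' Compute a pairwise co-expression table from an expression matrix
#'
#' Optional Pearson path: computes the correlation of expression profiles
#' (matrix rows = genes, columns = conditions) for the requested pairs.
#'
#' @param expr numeric matrix, genes x conditions.
#' @param pairs data.frame with columns `a`, `b`; defaults to all gene
#'   pairs.
#' @return data.frame `a`, `b`, `r`.
#' @export
coexpressionFromMatrix <- function(expr, pairs = NULL) {
  if (is.null(pairs)) {
    cp <- utils::combn(rownames(expr), 2)
    pairs <- data.frame(a = cp[1, ], b = cp[2, ], stringsAsFactors = FALSE)
  }
  pairs$r <- vapply(seq_len(nrow(pairs)), function(i)
    stats::cor(expr[pairs$a[[i]], ], expr[pairs$b[[i]], ]), 1)
  pairs
}
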