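## Synthetic-data generators. Each operation draws from its own RNG stream
## derived from the master seed (see utils.R), so adding or rerunning one
## generator never perturbs another's output.

#' Simulate substrates with embedded tripartite degrons
#'
#' Each substrate gets a random amino-acid sequence of length 200-800, one
#' primary degron (6-14 residues), one Ubsite lysine, and a per-residue
#' disorder profile built from piecewise-constant blocks (ordered blocks
#' around 0.25, disordered around 0.75) with bounded additive noise, so
#' threshold-0.5 runs coincide exactly with the planted blocks. A
#' qualifying disordered block of >= 20 residues is planted at or near the
#' Ubsite; the run nearest the Ubsite (upstream on ties) is recorded as
#' the true tertiary degron.
#'
#' @param cfg a [synthConfig()] object.
#' @return list with
#'   \describe{
#'     \item{substrates}{data.frame `substrate_id`, `length`, `sequence`.}
#'     \item{degrons}{degron annotation data.frame (`substrate_id`,
#'       `degron_class`, `start`, `end`, `sequence`, `ubsite`,
#'       `provenance`): one primary, one secondary (the Ubsite as a
#'       single-residue region) and one tertiary per substrate.}
#'     \item{profiles}{named list of numeric disorder profiles.}
#'     \item{truth}{data.frame of true tertiary regions per substrate.}
#'   }
#' @export
simulateSubstrates <- function(cfg) {
  .validateSynthConfig(cfg)
  withStream(cfg$seed, "substrates", {
    aa <- aaAlphabet()
    subs <- vector("list", cfg$n_substrates)
    degrons <- vector("list", cfg$n_substrates)
    profiles <- list()
    truth <- vector("list", cfg$n_substrates)
    for (i in seq_len(cfg$n_substrates)) {
      id <- sprintf("S%03d", i)
      len <- sample(200:800, 1)
      seqv <- sample(aa, len, replace = TRUE)
      ## Ubsite and the planted tertiary block near it
      ub <- sample(floor(0.3 * len):ceiling(0.7 * len), 1)
      seqv[ub] <- "K"
      blockLen <- sample(20:60, 1)
      offset <- sample(-10:10, 1)
      tstart <- clamp(ub + offset - floor(blockLen / 2), 1, len - blockLen + 1)
      tend <- tstart + blockLen - 1L
      ## primary degron: 6-14 residues, outside the planted block when
      ## possible (placement is unconstrained biology-wise)
      plen <- sample(6:14, 1)
      pstart <- sample(seq_len(len - plen + 1), 1)
      pend <- pstart + plen - 1L
      ## disorder profile: ordered baseline + planted disordered blocks
      profile <- runif(len, 0.10, 0.40)
      profile[tstart:tend] <- runif(blockLen, 0.60, 0.90)
      ## occasionally plant extra disordered blocks (some sub-threshold
      ## length) elsewhere, separated from the main block
      nExtra <- sample(0:2, 1)
      for (k in seq_len(nExtra)) {
        elen <- sample(c(8:15, 20:40), 1)
        for (try in 1:25) {
          es <- sample(seq_len(max(1L, len - elen + 1L)), 1)
          ee <- es + elen - 1L
          if (ee < tstart - 3L || es > tend + 3L) {
            profile[es:ee] <- runif(elen, 0.60, 0.90)
            break
          }
        }
      }
      ## true tertiary region: nearest >= 20 run to the Ubsite (upstream
      ## on ties), from the noiseless block structure = threshold runs
      tt <- inferTertiaryDegron(profile, ub, minRun = 20, threshold = 0.5)
      subs[[i]] <- data.frame(substrate_id = id, length = len,
                              sequence = paste(seqv, collapse = ""),
                              stringsAsFactors = FALSE)
      degrons[[i]] <- data.frame(
        substrate_id = id,
        degron_class = c("primary", "secondary", "tertiary"),
        start = c(pstart, ub, tt$start),
        end = c(pend, ub, tt$end),
        sequence = c(paste(seqv[pstart:pend], collapse = ""), "K", NA),
        ubsite = c(NA, ub, NA),
        provenance = c("experimental", "experimental", "inferred"),
        stringsAsFactors = FALSE)
      profiles[[id]] <- profile
      truth[[i]] <- data.frame(substrate_id = id, start = tt$start,
                               end = tt$end, ubsite = ub,
                               stringsAsFactors = FALSE)
    }
    list(substrates = do.call(rbind, subs),
         degrons = do.call(rbind, degrons),
         profiles = profiles,
         truth = do.call(rbind, truth))
  })
}

## partners flagged with UPS-branch GO terms; drawn from a dedicated
## stream so the interaction and GO generators agree without coupling
upsPartnerIds <- function(cfg) {
  allPartners <- unlist(lapply(seq_len(cfg$n_substrates), function(i)
    sprintf("S%03d_P%02d", i, seq_len(cfg$n_partners_per_substrate))),
    use.names = FALSE)
  withStream(cfg$seed, "ups", {
    nUps <- round(cfg$ups_fraction * length(allPartners))
    sort(sample(allPartners, nUps))
  })
}

#' Simulate interaction records with masking and non-masking features
#'
#' For each substrate, generates `n_partners_per_substrate` partners plus
#' one E3 ligase. A Bernoulli(`masking_fraction`) subset of partners
#' carries a binding feature overlapping one of the substrate's degrons;
#' the rest carry a feature positioned with no relation (gap > window) to
#' any degron, or no feature at all. Confidence scores come from a
#' two-component mixture with a known below-0.3 subset, and a known subset
#' of partners is UPS-flagged (see [upsPartnerIds()]). The E3 binds the
#' primary degron and is UPS-flagged by construction.
#'
#' @param cfg a [synthConfig()] object.
#' @param substrates,degrons output of [simulateSubstrates()].
#' @param window adjacency window used when placing unrelated features
#'   (default 10).
#' @return list with
#'   \describe{
#'     \item{records}{data.frame: `substrate_id`, `partner_id`,
#'       `interaction_id`, `confidence`, `feature_kind`, `start`, `end`
#'       (NA coordinates = no mapped feature).}
#'     \item{maskingPairs}{planted masking (substrate, partner) pairs.}
#'     \item{recoverablePairs}{the subset with confidence >= 0.3 and a
#'       non-UPS partner (what the filtered census should recover).}
#'     \item{modules}{list of [regulatoryModule()]s (substrate, its E3,
#'       its recoverable masking partners as APs).}
#'     \item{lowConfidencePairs, upsPartners}{the planted known subsets.}
#'   }
#' @export
simulateInteractions <- function(cfg, substrates, degrons, window = 10) {
  .validateSynthConfig(cfg)
  ups <- upsPartnerIds(cfg)
  kinds <- c("sufficient_binding_region", "binding_associated_region",
             "necessary_binding_region", "mutation_evidence")
  withStream(cfg$seed, "interactions", {
    rows <- list(); maskPairs <- list()
    for (i in seq_len(nrow(substrates))) {
      sid <- substrates$substrate_id[[i]]
      len <- substrates$length[[i]]
      dg <- degrons[degrons$substrate_id == sid, , drop = FALSE]
      for (j in seq_len(cfg$n_partners_per_substrate)) {
        pid <- sprintf("%s_P%02d", sid, j)
        iid <- sprintf("I-%s-%02d", sid, j)
        conf <- if (runif(1) < cfg$low_conf_fraction)
          round(runif(1, 0.05, 0.29), 3) else round(runif(1, 0.35, 0.95), 3)
        isMasking <- runif(1) < cfg$masking_fraction
        kind <- sample(kinds, 1, prob = c(0.4, 0.3, 0.15, 0.15))
        if (isMasking) {
          d <- dg[sample(nrow(dg), 1), ]
          fs <- max(1L, d$start - sample(0:5, 1))
          fe <- min(len, d$end + sample(0:5, 1))
          rows[[length(rows) + 1L]] <- data.frame(
            substrate_id = sid, partner_id = pid, interaction_id = iid,
            confidence = conf, feature_kind = kind,
            start = fs, end = fe, stringsAsFactors = FALSE)
          maskPairs[[length(maskPairs) + 1L]] <-
            data.frame(substrate_id = sid, partner_id = pid,
                       confidence = conf, stringsAsFactors = FALSE)
        } else if (runif(1) < 0.7) {
          ## unrelated feature: resample until no overlap/adjacency with
          ## any degron of this substrate
          placed <- FALSE
          for (try in 1:50) {
            flen <- sample(8:30, 1)
            fs <- sample(seq_len(len - flen + 1L), 1)
            fe <- fs + flen - 1L
            rel <- .relationVec(dg$start, dg$end, rep(fs, nrow(dg)),
                                rep(fe, nrow(dg)), window)
            if (all(rel$relation == "none")) { placed <- TRUE; break }
          }
          rows[[length(rows) + 1L]] <- if (placed) data.frame(
            substrate_id = sid, partner_id = pid, interaction_id = iid,
            confidence = conf, feature_kind = kind,
            start = fs, end = fe, stringsAsFactors = FALSE)
          else data.frame(
            substrate_id = sid, partner_id = pid, interaction_id = iid,
            confidence = conf, feature_kind = NA_character_,
            start = NA_integer_, end = NA_integer_,
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            substrate_id = sid, partner_id = pid, interaction_id = iid,
            confidence = conf, feature_kind = NA_character_,
            start = NA_integer_, end = NA_integer_, stringsAsFactors = FALSE)
        }
      }
      ## the E3 ligase: binds the primary degron, high confidence
      eid <- sprintf("%s_E3", sid)
      dp <- dg[dg$degron_class == "primary", ]
      rows[[length(rows) + 1L]] <- data.frame(
        substrate_id = sid, partner_id = eid,
        interaction_id = sprintf("I-%s-E3", sid),
        confidence = round(runif(1, 0.6, 0.95), 3),
        feature_kind = "sufficient_binding_region",
        start = dp$start, end = dp$end, stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    maskingPairs <- if (length(maskPairs)) do.call(rbind, maskPairs) else
      data.frame(substrate_id = character(), partner_id = character(),
                 confidence = numeric())
    recoverable <- maskingPairs[maskingPairs$confidence >= 0.3 &
                                  !maskingPairs$partner_id %in% ups,
                                c("substrate_id", "partner_id")]
    rownames(recoverable) <- NULL
    lowConf <- unique(records$interaction_id[records$confidence < 0.3])
    modules <- lapply(substrates$substrate_id, function(sid) {
      aps <- recoverable$partner_id[recoverable$substrate_id == sid]
      regulatoryModule(sid, sprintf("%s_E3", sid), aps)
    })
    modules <- modules[vapply(modules, function(m) length(m$aps) > 0,
                              TRUE)]
    list(records = records,
         maskingPairs = maskingPairs[, c("substrate_id", "partner_id")],
         recoverablePairs = recoverable,
         modules = modules,
         lowConfidencePairs = lowConf,
         upsPartners = ups)
  })
}

#' Simulate a GO-style DAG and gene annotations
#'
#' Builds a single-rooted biological-process DAG with `is_a` and `part_of`
#' edges: per-module branches whose leaves are the module members' shared
#' specific terms, a dedicated UPS branch (with descendants) that supplies
#' blacklist terms, a background branch of unspecific leaves, and a small
#' separate molecular-function root to exercise namespace filtering.
#' Module members are annotated with their module's shared terms (IDA/IPI)
#' plus one random background term; background genes get random background
#' terms; UPS-flagged partners get UPS-branch terms. A sprinkle of IEA
#' records exercises the evidence filter.
#'
#' @param cfg a [synthConfig()] object.
#' @return list with `dag` (a [GoDag-class]), `gaf` (data.frame `gene`,
#'   `term`, `evidence_code`), and `blacklist` (the UPS branch roots).
#' @export
simulateGoAnnotations <- function(cfg) {
  .validateSynthConfig(cfg)
  ups <- upsPartnerIds(cfg)
  withStream(cfg$seed, "go", {
    terms <- c("BP:0000001"); nm <- c("BP:0000001" = "biological_process")
    edges <- list()
    addTerm <- function(id, name, parent, relation = "is_a") {
      terms <<- c(terms, id); nm[id] <<- name
      edges[[length(edges) + 1L]] <<- data.frame(
        child = id, parent = parent, relation = relation,
        stringsAsFactors = FALSE)
    }
    ## module branches: root -> branch -> shared leaf terms
    moduleTerms <- list()
    for (m in seq_len(cfg$n_modules)) {
      br <- sprintf("BP:%07d", 100 + m)
      addTerm(br, sprintf("module %d process", m), "BP:0000001")
      leaves <- sprintf("BP:2%03d%03d", m, seq_len(cfg$semsim_shared_terms))
      for (k in seq_along(leaves))
        addTerm(leaves[[k]], sprintf("module %d leaf %d", m, k), br,
                relation = if (k == 1) "part_of" else "is_a")
      moduleTerms[[m]] <- leaves
    }
    ## UPS branch with two levels of descendants
    addTerm("BP:0009000", "protein catabolic process, UPS", "BP:0000001")
    upsKids <- sprintf("BP:%07d", 9001:9003)
    for (k in seq_along(upsKids))
      addTerm(upsKids[[k]], sprintf("UPS child %d", k), "BP:0009000")
    upsGrand <- sprintf("BP:%07d", 9011:9013)
    for (k in seq_along(upsGrand))
      addTerm(upsGrand[[k]], sprintf("UPS grandchild %d", k), upsKids[[k]])
    ## background: many shallow branches so random gene pairs are
    ## functionally unrelated (their leaves share ancestry only near the
    ## root, as in a real process ontology)
    bgLeaves <- character()
    for (br in 1:12) {
      bid <- sprintf("BP:%07d", 5000 + br)
      addTerm(bid, sprintf("background process %d", br), "BP:0000001")
      leaves <- sprintf("BP:5%03d%03d", br, 1:5)
      for (k in seq_along(leaves))
        addTerm(leaves[[k]], sprintf("background leaf %d.%d", br, k), bid,
                relation = if (k == 5) "part_of" else "is_a")
      bgLeaves <- c(bgLeaves, leaves)
    }
    ## a separate molecular-function root (namespace filter fodder)
    terms <- c(terms, "MF:0000001", "MF:0000002")
    nm["MF:0000001"] <- "molecular_function"
    nm["MF:0000002"] <- "binding"
    edges[[length(edges) + 1L]] <- data.frame(
      child = "MF:0000002", parent = "MF:0000001", relation = "is_a",
      stringsAsFactors = FALSE)
    namespace <- setNames(ifelse(startsWith(terms, "MF"),
                                 "molecular_function",
                                 "biological_process"), terms)
    dag <- new("GoDag", terms = terms, termNames = nm[terms],
               namespace = namespace,
               edges = do.call(rbind, edges), obsolete = "BP:0999999")

    gaf <- list()
    annotate <- function(gene, term, code) {
      gaf[[length(gaf) + 1L]] <<- data.frame(
        gene = gene, term = term, evidence_code = code,
        stringsAsFactors = FALSE)
    }
    ## module members: shared terms + one background extra
    for (m in seq_len(cfg$n_modules)) {
      for (k in seq_len(cfg$module_size)) {
        gene <- sprintf("M%d_P%d", m, k)
        for (t in moduleTerms[[m]])
          annotate(gene, t, sample(c("IDA", "IPI"), 1))
        annotate(gene, sample(bgLeaves, 1), "IDA")
      }
    }
    ## background genes: 3-4 scattered background terms
    for (k in seq_len(cfg$n_background)) {
      gene <- sprintf("B%03d", k)
      for (t in sample(bgLeaves, sample(3:4, 1)))
        annotate(gene, t, sample(c("IDA", "IPI"), 1))
    }
    ## UPS-flagged partners: one UPS term (often a descendant, so the
    ## blacklist closure matters) plus a background term
    for (p in ups) {
      annotate(p, sample(c(upsKids, upsGrand), 1), "IDA")
      annotate(p, sample(bgLeaves, 1), "IDA")
    }
    ## non-UPS partners: background terms only
    allPartners <- unlist(lapply(seq_len(cfg$n_substrates), function(i)
      sprintf("S%03d_P%02d", i, seq_len(cfg$n_partners_per_substrate))),
      use.names = FALSE)
    for (p in setdiff(allPartners, ups))
      for (t in sample(bgLeaves, 2))
        annotate(p, t, "IDA")
    ## E3s are UPS machinery by definition
    for (i in seq_len(cfg$n_substrates))
      annotate(sprintf("S%03d_E3", i), "BP:0009000", "IDA")
    ## evidence/namespace filter fodder
    annotate("M1_P1", "MF:0000002", "IDA")
    annotate("B001", sample(bgLeaves, 1), "IEA")
    list(dag = dag, gaf = do.call(rbind, gaf), blacklist = "BP:0009000")
  })
}

#' Simulate ELM-style motif annotations
#'
#' Places short linear motifs (3-20 residues) on the substrates: per
#' substrate, a handful of motifs with known relation to the degrons --
#' some overlapping a degron, some adjacent (within the window), some
#' unrelated -- with functional categories sampled in the proportions
#' typical of curated motif classes (modification and docking most
#' common).
#'
#' @param cfg a [synthConfig()] object.
#' @param substrates,degrons output of [simulateSubstrates()].
#' @param window adjacency window used for placement (default 10).
#' @return data.frame `substrate_id`, `motif_id`, `category`, `start`,
#'   `end`, plus a `planted_relation` column recording the intended
#'   relation class for ground-truth checks.
#' @export
simulateMotifs <- function(cfg, substrates, degrons, window = 10) {
  .validateSynthConfig(cfg)
  categories <- c("modification", "docking", "ligand_binding", "targeting",
                  "cleavage")
  withStream(cfg$seed, "motifs", {
    rows <- list()
    for (i in seq_len(nrow(substrates))) {
      sid <- substrates$substrate_id[[i]]
      len <- substrates$length[[i]]
      dg <- degrons[degrons$substrate_id == sid, , drop = FALSE]
      nMotifs <- sample(2:5, 1)
      for (j in seq_len(nMotifs)) {
        mlen <- sample(3:20, 1)
        intent <- sample(c("overlap", "adjacent", "none"), 1,
                         prob = c(0.4, 0.3, 0.3))
        d <- dg[sample(nrow(dg), 1), ]
        pos <- switch(intent,
          overlap = sample(max(1L, d$start - mlen + 1L):min(d$end,
                                                            len - mlen + 1L),
                           1),
          adjacent = {
            gap <- sample(0:window, 1)
            cand <- c(d$start - gap - mlen, d$end + gap + 1L)
            cand <- cand[cand >= 1 & cand + mlen - 1L <= len]
            if (length(cand)) sample(cand, 1) else NA_integer_
          },
          none = {
            p <- NA_integer_
            for (try in 1:40) {
              s <- sample(seq_len(len - mlen + 1L), 1)
              rel <- .relationVec(dg$start, dg$end, rep(s, nrow(dg)),
                                  rep(s + mlen - 1L, nrow(dg)), window)
              if (all(rel$relation == "none")) { p <- s; break }
            }
            p
          })
        if (is.na(pos)) next
        ## adjacency intent can be spoiled by another degron nearby; record
        ## the realized relation instead of the intent when they differ
        rows[[length(rows) + 1L]] <- data.frame(
          substrate_id = sid, motif_id = sprintf("%s_ELM%02d", sid, j),
          category = sample(categories, 1,
                            prob = c(0.35, 0.3, 0.2, 0.1, 0.05)),
          start = pos, end = pos + mlen - 1L,
          planted_relation = intent, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate PaxDb-style abundance datasets
#'
#' Per dataset, log10-ppm values are drawn around role-specific medians
#' (AP:E3 median ratio = `e3_ap_fold`), with a dataset-level latent factor
#' shared by substrates and E3s (inducing their cross-dataset
#' correlation), plus `n_filler` background proteins; each protein is
#' dropped with probability `missing_rate`, and the dataset is then
#' renormalized so ppm sums to exactly 1e6.
#'
#' @param cfg a [synthConfig()] object.
#' @param roles named character vector protein -> role (`substrate`,
#'   `e3`, `ap`); e.g. derived from [simulateInteractions()] modules.
#' @return list of [AbundanceDataset-class] objects (categories cycle
#'   through integrated / whole_organism / tissue / cell_line).
#' @export
simulateAbundanceDatasets <- function(cfg, roles) {
  .validateSynthConfig(cfg)
  if (is.null(names(roles)) || !all(roles %in% c("substrate", "e3", "ap")))
    stopInput("roles must be a named vector over substrate/e3/ap")
  med <- cfg$role_median_log_ppm
  cats <- c("integrated", "whole_organism", "tissue", "cell_line")
  withStream(cfg$seed, "abundance", {
    filler <- sprintf("F%04d", seq_len(cfg$n_filler))
    lapply(seq_len(cfg$n_datasets), function(d) {
      latent <- rnorm(1, 0, cfg$latent_log_sd)
      logAb <- vapply(seq_along(roles), function(i) {
        r <- roles[[i]]
        med[[r]] + (if (r %in% c("substrate", "e3")) latent else 0) +
          rnorm(1, 0, cfg$abundance_log_sd)
      }, 1)
      names(logAb) <- names(roles)
      fillerAb <- setNames(rnorm(cfg$n_filler, 1.5, 0.8), filler)
      ab <- 10^c(logAb, fillerAb)
      keep <- runif(length(ab)) >= cfg$missing_rate
      keep[1] <- TRUE  # never emit an empty dataset
      ab <- ab[keep]
      ab <- ab * (1e6 / sum(ab))
      AbundanceDataset(sprintf("SYNTH%03d", d), ab,
                       category = cats[((d - 1) %% 4) + 1])
    })
  })
}

#' Simulate a PPI network with planted co-degrading modules
#'
#' Modules are connected subgraphs (a backbone chain plus one short
#' chord) whose members share a module-level mean half-life with
#' coefficient of variation `within_module_halflife_cv`, so pairwise
#' ratios concentrate at or above 0.8. Background nodes form a sparse
#' random graph with independent log-normal half-lives; one bridge edge
#' ties each module into the background so the network mixes under
#' randomization. Within-module co-expression centers on
#' `within_module_coexpr`, background pairs on 0. Each module's backbone
#' chain is recorded as a planted degronon path.
#'
#' @param cfg a [synthConfig()] object.
#' @return list with `network` ([PpiNetwork-class]), `halflives`
#'   ([HalfLifeTable-class]), `coexpression` (pair data.frame `a`, `b`,
#'   `r`), and `truth` (list: `membership` named vector protein ->
#'   module id or `"background"`, `plantedPaths` list of ordered member
#'   vectors).
#' @export
simulateCodegradationNetwork <- function(cfg) {
  .validateSynthConfig(cfg)
  if (cfg$module_size < 2) stopConfig("module_size must be >= 2")
  withStream(cfg$seed, "network", {
    edges <- list(); membership <- character(); planted <- list()
    hl <- numeric()
    addEdge <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)
    for (m in seq_len(cfg$n_modules)) {
      members <- sprintf("M%d_P%d", m, seq_len(cfg$module_size))
      membership[members] <- sprintf("module%d", m)
      for (k in seq_len(cfg$module_size - 1L))
        addEdge(members[[k]], members[[k + 1L]])
      if (cfg$module_size >= 4)
        ## one chord at the chain head: keeps the module diameter at
        ## module_size - 2 and leaves every backbone member on at least
        ## one maximal geodesic, so planted membership stays recoverable
        addEdge(members[[1]], members[[3]])
      planted[[m]] <- members
      mu <- rnorm(1, log(60), 0.5)
      hl[members] <- exp(mu) *
        exp(rnorm(cfg$module_size, 0, cfg$within_module_halflife_cv))
    }
    bg <- sprintf("B%03d", seq_len(cfg$n_background))
    membership[bg] <- "background"
    hl[bg] <- exp(rnorm(cfg$n_background, log(60),
                        cfg$background_halflife_logsd))
    ## sparse background graph at the requested mean degree
    nEdges <- round(cfg$background_degree * cfg$n_background / 2)
    seen <- new.env(parent = emptyenv())
    made <- 0L
    while (made < nEdges) {
      ab <- sample(bg, 2)
      key <- paste(min(ab), max(ab), sep = "\r")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        addEdge(ab[[1]], ab[[2]])
        made <- made + 1L
      }
    }
    ## bridge each module into the background
    for (m in seq_len(cfg$n_modules))
      addEdge(sprintf("M%d_P1", m), sample(bg, 1))
    em <- do.call(rbind, edges)
    net <- PpiNetwork(em[, 1], em[, 2])
    ## co-expression: within-module pairs high, background edges near 0
    cox <- list()
    for (m in seq_len(cfg$n_modules)) {
      members <- planted[[m]]
      cp <- utils::combn(members, 2)
      cox[[length(cox) + 1L]] <- data.frame(
        a = cp[1, ], b = cp[2, ],
        r = clamp(rnorm(ncol(cp), cfg$within_module_coexpr, 0.08), -1, 1),
        stringsAsFactors = FALSE)
    }
    ed <- networkEdges(net)
    inModule <- membership[ed$a] != "background" &
      membership[ed$a] == membership[ed$b]
    bgEd <- ed[!inModule, , drop = FALSE]
    cox[[length(cox) + 1L]] <- data.frame(
      a = bgEd$a, b = bgEd$b,
      r = clamp(rnorm(nrow(bgEd), 0, 0.15), -1, 1),
      stringsAsFactors = FALSE)
    coexpression <- do.call(rbind, cox)
    key <- paste(pmin(coexpression$a, coexpression$b),
                 pmax(coexpression$a, coexpression$b), sep = "\r")
    coexpression <- coexpression[!duplicated(key), , drop = FALSE]
    rownames(coexpression) <- NULL
    list(network = net,
         halflives = HalfLifeTable(hl, units = "relative",
                                   datasetTag = "synthetic"),
         coexpression = coexpression,
         truth = list(membership = membership, plantedPaths = planted))
  })
}
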