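test_that("S-values decay along the chain with the is_a weight", {
  dag <- chainDag()  # b -is_a-> a -is_a-> root
  s <- computeSValues("b", dag)
  expect_equal(s[["b"]], 1)
  expect_equal(s[["a"]], 0.8)
  expect_equal(s[["root"]], 0.64)
  expect_equal(computeSValues("root", dag), c(root = 1))
})

test_that("term similarity reproduces the hand-computed chain value", {
  dag <- chainDag()
  # SV(b) = 2.44, SV(a) = 1.8; common {a, root}
  expect_equal(termSimilarity("b", "a", dag), 3.24 / 4.24)
  expect_equal(termSimilarity("b", "a", dag), termSimilarity("a", "b", dag))
  expect_equal(termSimilarity("b", "b", dag), 1)
})

test_that("diamond ancestors take the max over path products", {
  # t -> {m1 (is_a), m2 (part_of)} -> root: root via m1 = 0.64, via m2 = 0.36
  dag <- new("GoDag", terms = c("root", "m1", "m2", "t"),
             termNames = setNames(c("root", "m1", "m2", "t"),
                                  c("root", "m1", "m2", "t")),
             namespace = setNames(rep("biological_process", 4),
                                  c("root", "m1", "m2", "t")),
             edges = data.frame(
               child = c("t", "t", "m1", "m2"),
               parent = c("m1", "m2", "root", "root"),
               relation = c("is_a", "part_of", "is_a", "part_of"),
               stringsAsFactors = FALSE),
             obsolete = character())
  s <- computeSValues("t", dag)
  expect_equal(s[["m1"]], 0.8)
  expect_equal(s[["m2"]], 0.6)
  expect_equal(s[["root"]], max(0.8 * 0.8, 0.6 * 0.6))
})

test_that("implementation agrees with the recursive oracle on random DAGs", {
  for (seed in 1:20) {
    dag <- randomDag(sample(5:30, 1), seed = 1000 + seed)
    terms <- goTerms(dag)
    picks <- matrix(sample(terms, 6, replace = TRUE), ncol = 2)
    for (k in seq_len(nrow(picks))) {
      t1 <- picks[k, 1]; t2 <- picks[k, 2]
      expect_equal(termSimilarity(t1, t2, dag), oracleTermSim(t1, t2, dag),
                   tolerance = 1e-9)
    }
  }
})

test_that("gene similarity is 1 for identical sets and matches BMA oracle", {
  dag <- randomDag(20, seed = 77)
  terms <- goTerms(dag)
  ann <- new("GeneAnnotation",
             annotations = list(g1 = terms[c(3, 7)],
                                g2 = terms[c(3, 7)],
                                g3 = terms[c(4, 9, 12)]),
             evidenceCodes = c("IDA", "IPI"),
             namespace = "biological_process")
  expect_equal(geneSimilarity("g1", "g2", ann, dag), 1)
  # brute-force max-row/max-column average on the 2x3 case
  m <- outer(terms[c(3, 7)], terms[c(4, 9, 12)],
             Vectorize(function(a, b) oracleTermSim(a, b, dag)))
  bma <- (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
  expect_equal(geneSimilarity("g1", "g3", ann, dag), bma, tolerance = 1e-9)
  expect_equal(geneSimilarity("g1", "g3", ann, dag),
               geneSimilarity("g3", "g1", ann, dag))
  expect_true(is.na(geneSimilarity("g1", "unknown", ann, dag)))
})

test_that("chain-DAG gene similarity equals the single best match", {
  dag <- chainDag()
  ann <- new("GeneAnnotation", annotations = list(gb = "b", ga = "a"),
             evidenceCodes = c("IDA", "IPI"),
             namespace = "biological_process")
  expect_equal(geneSimilarity("gb", "ga", ann, dag), 3.24 / 4.24)
})

test_that("dropping a shared term never increases BMA gene similarity", {
  set.seed(4)
  for (rep in 1:15) {
    dag <- randomDag(18, seed = 400 + rep)
    terms <- goTerms(dag)
    shared <- sample(terms, 3)
    extra1 <- sample(setdiff(terms, shared), 2)
    extra2 <- sample(setdiff(terms, c(shared, extra1)), 2)
    annFull <- new("GeneAnnotation",
                   annotations = list(g1 = c(shared, extra1),
                                      g2 = c(shared, extra2)),
                   evidenceCodes = "IDA", namespace = "biological_process")
    annLess <- new("GeneAnnotation",
                   annotations = list(g1 = c(shared[-1], extra1),
                                      g2 = c(shared, extra2)),
                   evidenceCodes = "IDA", namespace = "biological_process")
    expect_gte(geneSimilarity("g1", "g2", annFull, dag) + 1e-12,
               geneSimilarity("g1", "g2", annLess, dag))
  }
})

test_that("evidence and namespace filtering keeps only IDA/IPI BP records", {
  cfg <- tinyConfig()
  goa <- simulateGoAnnotations(cfg)
  gaf <- goa$gaf
  ann <- filterAnnotations(gaf, goa$dag)
  ns <- goNamespace(goa$dag)
  manual <- gaf[gaf$evidence_code %in% c("IDA", "IPI") &
                  ns[gaf$term] == "biological_process", ]
  manualSets <- lapply(split(manual$term, manual$gene),
                       function(t) sort(unique(t)))
  expect_equal(ann@annotations[sort(names(manualSets))],
               manualSets[sort(names(manualSets))])
  # the IEA-only and MF-only contributions must be gone
  expect_false("MF:0000002" %in% unlist(ann@annotations))
})

test_that("obsolete and unknown terms are dropped with warnings", {
  dag <- chainDag()
  rec <- data.frame(gene = c("g1", "g1", "g2"),
                    term = c("b", "zz_unknown", "a"),
                    evidence_code = "IDA", stringsAsFactors = FALSE)
  expect_warning(ann <- filterAnnotations(rec, dag), "unknown")
  expect_equal(geneTerms(ann, "g1"), "b")
})

test_that("cross-namespace term comparison is an input error", {
  cfg <- tinyConfig()
  dag <- simulateGoAnnotations(cfg)$dag
  expect_error(termSimilarity("BP:0000001", "MF:0000002", dag),
               class = "degronon_input_error")
})
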