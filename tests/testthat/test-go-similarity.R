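# OBO loading and Wang graph-based semantic similarity.

chain_obo <- c(
  "format-version: 1.2", "",
  "[Term]", "id: T:C", "name: root", "namespace: biological_process", "",
  "[Term]", "id: T:B", "name: mid", "namespace: biological_process",
  "is_a: T:C", "",
  "[Term]", "id: T:A", "name: leaf", "namespace: biological_process",
  "is_a: T:B", "",
  "[Term]", "id: T:OLD", "name: gone", "namespace: biological_process",
  "is_a: T:C", "is_obsolete: true", "",
  "[Term]", "id: T:REG", "name: regulator", "namespace: biological_process",
  "relationship: regulates T:C", "")

test_that("OBO terms load with is_a/part_of edges only, obsoletes dropped", {
  g <- load_obo_text(chain_obo)
  expect_setequal(g$terms$id, c("T:C", "T:B", "T:A", "T:REG"))
  expect_equal(sum(vapply(g$parents, nrow, 0L)), 2L)  # chain edges only
  expect_null(g$parents[["T:REG"]])  # unknown relationship ignored, term kept

  cyc <- c("format-version: 1.2", "",
           "[Term]", "id: T:X", "namespace: biological_process",
           "is_a: T:Y", "",
           "[Term]", "id: T:Y", "namespace: biological_process",
           "is_a: T:X", "")
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(cyc, f)
  expect_error(load_ontology(f), "cycle")
})

test_that("S-values decay along the ancestor chain and take path maxima", {
  g <- load_obo_text(chain_obo)
  w <- contribution_weights(is_a = 0.8, part_of = 0.6)
  expect_equal(s_values("T:C", g, w), c("T:C" = 1))
  expect_equal(s_values("T:A", g, w),
               c("T:A" = 1, "T:B" = 0.8, "T:C" = 0.64))

  # diamond: two paths to the root, S takes the maximum
  diamond <- c("format-version: 1.2", "",
    "[Term]", "id: T:R", "namespace: biological_process", "",
    "[Term]", "id: T:P1", "namespace: biological_process", "is_a: T:R", "",
    "[Term]", "id: T:P2", "namespace: biological_process",
    "relationship: part_of T:R", "",
    "[Term]", "id: T:A", "namespace: biological_process",
    "is_a: T:P1", "relationship: part_of T:P2", "")
  gd <- load_obo_text(diamond)
  S <- s_values("T:A", gd, w)
  # via is_a/is_a: 0.8*0.8 = 0.64; via part_of/part_of: 0.36 -> max wins
  expect_equal(S[["T:R"]], 0.64)
  expect_equal(S, s_values_oracle("T:A", gd, w)[names(S)])
})

test_that("term and gene similarities are bounded, symmetric, 1 on identity", {
  g <- load_obo_text(chain_obo)
  w <- contribution_weights()
  expect_equal(term_similarity("T:A", "T:A", g, w), 1)
  expect_equal(term_similarity("T:A", "T:B", g, w),
               term_similarity("T:B", "T:A", g, w))
  expect_error(term_similarity("T:A", "T:ZZ", g, w), "unknown term")

  expect_equal(gene_similarity("T:A", "T:A", g, w), 1)
  und <- gene_similarity(character(0), "T:A", g, w)
  expect_true(is.na(und))
  expect_equal(attr(und, "reason"), "unannotated_gene")
})

test_that("Wang computations match brute-force path enumeration on toy DAGs", {
  w <- contribution_weights()
  for (seed in 1:20) {
    g <- load_obo_text(random_toy_obo(seed))
    ids <- g$terms$id
    for (t in ids) {
      S <- s_values(t, g, w)
      oracle <- s_values_oracle(t, g, w)
      expect_equal(S[sort(names(S))], oracle[sort(names(oracle))],
                   tolerance = 1e-14, info = paste("seed", seed, "term", t))
    }
    pairs <- utils::combn(ids, 2)
    for (k in seq_len(ncol(pairs))) {
      t1 <- pairs[1, k]; t2 <- pairs[2, k]
      s12 <- term_similarity(t1, t2, g, w)
      expect_equal(s12, term_similarity_oracle(t1, t2, g, w),
                   tolerance = 1e-14)
      expect_equal(s12, term_similarity(t2, t1, g, w))
      expect_gte(s12, 0); expect_lte(s12, 1)
      expect_equal(term_similarity(t1, t1, g, w), 1)
    }
    # gene-level aggregation against an exhaustive oracle
    set.seed(seed + 1000)
    for (r in 1:5) {
      ta <- sample(ids, sample(1:3, 1))
      tb <- sample(ids, sample(1:3, 1))
      gs <- gene_similarity(ta, tb, g, w)
      expect_equal(gs, gene_similarity_oracle(ta, tb, g, w),
                   tolerance = 1e-14)
      expect_gte(gs, 0); expect_lte(gs, 1)
    }
  }
})

test_that("group similarity respects the size cap and tracks IEA content", {
  g <- load_obo_text(chain_obo)
  ann <- data.frame(gene_id = c("gA", "gB", "gA", "gB"),
                    term_id = c("T:A", "T:A", "T:B", "T:B"),
                    evidence = c("IEA", "IEA", "IEA", "IEA"),
                    aspect = "biological_process",
                    stringsAsFactors = FALSE)
  gs <- group_semantic_similarity(c("gA", "gB"), ann, g)
  expect_equal(gs$pairs$similarity, 1)  # identically annotated genes
  expect_equal(gs$iea_proportion, 1.0)

  over <- group_semantic_similarity(sprintf("g%02d", 1:16), ann, g, cap = 15)
  expect_equal(over$skipped_reason, "group_size_exceeds_cap")

  # one annotated gene only: no comparison in that namespace
  solo <- group_semantic_similarity(c("gA", "gX"), ann, g)
  expect_null(solo$pairs)
})

test_that("NOT-qualified annotations are dropped on read, aspects normalised", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gA\tT:A\tIEA\tP\t",
               "gB\tT:A\tEXP\tP\tNOT",
               "gC\tT:B\tIDA\tmolecular_function\t"), f)
  ann <- read_annotations(f)
  expect_equal(nrow(ann), 2L)
  expect_false("gB" %in% ann$gene_id)
  expect_setequal(unique(ann$aspect),
                  c("biological_process", "molecular_function"))
})
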