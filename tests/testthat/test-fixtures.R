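# Synthetic-fixture generators: determinism, planted structure, emitted
# formats.

test_that("genome generation is reproducible and plants families as stated", {
  spec <- fixture_spec(n_chromosomes = 2, genes_per_chromosome = 40,
                       n_families = 4, family_sizes = 3, divergence = 0)
  a <- generate_genome(spec, seed = 5)
  b <- generate_genome(spec, seed = 5)
  expect_identical(a, b)
  c <- generate_genome(spec, seed = 6)
  expect_false(identical(a, c))

  # divergence 0: identical peptides at adjacent ranks
  idx <- build_gene_index(a$genes)
  for (f in unique(a$truth$family_id)) {
    members <- a$truth$gene_id[a$truth$family_id == f]
    seqs <- a$peptides$sequence[match(members, a$peptides$gene_id)]
    expect_equal(length(unique(seqs)), 1L)
    ranks <- sort(idx$rank[match(members, idx$gene_id)])
    expect_equal(diff(ranks), rep(1L, 2L))
  }
})

test_that("peptide mutation substitutes an exact position count", {
  set.seed(10)
  seq <- random_aa(1, 100)
  expect_identical(mutate_peptide(seq, 0), seq)
  mut <- mutate_peptide(seq, 0.1, seed = 3)
  expect_equal(nchar(mut), 100L)
  diffs <- sum(strsplit(seq, "")[[1]] != strsplit(mut, "")[[1]])
  expect_equal(diffs, 10L)  # identity 1 - divergence by construction
  expect_identical(mutate_peptide(seq, 0.1, seed = 3), mut)
})

test_that("high-divergence families are not recovered (negative control)", {
  spec <- fixture_spec(n_chromosomes = 1, genes_per_chromosome = 30,
                       n_families = 2, family_sizes = 3, divergence = 0.8)
  fix <- generate_genome(spec, seed = 12)
  det <- run_detect(fix$genes, fix$peptides)
  expect_equal(det$summary$n_groups, 0L)
})

test_that("expression fixtures carry the planted correlation structure", {
  genes <- sprintf("g%02d", 1:10)
  groups <- list(c("g01", "g02", "g03"))

  # rho = 1, no noise: member profiles identical
  spec1 <- fixture_spec(n_datasets = 2, n_samples = 8, rho = 1)
  ds <- generate_expression(groups, genes, spec1, seed = 4)
  expect_length(ds, 2L)
  expect_equal(ds[[1]]$mat["g01", ], ds[[1]]$mat["g02", ])

  # empirical mean pairwise r within groups approaches rho at large n
  spec2 <- fixture_spec(n_datasets = 1, n_samples = 1000, rho = 0.6)
  big <- generate_expression(groups, genes, spec2, seed = 5)[[1]]
  r <- cor(t(big$mat[groups[[1]], ]))
  expect_equal(mean(r[upper.tri(r)]), 0.6, tolerance = 0.08)

  # rho = 0: members uncorrelated
  spec0 <- fixture_spec(n_datasets = 1, n_samples = 1000, rho = 0)
  null <- generate_expression(groups, genes, spec0, seed = 6)[[1]]
  r0 <- cor(t(null$mat[groups[[1]], ]))
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.15)

  # missing values injected at the stated rate
  specm <- fixture_spec(n_datasets = 1, n_samples = 50, missing_rate = 0.2)
  miss <- generate_expression(groups, genes, specm, seed = 7)[[1]]
  expect_equal(mean(is.na(miss$mat)), 0.2, tolerance = 0.05)
})

test_that("toy ontologies have the regular-tree size and planted clustering", {
  spec <- fixture_spec(ontology_depth = 3, ontology_branching = 2)
  groups <- list(c("gA", "gB"), c("gC", "gD"))
  onto <- generate_ontology(groups, sprintf("r%02d", 1:10), spec, seed = 9,
                            namespaces = "biological_process")
  g <- load_obo_text(onto$obo)
  expect_equal(nrow(g$terms), 15L)  # 2^4 - 1

  # genes annotated to the same leaf are maximally similar
  leaf <- g$terms$id[nrow(g$terms)]
  expect_equal(gene_similarity(leaf, leaf, g), 1)

  # clustered annotations score higher on average than uniform ones
  ann <- onto$annotations
  by_gene <- split(ann$term_id, ann$gene_id)
  mean_sim <- function(gene_sets) {
    pr <- utils::combn(gene_sets, 2)
    mean(vapply(seq_len(ncol(pr)), function(k)
      gene_similarity(by_gene[[pr[1, k]]], by_gene[[pr[2, k]]], g), 0))
  }
  clustered <- mean(c(mean_sim(groups[[1]]), mean_sim(groups[[2]])))
  uniform <- mean_sim(sprintf("r%02d", 1:6))
  expect_gt(clustered, uniform)
})

test_that("a written fixture directory feeds the full pipeline", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(n_chromosomes = 1, genes_per_chromosome = 30,
                       n_families = 3, family_sizes = 2,
                       n_datasets = 3, n_samples = 6)
  write_fixture(spec, dir, seed = 21)
  expect_true(all(file.exists(file.path(dir,
    c("genes.tsv", "peptides.fa", "truth.tsv", "ontology.obo",
      "annotations.tsv")))))
  det <- run_detect(file.path(dir, "genes.tsv"), file.path(dir, "peptides.fa"))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_setequal(unlist(det$groups$members), truth$gene_id)
  res <- run_characterise(det$groups, det$index,
                          datasets = file.path(dir, "expression"),
                          obo = file.path(dir, "ontology.obo"),
                          gaf = file.path(dir, "annotations.tsv"))
  expect_equal(nrow(res$correlation), det$summary$n_groups)
  expect_true(all(res$go$mean_similarity >= 0 & res$go$mean_similarity <= 1))
})
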