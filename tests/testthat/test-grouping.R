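# Windowed pair discovery, closest-downstream linking, transitive grouping
# and summaries.

same_pep_index <- function(n, chromosome = "chr1", seq = NULL) {
  genes <- make_gene_table(n, chromosome = chromosome)
  idx <- build_gene_index(genes)
  seq <- seq %||% strrep("MKVLAWTRPQ", 20)
  peps <- make_peptides(genes$gene_id, rep(seq, n))
  list(idx = idx, peps = peps)
}

test_that("each gene links to its closest passing downstream hit", {
  f <- same_pep_index(3)
  pairs <- find_duplicate_pairs(f$idx, f$peps)
  got <- paste(pairs$gene_a, pairs$gene_b)
  expect_setequal(got, c("g01 g02", "g02 g03"))  # not (g01, g03)
  expect_equal(pairs$rank_distance, c(1L, 1L))
})

test_that("the window and the chromosome bound the search", {
  # identical peptides 150 ranks apart with window 100: no pair
  genes <- make_gene_table(151)
  idx <- build_gene_index(genes)
  peps <- make_peptides(c("g01", sprintf("g%02d", 151)),
                        rep(strrep("MKVLAWTRPQ", 20), 2))
  expect_warning(pairs <- find_duplicate_pairs(idx, peps), "without a peptide")
  expect_equal(nrow(pairs), 0L)

  # identical peptides on different chromosomes: no pair
  g1 <- same_pep_index(2, "chr1")
  g2 <- same_pep_index(2, "chr2")
  genes <- rbind(as.data.frame(g1$idx)[, -8], as.data.frame(g2$idx)[, -8])
  genes$gene_id <- sprintf("g%02d", 1:4)
  idx <- build_gene_index(genes)
  peps <- make_peptides(c("g01", "g03"), rep(strrep("MKVLAWTRPQ", 20), 2))
  suppressWarnings(pairs <- find_duplicate_pairs(idx, peps))
  expect_equal(nrow(pairs), 0L)
})

test_that("rank gap 100 is inside the window, 101 outside", {
  spec <- fixture_spec(n_chromosomes = 1, genes_per_chromosome = 102,
                       n_families = 1, family_sizes = 2, divergence = 0,
                       placement_gap = 100)
  fix <- generate_genome(spec, seed = 2)
  det <- run_detect(fix$genes, fix$peptides)
  expect_equal(det$summary$n_groups, 1L)
  expect_setequal(det$groups$members[[1]], fix$truth$gene_id)

  spec101 <- fixture_spec(n_chromosomes = 1, genes_per_chromosome = 102,
                          n_families = 1, family_sizes = 2, divergence = 0,
                          placement_gap = 101)
  fix101 <- generate_genome(spec101, seed = 2)
  det101 <- run_detect(fix101$genes, fix101$peptides)
  expect_equal(det101$summary$n_groups, 0L)
})

test_that("groups are the transitive closure of the pair graph", {
  genes <- make_gene_table(4)
  idx <- build_gene_index(genes)
  pairs <- data.frame(gene_a = c("g01", "g02"), gene_b = c("g02", "g03"),
                      stringsAsFactors = FALSE)
  groups <- build_groups(pairs, idx)
  expect_equal(nrow(groups), 1L)
  expect_setequal(groups$members[[1]], c("g01", "g02", "g03"))

  pairs2 <- data.frame(gene_a = c("g01", "g03"), gene_b = c("g02", "g04"))
  expect_equal(nrow(build_groups(pairs2, idx)), 2L)
})

test_that("union-find components agree with an independent graph oracle", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (rep in 1:100) {
    n <- sample(10:50, 1)
    genes <- make_gene_table(n)
    idx <- build_gene_index(genes)
    m <- sample(1:200, 1)
    pairs <- data.frame(gene_a = sample(genes$gene_id, m, replace = TRUE),
                        gene_b = sample(genes$gene_id, m, replace = TRUE),
                        stringsAsFactors = FALSE)
    pairs <- pairs[pairs$gene_a != pairs$gene_b, , drop = FALSE]
    if (nrow(pairs) == 0) next
    groups <- build_groups(pairs, idx)
    g <- igraph::graph_from_data_frame(pairs, directed = FALSE)
    comp <- igraph::components(g)
    oracle <- split(names(comp$membership), comp$membership)
    expect_setequal(
      unname(vapply(groups$members, function(x) paste(sort(x), collapse = ","), "")),
      unname(vapply(oracle, function(x) paste(sort(x), collapse = ","), "")))
  }
})

test_that("grouping output is invariant to pair order and partitions genes", {
  set.seed(44)
  genes <- make_gene_table(30)
  idx <- build_gene_index(genes)
  pairs <- data.frame(gene_a = sprintf("g%02d", sample(1:29, 40, TRUE)))
  pairs$gene_b <- sprintf("g%02d", as.integer(sub("g", "", pairs$gene_a)) + 1L)
  groups1 <- build_groups(pairs, idx)
  groups2 <- build_groups(pairs[sample(nrow(pairs)), ], idx)
  expect_identical(groups1, groups2)
  members <- unlist(groups1$members)
  expect_equal(anyDuplicated(members), 0L)  # no gene in two groups
  expect_true(all(groups1$n_genes >= 2L))
})

test_that("summaries report counts, histogram and spans in kb", {
  genes <- make_gene_table(7, start = c(1000, 2000, 59000, 100, 200,
                                        300, 1000000))
  genes$end <- genes$start + 1000
  genes$end[3] <- 60000
  idx <- build_gene_index(genes)
  groups <- data.frame(group_id = c("chr1:g01", "chr1:g04", "chr1:g06"),
                       chromosome = "chr1", n_genes = c(2L, 2L, 3L),
                       span_bp = c(59000, 10000, 1000000))
  groups$members <- list(c("g01", "g03"), c("g04", "g05"),
                         c("g02", "g06", "g07"))
  s <- summarize_groups(groups)
  expect_equal(s$n_groups, 3L)
  expect_equal(s$n_genes_in_groups, 7L)
  expect_equal(as.integer(s$size_histogram), c(2L, 1L))
  expect_equal(names(s$size_histogram), c("2", "3"))
  expect_equal(s$median_span_kb, 59)
  expect_equal(s$mean_span_kb, mean(c(59, 10, 1000)))

  # one group spanning 1,000-60,000 bp has a 59 kb span
  one <- build_groups(data.frame(gene_a = "g01", gene_b = "g03"), idx)
  expect_equal(one$span_bp, 59000)

  no_pairs <- data.frame(gene_a = character(0), gene_b = character(0))
  empty <- summarize_groups(build_groups(no_pairs, idx))
  expect_equal(empty$n_groups, 0L)
  expect_equal(empty$n_genes_in_groups, 0L)
})

test_that("a larger window never reduces the number of genes in groups", {
  spec <- fixture_spec(n_chromosomes = 2, genes_per_chromosome = 60,
                       n_families = 6, family_sizes = c(2, 3),
                       placement_gap = 4)
  fix <- generate_genome(spec, seed = 8)
  idx <- build_gene_index(fix$genes)
  peps <- select_longest_peptides(fix$peptides)
  n_in_groups <- vapply(c(2L, 4L, 10L, 100L), function(w) {
    pairs <- find_duplicate_pairs(idx, peps,
                                  params = detection_params(window = w))
    summarize_groups(build_groups(pairs, idx))$n_genes_in_groups
  }, 0L)
  expect_true(all(diff(n_in_groups) >= 0L))
})

test_that("planted families are recovered exactly on a small fixture", {
  spec <- fixture_spec(n_chromosomes = 2, genes_per_chromosome = 50,
                       n_families = 4, divergence = 0.15)
  fix <- generate_genome(spec, seed = 13)
  det <- run_detect(fix$genes, fix$peptides)
  truth <- split(fix$truth$gene_id, fix$truth$family_id)
  expect_setequal(
    unname(vapply(det$groups$members, function(x) paste(sort(x), collapse = ","), "")),
    unname(vapply(truth, function(x) paste(sort(x), collapse = ","), "")))
})
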