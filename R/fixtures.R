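# Synthetic fixtures: genomes with planted duplicate families, expression
# matrices with planted within-group correlation, and toy ontologies with
# planted annotation clustering.  Every generator is deterministic under a
# seed and returns the planted truth alongside the data, so detection and
# characterisation can be scored against a known answer.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

#' Specification of a synthetic fixture
#'
#' Defaults describe the standard test genome: 5 chromosomes of 200 genes,
#' 20 planted duplicate families (sizes cycling 2–5) whose members are
#' mutated copies of a family founder at 10% substitution divergence, placed
#' at adjacent ranks; background peptides are uniform-random sequences, far
#' below any identity threshold.  Expression fixtures plant a within-group
#' pairwise correlation of 0.9 over 20 datasets of 10 samples; ontology
#' fixtures are regular trees of depth 3 and branching 2 per namespace.
#'
#' @param n_chromosomes,genes_per_chromosome Genome shape.
#' @param n_families Number of planted duplicate families.
#' @param family_sizes Sizes assigned to families in rotation.
#' @param divergence Substitution proportion of each member vs the family
#'   founder, in \[0, 1).
#' @param placement_gap Rank gap between consecutive family members (1 =
#'   adjacent genes).
#' @param peptide_length Length range (aa) for founders and background.
#' @param n_datasets,n_samples,rho,noise_sd,missing_rate Expression fixture
#'   parameters: within-group pairwise correlation `rho`, profile scale
#'   `noise_sd`, missing-value injection rate.
#' @param ontology_depth,ontology_branching,terms_per_gene,iea_rate Toy
#'   ontology shape and annotation parameters.
#' @param seed Default seed for the generators.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_chromosomes = 5L, genes_per_chromosome = 200L,
                         n_families = 20L, family_sizes = c(2L, 3L, 4L, 5L),
                         divergence = 0.1, placement_gap = 1L,
                         peptide_length = c(150L, 400L),
                         n_datasets = 20L, n_samples = 10L, rho = 0.9,
                         noise_sd = 1, missing_rate = 0,
                         ontology_depth = 3L, ontology_branching = 2L,
                         terms_per_gene = 2L, iea_rate = 0.3,
                         seed = 1L) {
  stopifnot(divergence >= 0, divergence < 1, placement_gap >= 1,
            n_chromosomes >= 1, genes_per_chromosome >= 2,
            rho >= 0, rho <= 1, missing_rate >= 0, missing_rate < 1,
            ontology_depth >= 2, ontology_branching >= 2)
  sizes <- rep_len(family_sizes, n_families)
  if (n_families > 0 &&
      (max(sizes) - 1L) * placement_gap + 1L > genes_per_chromosome)
    stop("a planted family does not fit on a chromosome at this gap")
  structure(as.list(environment())[names(formals(fixture_spec))],
            class = "fixture_spec")
}

#' Generate a synthetic genome with planted duplicate families
#'
#' Families are assigned to chromosomes in rotation and placed at evenly
#' spaced anchor ranks, members `placement_gap` ranks apart; each member's
#' peptide is the family founder mutated at the divergence stored in `spec`.  All
#' other genes carry independent random peptides (pairwise identity far
#' below detection thresholds).  Deterministic under the seed.
#'
#' @param spec A [fixture_spec()].
#' @param seed Seed; defaults to the one stored in `spec`.
#' @return List: `genes` (gene table), `peptides` (peptide table; one
#'   peptide per gene), `truth` (data frame family_id, gene_id).
#' @export
generate_genome <- function(spec = fixture_spec(), seed = spec$seed) {
  with_seed(seed, {
    chroms <- paste0("chr", seq_len(spec$n_chromosomes))
    genes <- do.call(rbind, lapply(chroms, function(chrom) {
      m <- spec$genes_per_chromosome
      widths <- sample(500:5000, m, replace = TRUE)
      gaps <- sample(200:20000, m, replace = TRUE)
      start <- cumsum(gaps) + c(0, cumsum(widths))[1:m]
      data.frame(gene_id = sprintf("g_%s_%04d", chrom, seq_len(m)),
                 chromosome = chrom, start = start, end = start + widths,
                 strand = sample(c("+", "-"), m, replace = TRUE),
                 name = NA_character_, description = NA_character_,
                 stringsAsFactors = FALSE)
    }))
    # index position (row within chromosome block) == rank order by start
    sizes <- rep_len(spec$family_sizes, spec$n_families)
    truth <- list(); fam_rows <- integer(0)
    if (spec$n_families > 0) {
      fam_chrom <- rep_len(seq_len(spec$n_chromosomes), spec$n_families)
      for (ci in seq_len(spec$n_chromosomes)) {
        fams <- which(fam_chrom == ci)
        if (!length(fams)) next
        anchors <- floor(spec$genes_per_chromosome *
                           (seq_along(fams) - 0.5) / length(fams)) + 1L
        for (k in seq_along(fams)) {
          f <- fams[k]
          ranks <- anchors[k] + (seq_len(sizes[f]) - 1L) * spec$placement_gap
          if (max(ranks) > spec$genes_per_chromosome)
            ranks <- ranks - (max(ranks) - spec$genes_per_chromosome)
          rows <- (ci - 1L) * spec$genes_per_chromosome + ranks
          if (any(rows %in% fam_rows))
            stop("planted families overlap; reduce families or the gap")
          fam_rows <- c(fam_rows, rows)
          truth[[f]] <- data.frame(family_id = sprintf("fam%02d", f),
                                   gene_id = genes$gene_id[rows],
                                   stringsAsFactors = FALSE)
        }
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else data.frame(family_id = character(0), gene_id = character(0))
    rownames(truth) <- NULL
    lens <- sample(spec$peptide_length[1L]:spec$peptide_length[2L],
                   nrow(genes), replace = TRUE)
    sequence <- vapply(lens, random_peptide, "")
    for (f in unique(truth$family_id)) {
      members <- match(truth$gene_id[truth$family_id == f], genes$gene_id)
      founder <- random_peptide(sample(
        spec$peptide_length[1L]:spec$peptide_length[2L], 1L))
      sequence[members] <- vapply(members, function(i)
        mutate_peptide(founder, spec$divergence), "")
    }
    peptides <- data.frame(peptide_id = paste0(genes$gene_id, "_p1"),
                           gene_id = genes$gene_id, sequence = sequence,
                           stringsAsFactors = FALSE)
    list(genes = genes, peptides = peptides, truth = truth)
  })
}

#' Substitute a fixed proportion of residues in a peptide
#'
#' Exactly `round(divergence * length)` positions (half up) are replaced by
#' uniformly drawn different residues; length is preserved, so the identity
#' between original and mutant is 1 - divergence by construction.
#'
#' @param seq Amino-acid string.
#' @param divergence Substitution proportion in \[0, 1).
#' @param seed Optional seed.
#' @return Mutated sequence.
#' @export
mutate_peptide <- function(seq, divergence, seed = NULL) {
  stopifnot(divergence >= 0, divergence < 1)
  with_seed(seed, {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    k <- round_half_up(divergence * length(chars))
    if (k > 0) {
      pos <- sample(length(chars), k)
      chars[pos] <- vapply(chars[pos], function(old)
        sample(setdiff(AA20, old), 1L), "")
    }
    paste(chars, collapse = "")
  })
}

#' Generate expression datasets with planted within-group correlation
#'
#' Each dataset is a genes x samples matrix.  Members of a planted group
#' share a latent factor: a member profile is
#' `sqrt(rho) * f + sqrt(1 - rho) * e`, scaled by `noise_sd`, which gives a
#' pairwise correlation of `rho` between members in expectation; all other
#' genes are independent noise.  Missing values are injected uniformly at
#' the rate stored in `spec`.
#'
#' @param groups List of character vectors (member gene ids per group).
#' @param gene_ids All gene ids to include as rows.
#' @param spec A [fixture_spec()].
#' @param seed Seed; defaults to the one stored in `spec`.
#' @return List of [expression_dataset()] objects.
#' @export
generate_expression <- function(groups, gene_ids, spec = fixture_spec(),
                                seed = spec$seed) {
  with_seed(seed, {
    lapply(seq_len(spec$n_datasets), function(d) {
      mat <- matrix(stats::rnorm(length(gene_ids) * spec$n_samples,
                                 sd = spec$noise_sd),
                    nrow = length(gene_ids),
                    dimnames = list(gene_ids,
                                    sprintf("s%02d", seq_len(spec$n_samples))))
      for (members in groups) {
        f <- stats::rnorm(spec$n_samples)
        for (g in intersect(members, gene_ids)) {
          mat[g, ] <- spec$noise_sd *
            (sqrt(spec$rho) * f +
             sqrt(1 - spec$rho) * stats::rnorm(spec$n_samples))
        }
      }
      if (spec$missing_rate > 0) {
        drop <- stats::runif(length(mat)) < spec$missing_rate
        mat[drop] <- NA_real_
      }
      expression_dataset(sprintf("DS%02d", d), mat)
    })
  })
}

#' Generate a toy ontology and gene annotations with planted clustering
#'
#' Builds a regular tree per namespace (depth `ontology_depth`, branching
#' `ontology_branching`; edges are `is_a` except each node's last child,
#' which attaches by `part_of`) and emits it as OBO text.  Genes of planted
#' groups are annotated to leaves of a single randomly chosen depth-1
#' subtree per group ("clustered"); all other genes to uniformly random
#' leaves ("uniform").  Evidence codes are IEA with probability `iea_rate`,
#' otherwise EXP.
#'
#' @param groups List of character vectors (member gene ids per group).
#' @param background_genes Gene ids annotated uniformly.
#' @param spec A [fixture_spec()].
#' @param seed Seed; defaults to the one stored in `spec`.
#' @param namespaces Namespaces to build (default all three).
#' @return List: `obo` (character vector of OBO lines), `annotations` (data
#'   frame gene_id, term_id, evidence, aspect), `truth` (data frame gene_id,
#'   class).
#' @export
generate_ontology <- function(groups, background_genes,
                              spec = fixture_spec(), seed = spec$seed,
                              namespaces = c("biological_process",
                                             "molecular_function",
                                             "cellular_component")) {
  prefix <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")
  with_seed(seed, {
    obo <- c("format-version: 1.2", "")
    ann <- list()
    for (ns in namespaces) {
      b <- spec$ontology_branching; d <- spec$ontology_depth
      n_terms <- sum(b^(0:d))
      ids <- sprintf("%s:%04d", prefix[[ns]], seq_len(n_terms))
      parent_of <- c(NA_integer_, rep(seq_len(n_terms), each = b))[seq_len(n_terms)]
      for (i in seq_len(n_terms)) {
        obo <- c(obo, "[Term]",
                 paste0("id: ", ids[i]),
                 paste0("name: ", tolower(prefix[[ns]]), " term ", i),
                 paste0("namespace: ", ns))
        if (!is.na(parent_of[i])) {
          # below depth 1, the last child of each node attaches by part_of
          obo <- c(obo, if (i > 1L + b && (i - 2L) %% b == b - 1L)
            paste0("relationship: part_of ", ids[parent_of[i]])
          else paste0("is_a: ", ids[parent_of[i]]))
        }
        obo <- c(obo, "")
      }
      # leaves are the last b^d terms; depth-1 subtrees root at terms 2..b+1
      leaves <- ids[(n_terms - b^d + 1L):n_terms]
      subtree_leaf <- split(leaves, rep(seq_len(b), each = b^(d - 1L)))
      for (gi in seq_along(groups)) {
        sub <- sample(b, 1L)
        for (g in groups[[gi]])
          for (t in sample(subtree_leaf[[sub]],
                           min(spec$terms_per_gene, length(subtree_leaf[[sub]])),
                           replace = FALSE))
            ann[[length(ann) + 1L]] <- data.frame(
              gene_id = g, term_id = t,
              evidence = if (stats::runif(1) < spec$iea_rate) "IEA" else "EXP",
              aspect = ns, stringsAsFactors = FALSE)
      }
      for (g in background_genes)
        for (t in sample(leaves, min(spec$terms_per_gene, length(leaves))))
          ann[[length(ann) + 1L]] <- data.frame(
            gene_id = g, term_id = t,
            evidence = if (stats::runif(1) < spec$iea_rate) "IEA" else "EXP",
            aspect = ns, stringsAsFactors = FALSE)
    }
    annotations <- do.call(rbind, ann)
    truth <- data.frame(
      gene_id = c(unlist(groups), background_genes),
      class = c(rep("clustered", length(unlist(groups))),
                rep("uniform", length(background_genes))),
      stringsAsFactors = FALSE)
    list(obo = obo, annotations = annotations, truth = truth)
  })
}

#' Write a complete fixture to a directory
#'
#' Emits the same standard formats the pipeline reads: `genes.tsv`,
#' `peptides.fa`, `truth.tsv`, one expression matrix per dataset under
#' `expression/`, `ontology.obo` and `annotations.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param seed Seed; defaults to the one stored in `spec`.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(spec = fixture_spec(), dir, seed = spec$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fix <- generate_genome(spec, seed)
  write_gene_table(fix$genes, file.path(dir, "genes.tsv"))
  write_peptides(fix$peptides, file.path(dir, "peptides.fa"))
  utils::write.table(fix$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  groups <- split(fix$truth$gene_id, fix$truth$family_id)
  expr <- generate_expression(groups, fix$genes$gene_id, spec, seed + 1L)
  dir.create(file.path(dir, "expression"), showWarnings = FALSE)
  for (ds in expr)
    write_expression(ds, file.path(dir, "expression",
                                   paste0(ds$dataset_id, ".tsv")))
  onto <- generate_ontology(groups,
                            setdiff(fix$genes$gene_id, fix$truth$gene_id),
                            spec, seed + 2L)
  writeLines(onto$obo, file.path(dir, "ontology.obo"))
  utils::write.table(onto$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
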