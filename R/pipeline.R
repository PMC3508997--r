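# End-to-end stages: detection (annotation + peptides -> group tables) and
# characterisation (groups -> co-expression and GO similarity reports).
# Every output table carries a header comment with the package version and a
# hash of the effective configuration, and each stage logs its filter counts.

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(config),
                   vapply(config, function(x) paste(format(x), collapse = ","), ""),
                   sep = "="), f)
  unname(tools::md5sum(f))
}

output_comment <- function(config) {
  paste0("tandemdup ", utils::packageVersion("tandemdup"),
         " config=", config_hash(config))
}

#' Detect co-localised duplicated genes
#'
#' Full detection stage: read annotation and peptides, keep the longest
#' peptide per gene, index genes by chromosome position, find duplicate
#' pairs within the window, assemble groups by transitive closure, and write
#' gene-list and group-list tables plus a summary.  Counts at each filter
#' (peptides in, non-redundant kept, pairs scored, pairs passing, links,
#' groups, genes in groups) are logged.
#'
#' @param annotation Annotation file path, or a gene data frame.
#' @param peptides Peptide FASTA path, or a peptide data frame.
#' @param out_dir Output directory; NULL skips writing.
#' @param dialect Annotation dialect for file input.
#' @param params [detection_params()].
#' @param alignments Optional precomputed alignment file
#'   ([parse_alignment_tabular()] format) or list of alignment results.
#' @param gene_map Optional peptide-to-gene side table for
#'   [read_peptides()].
#' @param ... Passed to [find_duplicate_pairs()].
#' @return Invisibly, a list: `index`, `pairs`, `groups`, `summary`,
#'   `report`.
#' @export
run_detect <- function(annotation, peptides, out_dir = NULL,
                       dialect = "tsv", params = detection_params(),
                       alignments = NULL, gene_map = NULL, ...) {
  genes <- if (is.character(annotation))
    read_gene_annotation(annotation, dialect) else annotation
  peps <- if (is.character(peptides))
    read_peptides(peptides, gene_map) else peptides
  if (is.character(alignments)) {
    lens <- stats::setNames(nchar(peps$sequence), peps$peptide_id)
    alignments <- parse_alignment_tabular(alignments, seq_lengths = lens)
  }
  n_in <- nrow(peps)
  peps <- select_longest_peptides(peps)
  index <- build_gene_index(genes)
  pairs <- find_duplicate_pairs(index, peps, params = params,
                                alignments = alignments, ...)
  groups <- build_groups(pairs, index)
  summary <- summarize_groups(groups)
  report <- attr(pairs, "report")
  report$n_peptides_in <- n_in
  report$n_peptides_kept <- nrow(peps)
  message("peptides in: ", n_in,
          " | non-redundant kept: ", nrow(peps),
          " | pairs scored: ", report$n_pairs_scored,
          " | pairs passing: ", report$n_pairs_passing,
          " | links: ", report$n_links,
          " | groups: ", summary$n_groups,
          " | genes in groups: ", summary$n_genes_in_groups)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- c(unclass(params), list(dialect = dialect))
    cmt <- output_comment(cfg)
    write_groups(groups, index, "gene-list",
                 file.path(out_dir, "genes_in_groups.tsv"), comment = cmt)
    write_groups(groups, index, "group-list",
                 file.path(out_dir, "groups.tsv"), comment = cmt)
    con <- file(file.path(out_dir, "summary.tsv"), "w")
    writeLines(paste0("# ", cmt), con)
    writeLines(paste("n_groups", summary$n_groups, sep = "\t"), con)
    writeLines(paste("n_genes_in_groups", summary$n_genes_in_groups, sep = "\t"), con)
    writeLines(paste("mean_span_kb", summary$mean_span_kb, sep = "\t"), con)
    writeLines(paste("median_span_kb", summary$median_span_kb, sep = "\t"), con)
    writeLines(paste("largest_group", summary$largest_group, sep = "\t"), con)
    close(con)
  }
  invisible(list(index = index, pairs = pairs, groups = groups,
                 summary = summary, report = report))
}

#' Characterise duplicate groups by co-expression and GO similarity
#'
#' For each group within the size caps, computes the proportion of
#' significant pairwise expression correlations over the eligible datasets
#' and the per-namespace Wang semantic similarities with the group's IEA
#' annotation proportion.  Stages with no input are skipped with a notice;
#' groups over a cap are reported as skipped with the reason.
#'
#' @param groups Group data frame from [build_groups()].
#' @param index [build_gene_index()].
#' @param datasets List of [expression_dataset()] objects, or a directory of
#'   expression matrices, or NULL to skip the expression stage.
#' @param obo,gaf Ontology and annotation file paths (or pre-loaded graph /
#'   annotation data frame); NULL skips the GO stage.
#' @param alpha Significance level for correlation tests.
#' @param expr_cap,go_cap Group-size caps (defaults 5 and 15).
#' @param weights [contribution_weights()].
#' @param out_dir Output directory; NULL skips writing.
#' @return Invisibly, a list: `correlation` (data frame per group),
#'   `go` (data frame per group x namespace), `skipped` (data frame
#'   group_id, stage, reason).
#' @export
run_characterise <- function(groups, index, datasets = NULL,
                             obo = NULL, gaf = NULL,
                             alpha = 0.05, expr_cap = 5L, go_cap = 15L,
                             weights = contribution_weights(),
                             out_dir = NULL) {
  skipped <- list()
  corr <- NULL
  if (is.character(datasets)) {
    files <- list.files(datasets, pattern = "\\.tsv$", full.names = TRUE)
    datasets <- lapply(files, read_expression)
  }
  if (is.null(datasets) || length(datasets) == 0L) {
    message("no expression data supplied; correlation stage skipped")
  } else {
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      gc <- proportion_significant(groups$members[[i]], datasets,
                                   alpha = alpha, max_group_size = expr_cap)
      if (!is.na(gc$skipped_reason)) {
        skipped[[length(skipped) + 1L]] <<- data.frame(
          group_id = groups$group_id[i], stage = "expression",
          reason = gc$skipped_reason, stringsAsFactors = FALSE)
        return(NULL)
      }
      data.frame(group_id = groups$group_id[i], n_genes = groups$n_genes[i],
                 proportion_significant = gc$proportion,
                 n_tests = gc$n_tests, n_datasets = gc$n_datasets,
                 stringsAsFactors = FALSE)
    })
    corr <- do.call(rbind, rows)
  }
  go <- NULL
  if (is.null(obo) || is.null(gaf)) {
    message("no ontology/annotations supplied; GO stage skipped")
  } else {
    graph <- if (is.character(obo)) load_ontology(obo) else obo
    ann <- if (is.character(gaf)) read_annotations(gaf) else gaf
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      gs <- group_semantic_similarity(groups$members[[i]], ann, graph,
                                      weights, cap = go_cap)
      if (!is.na(gs$skipped_reason)) {
        skipped[[length(skipped) + 1L]] <<- data.frame(
          group_id = groups$group_id[i], stage = "go",
          reason = gs$skipped_reason, stringsAsFactors = FALSE)
        return(NULL)
      }
      if (is.null(gs$pairs)) return(NULL)
      agg <- tapply(gs$pairs$similarity, gs$pairs$namespace, mean, na.rm = TRUE)
      data.frame(group_id = groups$group_id[i], n_genes = groups$n_genes[i],
                 namespace = names(agg), mean_similarity = as.numeric(agg),
                 iea_proportion = gs$iea_proportion,
                 stringsAsFactors = FALSE)
    })
    go <- do.call(rbind, rows)
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped)
             else data.frame(group_id = character(0), stage = character(0),
                             reason = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- list(alpha = alpha, expr_cap = expr_cap, go_cap = go_cap,
                weights = unclass(weights))
    cmt <- output_comment(cfg)
    write_commented <- function(df, path) {
      con <- file(path, "w"); on.exit(close(con))
      writeLines(paste0("# ", cmt), con)
      utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(corr)) write_commented(corr, file.path(out_dir, "coexpression.tsv"))
    if (!is.null(go)) write_commented(go, file.path(out_dir, "go_similarity.tsv"))
    write_commented(skipped, file.path(out_dir, "skipped_groups.tsv"))
  }
  invisible(list(correlation = corr, go = go, skipped = skipped))
}
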