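# Gene annotation and peptide input, longest-isoform selection, the
# coordinate-ordered gene index, and tab-delimited group output.
#
# Coordinates are 1-based inclusive throughout (Ensembl convention); BED
# input is converted on read.  Strand is carried but never used by the
# detection itself.

GENE_COLUMNS <- c("gene_id", "chromosome", "start", "end",
                  "strand", "name", "description")

validate_gene_table <- function(genes) {
  stopifnot(is.data.frame(genes))
  missing <- setdiff(c("gene_id", "chromosome", "start", "end"), names(genes))
  if (length(missing))
    stop("gene table lacks required column(s): ", paste(missing, collapse = ", "))
  for (col in c("strand", "name", "description")) {
    if (is.null(genes[[col]])) genes[[col]] <- NA_character_
    genes[[col]] <- as.character(genes[[col]])
    genes[[col]][!is.na(genes[[col]]) & !nzchar(genes[[col]])] <- NA_character_
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$chromosome <- as.character(genes$chromosome)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup))
    stop("duplicate gene_id(s): ", paste(dup, collapse = ", "))
  bad <- which(is.na(genes$start) | is.na(genes$end) | genes$start > genes$end)
  if (length(bad))
    stop("invalid coordinates (need start <= end) for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "))
  genes[GENE_COLUMNS]
}

#' Read gene annotations
#'
#' Reads gene records from GFF3 (rows of type "gene" only), BED (half-open
#' 0-based coordinates converted to 1-based inclusive) or a plain
#' tab-delimited gene table with header columns
#' `gene_id chromosome start end [strand name description]`.
#'
#' @param path Annotation file.
#' @param dialect One of "tsv", "gff3", "bed".
#' @return A data frame of gene records with columns `gene_id`, `chromosome`,
#'   `start`, `end`, `strand` (`+`, `-`, or `*` for unknown), `name`,
#'   `description`; `gene_id` is unique.
#' @export
read_gene_annotation <- function(path, dialect = c("tsv", "gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  genes <- switch(dialect,
    tsv = {
      tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                               comment.char = "#")
      num_bad <- which(is.na(suppressWarnings(as.integer(tab$start))) |
                       is.na(suppressWarnings(as.integer(tab$end))))
      if (length(num_bad))
        stop("malformed gene table row at line ", num_bad[1L] + 1L,
             " of ", path, ": non-numeric start/end")
      tab
    },
    gff3 = {
      gr <- rtracklayer::import(path, format = "gff3")
      df <- as.data.frame(gr, stringsAsFactors = FALSE)
      if (!is.null(df$type)) df <- df[df$type == "gene", , drop = FALSE]
      if (nrow(df) == 0L) stop("no 'gene' features in ", path)
      id <- df$ID %||% df$gene_id %||% df$Name
      if (is.null(id)) stop("GFF3 gene features carry no ID attribute")
      data.frame(gene_id = sub("^gene:", "", as.character(id)),
                 chromosome = as.character(df$seqnames),
                 start = df$start, end = df$end,
                 strand = as.character(df$strand),
                 name = as.character(df$Name %||% NA),
                 description = as.character(df$description %||% NA),
                 stringsAsFactors = FALSE)
    },
    bed = {
      gr <- rtracklayer::import(path, format = "bed")
      df <- as.data.frame(gr, stringsAsFactors = FALSE)
      if (is.null(df$name)) stop("BED input needs a name column for gene ids")
      data.frame(gene_id = as.character(df$name),
                 chromosome = as.character(df$seqnames),
                 start = df$start, end = df$end,   # GRanges is already 1-based
                 strand = as.character(df$strand),
                 name = as.character(df$name),
                 description = NA_character_,
                 stringsAsFactors = FALSE)
    })
  validate_gene_table(genes)
}

#' Write a gene table in the tab-delimited dialect
#'
#' @param genes Gene data frame as returned by [read_gene_annotation()].
#' @param path Output file.
#' @export
write_gene_table <- function(genes, path) {
  genes <- validate_gene_table(genes)
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read peptide sequences with their gene mapping
#'
#' Reads a peptide FASTA.  The peptide id is the first whitespace-delimited
#' token of each header; the owning gene comes either from a `gene:<id>`
#' token in the header or from a side table.  Sequences are upper-cased and
#' terminal stop symbols (`*`) are stripped.
#'
#' @param path Peptide FASTA file.
#' @param gene_map Optional side table: a data frame with columns
#'   `peptide_id` and `gene_id`, or a named character vector
#'   (names = peptide ids).  Overrides header tokens.
#' @return Data frame with columns `peptide_id`, `gene_id`, `sequence`.
#' @export
read_peptides <- function(path, gene_map = NULL) {
  if (!file.exists(path)) stop("peptide FASTA not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in ", path)
  headers <- names(aa)
  peptide_id <- vapply(strsplit(headers, "\\s+"), `[[`, "", 1L)
  if (!is.null(gene_map)) {
    if (is.data.frame(gene_map)) {
      stopifnot(all(c("peptide_id", "gene_id") %in% names(gene_map)))
      gene_map <- stats::setNames(as.character(gene_map$gene_id),
                                  as.character(gene_map$peptide_id))
    }
    gene_id <- unname(gene_map[peptide_id])
  } else {
    gene_id <- vapply(headers, function(h) {
      m <- regmatches(h, regexpr("gene[:=][^\\s]+", h))
      if (length(m)) sub("^gene[:=]", "", m) else NA_character_
    }, "", USE.NAMES = FALSE)
  }
  orphans <- peptide_id[is.na(gene_id)]
  if (length(orphans))
    stop("peptide(s) with no gene mapping: ", paste(orphans, collapse = ", "))
  sequence <- sub("\\*+$", "", toupper(as.character(aa)))
  if (any(!nzchar(sequence)))
    stop("empty peptide sequence(s): ",
         paste(peptide_id[!nzchar(sequence)], collapse = ", "))
  data.frame(peptide_id = peptide_id, gene_id = gene_id, sequence = sequence,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write peptides as FASTA with gene-token headers
#'
#' @param peptides Data frame with `peptide_id`, `gene_id`, `sequence`.
#' @param path Output file.
#' @export
write_peptides <- function(peptides, path) {
  aa <- Biostrings::AAStringSet(peptides$sequence)
  names(aa) <- paste0(peptides$peptide_id, " gene:", peptides$gene_id)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Keep one peptide per gene: the longest
#'
#' Multi-isoform genes are reduced to their single longest peptide; ties are
#' broken by the lexicographically smallest peptide id for determinism.
#'
#' @param peptides Data frame from [read_peptides()].
#' @return Data frame with one row per distinct `gene_id`.
#' @export
select_longest_peptides <- function(peptides) {
  stopifnot(is.data.frame(peptides), nrow(peptides) > 0L)
  ord <- order(peptides$gene_id, -nchar(peptides$sequence), peptides$peptide_id)
  peptides <- peptides[ord, , drop = FALSE]
  out <- peptides[!duplicated(peptides$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the per-chromosome coordinate-ordered gene index
#'
#' Genes are ordered within each chromosome by start coordinate (ties by end,
#' then gene id) and assigned a 0-based rank.  Rank distance in this index is
#' the co-localisation measure used by the detection window.
#'
#' @param genes Gene data frame.
#' @return A `gene_index`: the gene data frame sorted by (chromosome, start,
#'   end, gene_id) with an integer `rank` column, 0-based and contiguous per
#'   chromosome.
#' @export
build_gene_index <- function(genes) {
  genes <- validate_gene_table(genes)
  ord <- order(genes$chromosome, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- stats::ave(genes$start, genes$chromosome,
                           FUN = function(x) seq_along(x) - 1L)
  genes$rank <- as.integer(genes$rank)
  rownames(genes) <- NULL
  class(genes) <- c("gene_index", "data.frame")
  genes
}

#' @export
print.gene_index <- function(x, ...) {
  cat("gene_index:", nrow(x), "genes on",
      length(unique(x$chromosome)), "chromosome(s)\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Write duplicate groups as tab-delimited tables
#'
#' Two layouts: `gene-list` (one row per member gene: group_id, gene_id,
#' chromosome, start, end, name) and `group-list` (one row per group:
#' group_id, chromosome, n_genes, span_kb, comma-joined member ids).  Rows
#' are ordered by chromosome, then minimal member start; a header row is
#' always present.
#'
#' @param groups Group data frame from [build_groups()].
#' @param index A [build_gene_index()] object covering all member genes.
#' @param mode `"gene-list"` or `"group-list"`.
#' @param path Output file.
#' @param comment Optional comment line(s) written before the header,
#'   prefixed with `#`.
#' @export
write_groups <- function(groups, index,
                         mode = c("gene-list", "group-list"),
                         path, comment = NULL) {
  mode <- match.arg(mode)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  members_all <- unlist(groups$members)
  unknown <- setdiff(members_all, index$gene_id)
  if (length(unknown))
    stop("group member(s) absent from the gene index: ",
         paste(unknown, collapse = ", "))
  lookup <- index[match(members_all, index$gene_id), , drop = FALSE]
  if (nrow(groups) == 0L) {
    hdr <- if (mode == "gene-list")
      c("group_id", "gene_id", "chromosome", "start", "end", "name")
    else c("group_id", "chromosome", "n_genes", "span_kb", "genes")
    writeLines(paste(hdr, collapse = "\t"), con)
    return(invisible(path))
  }
  min_start <- vapply(groups$members, function(m)
    min(index$start[match(m, index$gene_id)]), 0)
  ord <- order(groups$chromosome, min_start)
  groups <- groups[ord, , drop = FALSE]
  if (mode == "gene-list") {
    rows <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
      m <- groups$members[[i]]
      g <- index[match(m, index$gene_id), , drop = FALSE]
      data.frame(group_id = groups$group_id[i], gene_id = g$gene_id,
                 chromosome = g$chromosome, start = g$start, end = g$end,
                 name = g$name, stringsAsFactors = FALSE)
    }))
  } else {
    rows <- data.frame(group_id = groups$group_id,
                       chromosome = groups$chromosome,
                       n_genes = groups$n_genes,
                       span_kb = groups$span_bp / 1000,
                       genes = vapply(groups$members, paste, "", collapse = ","),
                       stringsAsFactors = FALSE)
  }
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
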