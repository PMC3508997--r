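# Small in-code fixtures shared by the unit tests.

make_gene_table <- function(n, chromosome = "chr1", start = NULL, width = 1000) {
  start <- as.integer(start %||% seq(1, by = 10000, length.out = n))
  data.frame(gene_id = sprintf("g%02d", seq_len(n)),
             chromosome = chromosome,
             start = start, end = as.integer(start + width),
             strand = "+", name = NA_character_,
             description = NA_character_, stringsAsFactors = FALSE)
}

make_peptides <- function(gene_ids, sequences) {
  data.frame(peptide_id = paste0(gene_ids, "_p"),
             gene_id = gene_ids, sequence = sequences,
             stringsAsFactors = FALSE)
}

random_aa <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V"),
                 len, replace = TRUE), collapse = ""), "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
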