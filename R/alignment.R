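# Local alignment of peptide pairs and ingestion of precomputed tabular
# alignments.  Both routes produce alignment_result objects, so downstream
# duplicate decisions do not depend on where an alignment came from.

# Accept a peptide as a bare string, a PeptideRecord-style list, or a 1-row
# data frame; return list(id, seq).
as_peptide <- function(x, default_id) {
  if (is.character(x) && length(x) == 1L)
    return(list(id = default_id, seq = x))
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L, "sequence" %in% names(x))
    id <- if (!is.null(x$gene_id)) x$gene_id else x$peptide_id %||% default_id
    return(list(id = id, seq = x$sequence))
  }
  if (is.list(x) && !is.null(x$sequence)) {
    id <- x$gene_id %||% x$peptide_id %||% default_id
    return(list(id = id, seq = x$sequence))
  }
  stop("cannot interpret peptide input")
}

#' Optimal local alignment between two peptides
#'
#' Smith–Waterman local alignment with affine gaps, computed with
#' `Biostrings::pairwiseAlignment()`.  Returns the quantities the duplicate
#' criterion needs (aligned length with gaps, identical positions, residues
#' of each sequence inside the aligned region, full lengths).  When no
#' positive-scoring local alignment exists the result is empty (`L = 0`,
#' score 0).  No e-value is attached: internal alignments skip the e-value
#' filter.
#'
#' @param a,b Peptides: character strings, or records with a `sequence` field
#'   (and `gene_id`/`peptide_id` used as identifiers).
#' @param scoring A [scoring_scheme()].
#' @return An [alignment_result()].
#' @export
#' @examples
#' align_local("MKVLA", "MKILA")
align_local <- function(a, b, scoring = scoring_scheme()) {
  pa <- as_peptide(a, "query")
  pb <- as_peptide(b, "subject")
  if (!nzchar(pa$seq) || !nzchar(pb$seq)) stop("cannot align an empty sequence")
  mat <- substitution_matrix(scoring)
  aln <- Biostrings::pairwiseAlignment(
    pattern = pa$seq, subject = pb$seq, type = "local",
    substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  sc <- Biostrings::score(aln)
  Lq <- nchar(pa$seq); Ls <- nchar(pb$seq)
  if (sc <= 0) {
    return(alignment_result(pa$id, pb$id, L = 0L, identities = 0L,
                            n_query = 0L, n_subject = 0L,
                            L_query = Lq, L_subject = Ls, score = max(sc, 0)))
  }
  qal <- strsplit(as.character(Biostrings::pattern(aln)), "", fixed = TRUE)[[1L]]
  sal <- strsplit(as.character(Biostrings::subject(aln)), "", fixed = TRUE)[[1L]]
  alignment_result(pa$id, pb$id,
                   L = length(qal),
                   identities = sum(qal == sal & qal != "-"),
                   n_query = sum(qal != "-"),
                   n_subject = sum(sal != "-"),
                   L_query = Lq, L_subject = Ls, score = sc)
}

#' Read precomputed pairwise alignments in 12-column tabular format
#'
#' Parses the standard tab-separated alignment dialect (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore),
#' optionally extended with the full sequence lengths qlen and slen as
#' columns 13–14.  When the length columns are absent, `seq_lengths` (a
#' named vector of full sequence lengths, e.g. from the peptide FASTA) must
#' supply them.  Identity counts are reconstructed from the percent identity
#' as `round(pident * length / 100)` (half up); residues inside the aligned
#' region are taken from the query/subject coordinate spans.  Self matches
#' (query equal to subject) are dropped.
#'
#' @param path Tabular alignment file.
#' @param seq_lengths Optional named integer vector of full sequence lengths.
#' @return A list of [alignment_result()] objects.
#' @export
parse_alignment_tabular <- function(path, seq_lengths = NULL) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 12L)
    stop("alignment table must have at least 12 columns; got ", ncol(tab))
  names(tab)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                        "gapopen", "qstart", "qend", "sstart", "send",
                        "evalue", "bitscore")
  has_lens <- ncol(tab) >= 14L
  if (has_lens) names(tab)[13:14] <- c("qlen", "slen")
  tab <- tab[tab$qseqid != tab$sseqid, , drop = FALSE]
  if (nrow(tab) == 0L) return(list())
  if (!has_lens) {
    if (is.null(seq_lengths))
      stop("alignment table lacks qlen/slen columns and no sequence lengths ",
           "were supplied; cannot compute coverage for the weighted identity")
    missing <- setdiff(unique(c(tab$qseqid, tab$sseqid)), names(seq_lengths))
    if (length(missing))
      stop("no sequence length known for: ", paste(missing, collapse = ", "))
    tab$qlen <- as.integer(seq_lengths[tab$qseqid])
    tab$slen <- as.integer(seq_lengths[tab$sseqid])
  }
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    alignment_result(r$qseqid, r$sseqid,
                     L = r$length,
                     identities = round_half_up(r$pident * r$length / 100),
                     n_query = r$qend - r$qstart + 1L,
                     n_subject = r$send - r$sstart + 1L,
                     L_query = r$qlen, L_subject = r$slen,
                     score = r$bitscore, e_value = r$evalue)
  })
}

#' Write alignment results in the 12+2-column tabular format
#'
#' Inverse of [parse_alignment_tabular()]; used to exchange internally
#' computed alignments with external tooling.  Internal alignments carry no
#' e-value; those are written as 0.
#'
#' @param alignments List of [alignment_result()] objects.
#' @param path Output file.
#' @export
write_alignment_tabular <- function(alignments, path) {
  rows <- lapply(alignments, function(a) {
    data.frame(qseqid = a$query_id, sseqid = a$subject_id,
               pident = 100 * a$identities / max(a$L, 1L),
               length = a$L,
               mismatch = a$L - a$identities,
               gapopen = 0L,
               qstart = 1L, qend = a$n_query,
               sstart = 1L, send = a$n_subject,
               evalue = if (is.na(a$e_value)) 0 else a$e_value,
               bitscore = if (is.na(a$score)) 0 else a$score,
               qlen = a$L_query, slen = a$L_subject,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
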