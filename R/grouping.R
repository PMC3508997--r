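# Co-localised duplicate pair discovery, transitive-closure grouping and
# genome-level summaries.
#
# Candidate partners for a gene are the genes within `window` ranks on the
# same chromosome.  Among candidates passing the duplicate criterion, each
# gene is linked to the passing hit closest downstream (smallest positive
# rank offset).  Upstream-only situations are covered symmetrically: the
# upstream partner's own downstream link is the same unordered pair.  Groups
# are the connected components of the link graph, so the final grouping is
# insensitive to most link-choice details.

# Shared-k-mer candidate screen: peptide pairs sharing no k-mer cannot reach
# the identity thresholds, so they are skipped before alignment.  Pairs
# where either peptide is shorter than k are always scored.
kmer_candidate_pairs <- function(seqs, k) {
  n <- length(seqs)
  if (n < 2L) return(integer(0))
  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  df <- data.frame(kmer = unlist(kmers),
                   gene = rep.int(seq_len(n), lengths(kmers)))
  hits <- split(df$gene, df$kmer)
  hits <- hits[lengths(hits) > 1L]
  pairs <- unique(do.call(rbind, lapply(hits, function(g) {
    t(utils::combn(sort(g), 2L))
  })))
  short <- which(nchar(seqs) < k)
  if (length(short)) {
    extra <- expand.grid(i = short, j = seq_len(n))
    extra <- extra[extra$i != extra$j, ]
    extra <- unique(cbind(pmin(extra$i, extra$j), pmax(extra$i, extra$j)))
    pairs <- unique(rbind(pairs, extra))
  }
  pairs
}

#' Find co-localised duplicate gene pairs
#'
#' For each gene, candidate partners are the other genes within `window`
#' ranks on the same chromosome.  Candidate peptide pairs are locally
#' aligned (or looked up in externally supplied alignments) and tested with
#' [is_duplicate_pair()]; each gene is then linked to its closest passing
#' downstream hit.  Genes without a peptide are skipped with a warning but
#' keep their rank, so the window still reflects genomic context.
#'
#' @param index A [build_gene_index()] object.
#' @param peptides Data frame with one peptide per gene
#'   ([select_longest_peptides()] output).
#' @param params [detection_params()].
#' @param alignments Optional list of [alignment_result()] objects (e.g. from
#'   [parse_alignment_tabular()]); identifiers may be gene ids or peptide
#'   ids.  When supplied, no internal alignment is run.
#' @param scoring [scoring_scheme()] for internal alignment.
#' @param prescreen Use the shared-k-mer candidate screen before internal
#'   alignment (default TRUE; irrelevant when `alignments` is given).
#' @param kmer_size k-mer size of the screen.
#' @param link `"closest-downstream"` (default, the published behaviour) or
#'   `"all"`, which keeps every passing pair in the window (sensitivity
#'   analysis).
#' @return Data frame of unordered pairs, one row each, with `gene_a`
#'   upstream of `gene_b`: columns `gene_a`, `gene_b`, `chromosome`,
#'   `rank_distance`, `I`, `I_prime`, `threshold_used`, `branch`.  An
#'   attribute `report` carries stage counts (genes, genes without peptide,
#'   pairs scored, pairs passing, links kept).
#' @export
find_duplicate_pairs <- function(index, peptides,
                                 params = detection_params(),
                                 alignments = NULL,
                                 scoring = scoring_scheme(),
                                 prescreen = TRUE, kmer_size = 5L,
                                 link = c("closest-downstream", "all")) {
  link <- match.arg(link)
  stopifnot(inherits(index, "gene_index"))
  seq_of <- stats::setNames(peptides$sequence, peptides$gene_id)
  no_pep <- setdiff(index$gene_id, peptides$gene_id)
  if (length(no_pep))
    warning(length(no_pep), " gene(s) without a peptide were skipped")

  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      chromosome = character(0), rank_distance = integer(0),
                      I = numeric(0), I_prime = numeric(0),
                      threshold_used = numeric(0), branch = character(0),
                      stringsAsFactors = FALSE)

  # enumerate candidate unordered pairs within the window, per chromosome
  cand <- list()
  for (chrom in unique(index$chromosome)) {
    sub <- index[index$chromosome == chrom, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    keep <- sub$gene_id %in% names(seq_of)
    m <- nrow(sub)
    if (m < 2L) next
    ij <- do.call(rbind, lapply(seq_len(min(params$window, m - 1L)), function(d)
      cbind(1:(m - d), (1 + d):m)))
    ij <- ij[keep[ij[, 1L]] & keep[ij[, 2L]], , drop = FALSE]
    if (nrow(ij) == 0L) next
    if (is.null(alignments) && prescreen) {
      kp <- kmer_candidate_pairs(seq_of[sub$gene_id], kmer_size)
      if (length(kp) == 0L) next
      ij <- ij[paste(ij[, 1L], ij[, 2L]) %in% paste(kp[, 1L], kp[, 2L]), ,
               drop = FALSE]
    }
    if (nrow(ij) == 0L) next
    cand[[chrom]] <- data.frame(
      gene_a = sub$gene_id[ij[, 1L]], gene_b = sub$gene_id[ij[, 2L]],
      chromosome = chrom,
      rank_a = sub$rank[ij[, 1L]], rank_b = sub$rank[ij[, 2L]],
      stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  report <- list(n_genes = nrow(index), n_no_peptide = length(no_pep),
                 n_pairs_scored = 0L, n_pairs_passing = 0L, n_links = 0L)
  if (is.null(cand) || nrow(cand) == 0L) {
    attr(empty, "report") <- report
    return(empty)
  }
  rownames(cand) <- NULL

  # one decision per unordered candidate pair
  if (!is.null(alignments)) {
    # translate peptide ids to gene ids where needed, keep the best
    # alignment per unordered pair (score, then L, then subject id)
    pep2gene <- stats::setNames(peptides$gene_id, peptides$peptide_id)
    to_gene <- function(id) {
      ifelse(id %in% index$gene_id, id, unname(pep2gene[id]))
    }
    best <- new.env(parent = emptyenv())
    for (a in alignments) {
      ga <- to_gene(a$query_id); gb <- to_gene(a$subject_id)
      if (is.na(ga) || is.na(gb) || ga == gb) next
      key <- paste(sort(c(ga, gb)), collapse = "\r")
      old <- best[[key]]
      better <- is.null(old) ||
        (!is.na(a$score) && (is.na(old$score) || a$score > old$score ||
          (a$score == old$score && (a$L > old$L ||
            (a$L == old$L && a$subject_id < old$subject_id)))))
      if (better) best[[key]] <- a
    }
    decide <- function(ga, gb) {
      a <- best[[paste(sort(c(ga, gb)), collapse = "\r")]]
      if (is.null(a)) return(NULL)
      is_duplicate_pair(a, params)
    }
  } else {
    decide <- function(ga, gb) {
      aln <- align_local(seq_of[[ga]], seq_of[[gb]], scoring)
      report$n_pairs_scored <<- report$n_pairs_scored + 1L
      is_duplicate_pair(aln, params)
    }
  }
  decisions <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand)))
    decisions[[i]] <- decide(cand$gene_a[i], cand$gene_b[i])
  have <- !vapply(decisions, is.null, TRUE)
  if (!is.null(alignments)) report$n_pairs_scored <- sum(have)
  cand <- cand[have, , drop = FALSE]
  decisions <- decisions[have]
  passes <- vapply(decisions, `[[`, TRUE, "passes")
  report$n_pairs_passing <- sum(passes)
  cand <- cand[passes, , drop = FALSE]
  decisions <- decisions[passes]
  if (nrow(cand) == 0L) {
    attr(empty, "report") <- report
    return(empty)
  }
  cand$rank_distance <- cand$rank_b - cand$rank_a
  cand$I <- vapply(decisions, `[[`, 0, "I")
  cand$I_prime <- vapply(decisions, `[[`, 0, "I_prime")
  cand$threshold_used <- vapply(decisions, `[[`, 0, "threshold_used")
  cand$branch <- vapply(decisions, `[[`, "", "branch")

  if (link == "closest-downstream") {
    # per upstream gene keep the downstream hit with the smallest offset
    ord <- order(cand$gene_a, cand$rank_distance)
    cand <- cand[ord, , drop = FALSE]
    cand <- cand[!duplicated(cand$gene_a), , drop = FALSE]
  }
  cand <- cand[order(cand$chromosome, cand$rank_a, cand$rank_b), , drop = FALSE]
  report$n_links <- nrow(cand)
  out <- cand[, c("gene_a", "gene_b", "chromosome", "rank_distance",
                  "I", "I_prime", "threshold_used", "branch")]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}

# Minimal union-find with path halving; ids are integer indices.
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  list(root = i, parent = parent)
}
uf_union <- function(parent, i, j) {
  fi <- uf_find(parent, i); parent <- fi$parent
  fj <- uf_find(parent, j); parent <- fj$parent
  if (fi$root != fj$root) parent[fj$root] <- fi$root
  parent
}

#' Assemble duplicate groups by transitive closure
#'
#' Groups are the connected components of the pair graph: if A is similar to
#' B and to C, then A, B and C share a group even when B and C were never
#' found similar.  Components are computed with union-find; singleton genes
#' never form groups, so every group has at least two members.
#'
#' @param pairs Pair data frame from [find_duplicate_pairs()] (columns
#'   `gene_a`, `gene_b`; any extra columns are ignored).
#' @param index [build_gene_index()] covering the member genes, used for the
#'   genomic span and the deterministic ordering.
#' @return Data frame with one row per group: `group_id` (chromosome plus
#'   the id of the member with the smallest start), `chromosome`, `n_genes`,
#'   `span_bp` (max member end minus min member start) and a list column
#'   `members` (gene ids in rank order).  Ordered by (chromosome, min
#'   start); invariant to the input order of the pairs.
#' @export
build_groups <- function(pairs, index) {
  stopifnot(is.data.frame(pairs), inherits(index, "gene_index"))
  if (nrow(pairs) == 0L) {
    out <- data.frame(group_id = character(0), chromosome = character(0),
                      n_genes = integer(0), span_bp = numeric(0))
    out$members <- list()
    return(out)
  }
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  unknown <- setdiff(genes, index$gene_id)
  if (length(unknown))
    stop("pair member(s) absent from the gene index: ",
         paste(unknown, collapse = ", "))
  id <- stats::setNames(seq_along(genes), genes)
  parent <- uf_new(length(genes))
  for (i in seq_len(nrow(pairs)))
    parent <- uf_union(parent, id[[pairs$gene_a[i]]], id[[pairs$gene_b[i]]])
  root <- vapply(seq_along(genes), function(i) uf_find(parent, i)$root, 0L)
  comps <- split(genes, root)
  rows <- lapply(comps, function(m) {
    g <- index[match(m, index$gene_id), , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    if (length(unique(g$chromosome)) != 1L)
      stop("group spans multiple chromosomes; pairs are invalid")
    lead <- g$gene_id[which.min(g$start)]
    data.frame(group_id = paste0(g$chromosome[1L], ":", lead),
               chromosome = g$chromosome[1L],
               n_genes = nrow(g),
               span_bp = max(g$end) - min(g$start),
               min_start = min(g$start),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(comps, function(m) {
    g <- index[match(m, index$gene_id), , drop = FALSE]
    g$gene_id[order(g$rank)]
  })
  ord <- order(out$chromosome, out$min_start)
  out <- out[ord, c("group_id", "chromosome", "n_genes", "span_bp", "members")]
  rownames(out) <- NULL
  out
}

#' Genome-level summary of duplicate groups
#'
#' @param groups Group data frame from [build_groups()].
#' @return A `genome_summary` list: `n_groups`, `n_genes_in_groups`,
#'   `size_histogram` (named counts by member number), `mean_span_kb`,
#'   `median_span_kb`, `largest_group`.  All zero / empty for an empty group
#'   list.
#' @export
summarize_groups <- function(groups) {
  if (nrow(groups) == 0L) {
    return(structure(list(n_groups = 0L, n_genes_in_groups = 0L,
                          size_histogram = integer(0),
                          mean_span_kb = 0, median_span_kb = 0,
                          largest_group = 0L),
                     class = "genome_summary"))
  }
  sizes <- groups$n_genes
  structure(list(n_groups = nrow(groups),
                 n_genes_in_groups = sum(sizes),
                 size_histogram = table(sizes),
                 mean_span_kb = mean(groups$span_bp) / 1000,
                 median_span_kb = stats::median(groups$span_bp) / 1000,
                 largest_group = max(sizes)),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("Duplicate groups:", x$n_groups,
      "| genes in groups:", x$n_genes_in_groups,
      "| largest group:", x$largest_group, "\n")
  cat("Span (kb): mean", format(x$mean_span_kb, digits = 4),
      "median", format(x$median_span_kb, digits = 4), "\n")
  if (length(x$size_histogram)) {
    cat("Group-size distribution:\n")
    print(x$size_histogram)
  }
  invisible(x)
}
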