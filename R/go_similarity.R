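# Wang graph-based semantic similarity over the Gene Ontology DAG.
#
# Each term's semantics are the S-values of its ancestor DAG: S(term) = 1,
# and S decays along child->parent edges by an edge-type contribution factor
# (< 1), taking the best path when several exist.  Two terms are compared by
# the S-value mass of their shared ancestors relative to their total
# semantic value; genes by best-match averaging over their term sets.  All
# values are bounded in [0, 1].

#' Threshold above which two genes are conventionally called fairly similar
#'
#' Wang's recommendation: an aggregate gene-pair similarity of 0.5 marks the
#' boundary of functional similarity.  Exposed as a labelled constant for
#' reporting; no internal logic depends on it.
#' @export
wang_fairly_similar <- 0.5

#' Edge-type semantic contribution factors
#'
#' Decay factor applied to S-values across one edge of the given type.  The
#' defaults 0.8 (is_a) and 0.6 (part_of) are the values of the original
#' method.  Factors must lie strictly between 0 and 1.
#'
#' @param is_a,part_of Contribution factors.
#' @return A `contribution_weights` object (named numeric vector).
#' @export
contribution_weights <- function(is_a = 0.8, part_of = 0.6) {
  w <- c(is_a = is_a, part_of = part_of)
  stopifnot(all(w > 0), all(w < 1))
  structure(w, class = "contribution_weights")
}

#' Load a Gene Ontology graph from an OBO file
#'
#' Keeps non-obsolete `[Term]` stanzas and their `is_a` and `part_of` edges;
#' other relationship types (e.g. regulates) are ignored, the terms kept.
#' Terms are partitioned into the three namespaces (biological_process,
#' molecular_function, cellular_component).  A cycle among the retained
#' edges is an error.
#'
#' @param path OBO file.
#' @return An `ontology_graph`: list with `terms` (data frame id, name,
#'   namespace) and `parents` (named list: term -> data frame parent, type).
#' @export
load_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas in OBO file ", path)
  bounds <- c(starts, length(lines) + 1L)
  terms <- list(); edges <- list()
  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    block <- lines[(starts[s] + 1L):(bounds[s + 1L] - 1L)]
    field <- function(key) {
      v <- sub(paste0("^", key, ": "), "", grep(paste0("^", key, ": "), block,
                                                value = TRUE))
      sub(" !.*$", "", v)
    }
    id <- field("id")[1L]
    if (is.na(id)) next
    if (length(field("is_obsolete")) && field("is_obsolete")[1L] == "true") next
    terms[[id]] <- data.frame(id = id,
                              name = field("name")[1L] %||% NA_character_,
                              namespace = field("namespace")[1L] %||% NA_character_,
                              stringsAsFactors = FALSE)
    isa <- field("is_a")
    if (length(isa))
      edges[[length(edges) + 1L]] <- data.frame(child = id, parent = isa,
                                                type = "is_a",
                                                stringsAsFactors = FALSE)
    rel <- grep("^relationship: ", block, value = TRUE)
    rel <- sub("^relationship: ", "", sub(" !.*$", "", rel))
    po <- rel[startsWith(rel, "part_of ")]
    if (length(po))
      edges[[length(edges) + 1L]] <- data.frame(
        child = id, parent = sub("^part_of ", "", po), type = "part_of",
        stringsAsFactors = FALSE)
  }
  terms <- do.call(rbind, terms)
  if (is.null(terms)) stop("no usable terms in ", path)
  edges <- do.call(rbind, edges)
  if (!is.null(edges)) {
    edges <- edges[edges$child %in% terms$id & edges$parent %in% terms$id, ,
                   drop = FALSE]
  } else {
    edges <- data.frame(child = character(0), parent = character(0),
                        type = character(0))
  }
  g <- ontology_graph(terms, edges)
  rownames(g$terms) <- NULL
  g
}

# Build and validate the graph object (Kahn's algorithm for acyclicity).
ontology_graph <- function(terms, edges) {
  indeg <- stats::setNames(integer(nrow(terms)), terms$id)
  # count child->parent edges as parent depending on child: peel leaves first
  tab <- table(factor(edges$parent, levels = terms$id))
  indeg[names(tab)] <- as.integer(tab)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  by_child <- split(seq_len(nrow(edges)), edges$child)
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (i in by_child[[t]] %||% integer(0)) {
      p <- edges$parent[i]
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != nrow(terms)) stop("cycle detected in ontology graph")
  structure(list(terms = terms,
                 parents = lapply(by_child, function(i)
                   data.frame(parent = edges$parent[i], type = edges$type[i],
                              stringsAsFactors = FALSE))),
            class = "ontology_graph")
}

term_namespace <- function(graph, term) {
  i <- match(term, graph$terms$id)
  if (is.na(i)) stop("unknown term: ", term)
  graph$terms$namespace[i]
}

#' S-values of a term over its ancestor DAG
#'
#' `S(term) = 1`; along each child-to-parent edge the value decays by the
#' edge-type contribution factor, and an ancestor reachable by several paths
#' takes the best (maximum product).  S is therefore non-increasing along
#' any path away from the term and strictly positive.
#'
#' @param term Term id.
#' @param graph [load_ontology()] result.
#' @param weights [contribution_weights()].
#' @return Named numeric vector of S-values over the term and all its
#'   ancestors.
#' @export
s_values <- function(term, graph, weights = contribution_weights()) {
  if (!term %in% graph$terms$id) stop("unknown term: ", term)
  S <- c(1); names(S) <- term
  queue <- term
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    par <- graph$parents[[t]]
    if (is.null(par)) next
    for (i in seq_len(nrow(par))) {
      p <- par$parent[i]
      cand <- unname(weights[[par$type[i]]]) * S[[t]]
      if (is.na(S[p]) || cand > S[[p]]) {
        S[p] <- cand
        queue <- c(queue, p)
      }
    }
  }
  S
}

#' Wang similarity between two terms
#'
#' The S-value mass of the shared ancestors of the two terms, relative to
#' their total semantic values:
#' `sum(S1[shared] + S2[shared]) / (sum(S1) + sum(S2))`.
#' Symmetric, bounded in \[0, 1\], and exactly 1 for identical terms.  Both
#' terms must belong to the same namespace.
#'
#' @param t1,t2 Term ids.
#' @inheritParams s_values
#' @return Similarity in \[0, 1\].
#' @export
term_similarity <- function(t1, t2, graph, weights = contribution_weights()) {
  ns1 <- term_namespace(graph, t1); ns2 <- term_namespace(graph, t2)
  if (!identical(ns1, ns2))
    stop("terms belong to different namespaces: ", ns1, " vs ", ns2)
  if (t1 == t2) return(1)
  s1 <- s_values(t1, graph, weights)
  s2 <- s_values(t2, graph, weights)
  shared <- intersect(names(s1), names(s2))
  if (!length(shared)) return(0)
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

#' Semantic similarity between two annotated genes
#'
#' Aggregates term-level similarities over the two genes' term sets in one
#' namespace.  The default is the best-match average
#' `(sum_i max_j sim + sum_j max_i sim) / (m + n)`; `method = "max"` takes
#' the single best pair.  A gene with no annotation in the namespace makes
#' the comparison undefined (NA with a reason attribute): at least two
#' annotated genes are required for a comparison.
#'
#' @param terms_a,terms_b Character vectors of term ids (one namespace).
#' @inheritParams s_values
#' @param method `"bma"` (best-match average) or `"max"`.
#' @return Similarity in \[0, 1\], or NA when undefined.
#' @export
gene_similarity <- function(terms_a, terms_b, graph,
                            weights = contribution_weights(),
                            method = c("bma", "max")) {
  method <- match.arg(method)
  terms_a <- unique(terms_a); terms_b <- unique(terms_b)
  if (length(terms_a) == 0L || length(terms_b) == 0L)
    return(structure(NA_real_, reason = "unannotated_gene"))
  sim <- outer(terms_a, terms_b,
               Vectorize(function(u, v) term_similarity(u, v, graph, weights)))
  if (method == "max") return(max(sim))
  (sum(apply(sim, 1L, max)) + sum(apply(sim, 2L, max))) /
    (length(terms_a) + length(terms_b))
}

#' Read GAF-style gene annotations
#'
#' Tab-delimited with columns gene_id, term_id, evidence, aspect and an
#' optional qualifier column; a header row is detected by a first field of
#' `gene_id`.  Aspect accepts the one-letter codes (P, F, C) or full
#' namespace names.  Rows whose qualifier contains `NOT` are dropped.
#'
#' @param path Annotation file.
#' @return Data frame: gene_id, term_id, evidence, aspect (full namespace
#'   names).
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 1L)
  header <- startsWith(first, "gene_id")
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                           comment.char = "!")
  if (!header) {
    names(tab)[1:min(5L, ncol(tab))] <-
      c("gene_id", "term_id", "evidence", "aspect", "qualifier")[1:min(5L, ncol(tab))]
  }
  stopifnot(all(c("gene_id", "term_id", "evidence", "aspect") %in% names(tab)))
  if (!is.null(tab$qualifier))
    tab <- tab[!grepl("NOT", tab$qualifier), , drop = FALSE]
  ns_map <- c(P = "biological_process", F = "molecular_function",
              C = "cellular_component",
              biological_process = "biological_process",
              molecular_function = "molecular_function",
              cellular_component = "cellular_component")
  tab$aspect <- unname(ns_map[as.character(tab$aspect)])
  if (anyNA(tab$aspect)) stop("unknown aspect code in ", path)
  tab[, c("gene_id", "term_id", "evidence", "aspect")]
}

#' Per-namespace semantic similarity of a duplicate group
#'
#' Computes all pairwise gene similarities per GO namespace among the
#' annotated members (a namespace needs at least two annotated genes), plus
#' the group's proportion of electronically inferred (IEA) annotations.
#' GO characterisation is restricted to groups of at most `cap` genes
#' (default 15).
#'
#' @param members Character vector of member gene ids.
#' @param annotations Data frame from [read_annotations()].
#' @param graph [load_ontology()] result.
#' @param weights [contribution_weights()].
#' @param cap Maximum group size.
#' @param method Gene-level aggregation, see [gene_similarity()].
#' @return A `group_semantic_similarity` list: `pairs` (data frame gene_a,
#'   gene_b, namespace, similarity), `iea_proportion`, `n_annotations`,
#'   `skipped_reason` (NA unless the group was skipped).
#' @export
group_semantic_similarity <- function(members, annotations, graph,
                                      weights = contribution_weights(),
                                      cap = 15L, method = "bma") {
  skip <- function(reason)
    structure(list(pairs = NULL, iea_proportion = NA_real_,
                   n_annotations = 0L, skipped_reason = reason),
              class = "group_semantic_similarity")
  if (length(members) > cap) return(skip("group_size_exceeds_cap"))
  ann <- annotations[annotations$gene_id %in% members &
                     annotations$term_id %in% graph$terms$id, , drop = FALSE]
  n_ann <- nrow(ann)
  iea <- if (n_ann) mean(ann$evidence == "IEA") else NA_real_
  rows <- list()
  for (ns in unique(graph$terms$namespace)) {
    sub <- ann[ann$aspect == ns, , drop = FALSE]
    by_gene <- split(sub$term_id, sub$gene_id)
    annotated <- names(by_gene)
    if (length(annotated) < 2L) next
    pr <- utils::combn(sort(annotated), 2L)
    for (k in seq_len(ncol(pr))) {
      val <- gene_similarity(by_gene[[pr[1L, k]]], by_gene[[pr[2L, k]]],
                             graph, weights, method)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = pr[1L, k], gene_b = pr[2L, k], namespace = ns,
        similarity = as.numeric(val), stringsAsFactors = FALSE)
    }
  }
  structure(list(pairs = if (length(rows)) do.call(rbind, rows) else NULL,
                 iea_proportion = iea, n_annotations = n_ann,
                 skipped_reason = NA_character_),
            class = "group_semantic_similarity")
}
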