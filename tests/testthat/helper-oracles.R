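# Independent oracles used to validate the implementation.  These are kept
# deliberately naive (plain dynamic programming, explicit path enumeration)
# and share no code with the package internals they check.

# Smith-Waterman score by plain dynamic programming with affine gaps; a gap
# of length k costs open + k * ext.
sw_score_oracle <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - (open + ext), F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# S-values by exhaustive enumeration of every child->parent path, taking the
# maximum path product per ancestor.
s_values_oracle <- function(term, graph, weights) {
  vals <- numeric(0); labs <- character(0)
  enum <- function(t, v) {
    vals <<- c(vals, v); labs <<- c(labs, t)
    par <- graph$parents[[t]]
    if (is.null(par)) return(invisible())
    for (i in seq_len(nrow(par)))
      enum(par$parent[i], v * unname(weights[[par$type[i]]]))
  }
  enum(term, 1)
  agg <- tapply(vals, labs, max)
  stats::setNames(as.numeric(agg), names(agg))
}

term_similarity_oracle <- function(t1, t2, graph, weights) {
  s1 <- s_values_oracle(t1, graph, weights)
  s2 <- s_values_oracle(t2, graph, weights)
  shared <- intersect(names(s1), names(s2))
  if (!length(shared)) return(0)
  sum(s1[shared] + s2[shared]) / (sum(s1) + sum(s2))
}

gene_similarity_oracle <- function(ta, tb, graph, weights) {
  ta <- unique(ta); tb <- unique(tb)
  sim <- matrix(0, length(ta), length(tb))
  for (i in seq_along(ta))
    for (j in seq_along(tb))
      sim[i, j] <- term_similarity_oracle(ta[i], tb[j], graph, weights)
  (sum(apply(sim, 1, max)) + sum(apply(sim, 2, max))) /
    (length(ta) + length(tb))
}

# Random small ontology (one namespace, <= 15 terms, diamonds allowed)
# emitted as OBO text; term 1 is the root.
random_toy_obo <- function(seed, max_terms = 15) {
  set.seed(seed)
  n <- sample(6:max_terms, 1)
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(n)) {
    lines <- c(lines, "[Term]", sprintf("id: T:%03d", i),
               sprintf("name: term %d", i), "namespace: biological_process")
    if (i > 1) {
      parents <- sample(seq_len(i - 1), min(sample(1:2, 1), i - 1))
      for (p in parents) {
        if (runif(1) < 0.7)
          lines <- c(lines, sprintf("is_a: T:%03d", p))
        else
          lines <- c(lines, sprintf("relationship: part_of T:%03d", p))
      }
    }
    lines <- c(lines, "")
  }
  lines
}

load_obo_text <- function(lines) {
  f <- withr::local_tempfile(fileext = ".obo",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  load_ontology(f)
}
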