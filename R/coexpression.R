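# Expression co-correlation of duplicate groups: dataset filtering, pairwise
# Pearson tests, per-group proportions of significant correlations, control
# group sampling and class comparison.

#' Expression dataset container
#'
#' A genes x samples numeric matrix with row names = gene ids and column
#' names = sample ids; missing values are allowed.
#'
#' @param dataset_id Identifier of the dataset (e.g. an experiment series).
#' @param mat Numeric matrix; rownames gene ids, colnames sample ids.
#' @return An `expression_dataset` object.
#' @export
expression_dataset <- function(dataset_id, mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L, ncol(mat) >= 1L,
            !is.null(rownames(mat)), !is.null(colnames(mat)),
            !anyDuplicated(colnames(mat)), !anyDuplicated(rownames(mat)))
  structure(list(dataset_id = dataset_id, mat = mat),
            class = "expression_dataset")
}

#' Read a genes x samples expression matrix
#'
#' Tab-delimited: first column gene id, header row of sample ids; missing
#' values empty or NA.
#'
#' @param path Matrix file.
#' @param dataset_id Dataset identifier; defaults to the file name.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, dataset_id = NULL) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(tab[[1L]])
  expression_dataset(dataset_id %||% basename(path), mat)
}

#' Write an expression dataset in the tab-delimited layout
#' @param ds An [expression_dataset()].
#' @param path Output file.
#' @export
write_expression <- function(ds, path) {
  out <- data.frame(gene_id = rownames(ds$mat), ds$mat,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Filter expression datasets eligible for a group
#'
#' A dataset is kept when (a) it has at least 3 samples, (b) every member
#' gene of the group is present, and (c) no member's profile is entirely
#' missing or constant across samples.
#'
#' @param members Character vector of member gene ids.
#' @param datasets List of [expression_dataset()] objects.
#' @return The eligible subset of `datasets`.
#' @export
filter_datasets <- function(members, datasets) {
  Filter(function(ds) {
    if (ncol(ds$mat) < 3L) return(FALSE)
    if (!all(members %in% rownames(ds$mat))) return(FALSE)
    for (g in members) {
      v <- ds$mat[g, ]
      v <- v[!is.na(v)]
      if (length(v) == 0L || length(unique(v)) == 1L) return(FALSE)
    }
    TRUE
  }, datasets)
}

#' Pearson correlation with a two-sided (bilateral) test
#'
#' Pairwise-complete observations; the p-value comes from the t distribution
#' with n - 2 degrees of freedom.  Pairs with fewer than 3 complete
#' observations, or a constant profile, return NA with a reason and are
#' counted as skipped by the callers.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List `r`, `p`, `n` (complete observations), `reason` (NA when the
#'   test was performed).
#' @export
pairwise_pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L)
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "too_few_observations"))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, reason = "constant_profile"))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n, reason = NA_character_)
}

#' Proportion of significant pairwise correlations for a gene group
#'
#' For every unordered gene pair of the group and every eligible dataset
#' (see [filter_datasets()]), the Pearson correlation and its two-sided
#' p-value are computed; the proportion of tests with p below `alpha` is
#' returned.  Expression characterisation is restricted to small groups
#' (default at most 5 genes), as data for larger groups is typically too
#' incomplete.
#'
#' @param members Character vector of member gene ids.
#' @param datasets List of [expression_dataset()] objects.
#' @param alpha Significance level (default 0.05).
#' @param max_group_size Size cap; larger groups are skipped with a reason.
#' @param p_adjust Multiple-testing adjustment applied across the group's
#'   tests before thresholding ("none" by default, matching a raw
#'   proportion-of-significant reading; "BH" available).
#' @param by `"pooled"` (default): one proportion over all pair x dataset
#'   tests; `"pair"`: mean of per-pair proportions across datasets.
#' @return A `group_correlation` list: `proportion`, `n_tests`,
#'   `n_significant`, `n_skipped`, `n_datasets`, `tests` (data frame:
#'   dataset_id, gene_a, gene_b, r, p, n), `skipped_reason` (NA unless the
#'   whole group was skipped).
#' @export
proportion_significant <- function(members, datasets, alpha = 0.05,
                                   max_group_size = 5L,
                                   p_adjust = c("none", "BH"),
                                   by = c("pooled", "pair")) {
  p_adjust <- match.arg(p_adjust)
  by <- match.arg(by)
  skip <- function(reason)
    structure(list(proportion = NA_real_, n_tests = 0L, n_significant = 0L,
                   n_skipped = 0L, n_datasets = 0L,
                   tests = NULL, skipped_reason = reason),
              class = "group_correlation")
  if (length(members) < 2L) return(skip("fewer_than_two_genes"))
  if (length(members) > max_group_size) return(skip("group_size_exceeds_cap"))
  eligible <- filter_datasets(members, datasets)
  if (length(eligible) == 0L) return(skip("no_eligible_dataset"))
  pairs <- utils::combn(sort(members), 2L)
  rows <- list()
  for (ds in eligible) {
    for (k in seq_len(ncol(pairs))) {
      res <- pairwise_pearson(ds$mat[pairs[1L, k], ], ds$mat[pairs[2L, k], ])
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_id = ds$dataset_id, gene_a = pairs[1L, k], gene_b = pairs[2L, k],
        r = res$r, p = res$p, n = res$n, reason = res$reason,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  valid <- !is.na(tests$p)
  if (!any(valid)) return(skip("no_valid_test"))
  p_use <- tests$p
  if (p_adjust == "BH") p_use[valid] <- stats::p.adjust(tests$p[valid], "BH")
  tests$significant <- !is.na(p_use) & p_use < alpha
  proportion <- if (by == "pooled") {
    sum(tests$significant[valid]) / sum(valid)
  } else {
    key <- paste(tests$gene_a, tests$gene_b)[valid]
    mean(tapply(tests$significant[valid], key, mean))
  }
  structure(list(proportion = proportion,
                 n_tests = sum(valid),
                 n_significant = sum(tests$significant[valid]),
                 n_skipped = sum(!valid),
                 n_datasets = length(eligible),
                 tests = tests, skipped_reason = NA_character_),
            class = "group_correlation")
}

#' Sample control gene groups
#'
#' Controls for the co-expression comparison: `colocalised` groups are runs
#' of adjacent-rank genes none of which belong to a duplicate group;
#' `random` groups are uniform draws (without replacement within a group)
#' from all non-duplicated genes genome-wide.  Sizes are usually matched to
#' the duplicated-group size distribution.
#'
#' @param index [build_gene_index()].
#' @param exclude Gene ids already in duplicate groups.
#' @param kind `"colocalised"` or `"random"`.
#' @param sizes Integer vector: one control group per element.
#' @param seed Optional seed for reproducible draws.
#' @return List of character vectors of gene ids.
#' @export
sample_control_groups <- function(index, exclude,
                                  kind = c("colocalised", "random"),
                                  sizes, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(index, "gene_index"), all(sizes >= 2L))
  pool <- index[!(index$gene_id %in% exclude), , drop = FALSE]
  if (nrow(pool) < max(sizes))
    stop("not enough non-duplicated genes to sample control groups")
  with_seed(seed, {
    lapply(sizes, function(size) {
      if (kind == "random") {
        sample(pool$gene_id, size)
      } else {
        # feasible starts: `size` consecutive ranks, all non-duplicated
        ok <- index$gene_id %in% pool$gene_id
        starts <- list()
        for (chrom in unique(index$chromosome)) {
          sub <- which(index$chromosome == chrom)
          okc <- ok[sub]
          if (length(okc) < size) next
          run <- stats::filter(as.numeric(okc), rep(1, size), sides = 1)
          pos <- which(run == size) - size + 1L
          if (length(pos)) starts[[chrom]] <- sub[pos]
        }
        starts <- unlist(starts, use.names = FALSE)
        if (is.null(starts) || length(starts) == 0L)
          stop("no run of ", size, " adjacent non-duplicated genes available")
        s <- if (length(starts) == 1L) starts else sample(starts, 1L)
        index$gene_id[s:(s + size - 1L)]
      }
    })
  })
}

#' Compare proportions of significant correlations between group classes
#'
#' Two-sample t-test in the unequal-variance (Welch) form, two-sided.
#'
#' @param a,b Numeric vectors of per-group proportions (NAs dropped).
#' @return List `t`, `p`, `mean_a`, `mean_b`.
#' @export
compare_proportions <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # Welch statistic is degenerate without variance; identical constant
    # samples are indistinguishable, distinct ones maximally separated
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(list(t = 0, p = 1, mean_a = mean(a), mean_b = mean(b)))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_a = mean(a), mean_b = mean(b))
}
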