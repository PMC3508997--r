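#' Scoring scheme for local peptide alignment
#'
#' Conventional protein-search defaults: BLOSUM62 with affine gap penalties
#' of 11 (open) and 1 (extend), so a gap of length k costs 11 + k.  Unknown
#' residues (X) score 0 against everything.
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (e.g. "BLOSUM62", "BLOSUM45", "PAM250").
#' @param gap_open,gap_extend Positive gap penalties in score units.
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  stopifnot(is.character(matrix), length(matrix) == 1L,
            gap_open > 0, gap_extend > 0)
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

# Fetch a Biostrings substitution matrix with the X row/column zeroed.
substitution_matrix <- function(scoring) {
  env <- new.env()
  utils::data(list = scoring$matrix, package = "Biostrings", envir = env)
  mat <- env[[scoring$matrix]]
  if (!isTRUE(all.equal(mat, t(mat))))
    stop("substitution matrix must be symmetric")
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
  }
  mat
}

#' Detection parameters for the duplicate-pair criterion
#'
#' Defaults follow the published method: BLAST-style hits are discarded when
#' the e-value exceeds 0.2 (a coarse relevance filter only); a pair is a
#' duplicate when the weighted identity I' reaches 30% for aligned regions of
#' at least 150 aa, or clears the twilight-zone curve [rost_threshold()] for
#' shorter alignments; candidate partners are restricted to a window of 100
#' genes on the same chromosome.  The curve offset n = 6 makes the two
#' branches continuous at the 150-aa breakpoint.
#'
#' @param evalue_max Maximum e-value for externally supplied alignments.
#' @param long_branch_cutoff Identity cutoff (proportion) for long alignments.
#' @param length_breakpoint Aligned length (aa) separating the two branches.
#' @param rost_n Offset n of the twilight-zone curve.
#' @param window Co-localisation window, in genes (rank distance).
#' @param short_branch_stat Statistic compared against the curve on the short
#'   branch: the weighted identity `"I_prime"` (default, conservative) or the
#'   raw identity `"I"`.
#' @return A `detection_params` object.
#' @export
detection_params <- function(evalue_max = 0.2,
                             long_branch_cutoff = 0.30,
                             length_breakpoint = 150,
                             rost_n = 6,
                             window = 100,
                             short_branch_stat = c("I_prime", "I")) {
  short_branch_stat <- match.arg(short_branch_stat)
  stopifnot(evalue_max > 0, long_branch_cutoff > 0, long_branch_cutoff <= 1,
            length_breakpoint > 0, rost_n > 0, window >= 1)
  if (abs(rost_threshold(length_breakpoint, rost_n) - long_branch_cutoff) >= 0.005)
    warning("threshold curve is discontinuous at the length breakpoint: ",
            "rost_threshold(", length_breakpoint, ", ", rost_n, ") and the ",
            "long-branch cutoff differ by >= 0.005")
  structure(list(evalue_max = evalue_max,
                 long_branch_cutoff = long_branch_cutoff,
                 length_breakpoint = length_breakpoint,
                 rost_n = rost_n,
                 window = as.integer(window),
                 short_branch_stat = short_branch_stat),
            class = "detection_params")
}

#' Length-dependent identity threshold (twilight-zone curve)
#'
#' Rost's empirical curve separating likely homologs from the twilight zone,
#' on the proportion scale:
#' `0.01 * n + 4.8 * L^(-0.32 * (1 + exp(-L / 1000)))`.
#' Short alignments demand much higher identity; with the default offset
#' n = 6 the curve meets the 30% long-alignment cutoff at L = 150.
#'
#' @param L Aligned-region length(s) in amino acids (>= 1), gaps included.
#' @param n Curve offset; 6 by default.
#' @return Threshold proportion(s); may exceed 1 for very short alignments,
#'   in which case no alignment of that length can pass.
#' @export
#' @examples
#' rost_threshold(150)   # ~0.303, i.e. 30% at the breakpoint
#' rost_threshold(50)    # ~0.477: short alignments need far higher identity
rost_threshold <- function(L, n = 6) {
  stopifnot(is.numeric(L), all(L >= 1), is.numeric(n), n > 0)
  0.01 * n + 4.8 * L^(-0.32 * (1 + exp(-L / 1000)))
}

#' Pairwise alignment record
#'
#' Container for one local alignment between two peptides, carrying the
#' quantities the duplicate criterion needs: `L` the aligned-region length in
#' columns (gaps included), `identities` the count of identical aligned
#' residue pairs, `n_query`/`n_subject` the residues of each sequence inside
#' the aligned region, and `L_query`/`L_subject` the full sequence lengths.
#' An empty alignment (no positive-scoring region) has `L = 0`.
#'
#' @param query_id,subject_id Peptide or gene identifiers.
#' @param L,identities,n_query,n_subject,L_query,L_subject Integer counts,
#'   see above.
#' @param score Alignment score (NA when unknown).
#' @param e_value Expectation value; NA for internal alignments, which carry
#'   none.
#' @return An `alignment_result` object.
#' @export
alignment_result <- function(query_id, subject_id, L, identities,
                             n_query, n_subject, L_query, L_subject,
                             score = NA_real_, e_value = NA_real_) {
  stopifnot(L >= 0, identities >= 0, identities <= max(L, 0),
            n_query <= max(L, 1) || L == 0, n_subject <= max(L, 1) || L == 0,
            n_query <= L_query, n_subject <= L_subject,
            L_query >= 1, L_subject >= 1)
  if (L > 0 && (n_query > L || n_subject > L))
    stop("residue counts n_i cannot exceed the aligned length L")
  structure(list(query_id = query_id, subject_id = subject_id,
                 L = as.integer(L), identities = as.integer(identities),
                 n_query = as.integer(n_query), n_subject = as.integer(n_subject),
                 L_query = as.integer(L_query), L_subject = as.integer(L_subject),
                 score = as.numeric(score), e_value = as.numeric(e_value)),
            class = "alignment_result")
}

#' Raw and weighted alignment identity
#'
#' `I` is the proportion of identical amino acids over the aligned region,
#' gap columns included in the denominator.  The weighted identity
#' `I' = I * min(n1/L1, n2/L2)` down-weights alignments that cover only a
#' small fraction of either sequence, so a short protein perfectly matching
#' one domain of a much longer protein is not called a duplicate.
#'
#' @param aln An [alignment_result()] with `L > 0`.
#' @return List with elements `I` and `I_prime`, both in \[0, 1\].
#' @export
weighted_identity <- function(aln) {
  stopifnot(inherits(aln, "alignment_result"))
  if (aln$L <= 0) stop("weighted identity is undefined for an empty alignment")
  I <- aln$identities / aln$L
  coverage <- min(aln$n_query / aln$L_query, aln$n_subject / aln$L_subject)
  list(I = I, I_prime = I * coverage)
}

#' Decide whether an aligned peptide pair is a duplicate
#'
#' Applies the two criteria: (i) e-value at most `evalue_max` (skipped for
#' internal alignments, which carry no e-value); (ii) weighted identity I'
#' at least `long_branch_cutoff` when the aligned region is at least
#' `length_breakpoint` aa, or at least [rost_threshold()] of the aligned
#' length otherwise.  An empty alignment never passes.
#'
#' @param aln An [alignment_result()].
#' @param params A [detection_params()] object.
#' @return A `similarity_decision`: list with `I`, `I_prime`,
#'   `threshold_used`, `branch` ("long"/"short") and `passes`.
#' @export
is_duplicate_pair <- function(aln, params = detection_params()) {
  stopifnot(inherits(aln, "alignment_result"), inherits(params, "detection_params"))
  if (aln$L <= 0) {
    return(structure(list(I = NA_real_, I_prime = NA_real_,
                          threshold_used = NA_real_, branch = "short",
                          passes = FALSE),
                     class = "similarity_decision"))
  }
  wi <- weighted_identity(aln)
  long <- aln$L >= params$length_breakpoint
  threshold <- if (long) params$long_branch_cutoff
               else rost_threshold(aln$L, params$rost_n)
  stat <- if (long || params$short_branch_stat == "I_prime") wi$I_prime else wi$I
  evalue_ok <- is.na(aln$e_value) || aln$e_value <= params$evalue_max
  structure(list(I = wi$I, I_prime = wi$I_prime,
                 threshold_used = threshold,
                 branch = if (long) "long" else "short",
                 passes = evalue_ok && stat >= threshold),
            class = "similarity_decision")
}
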