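# Core atrophy-score arithmetic.
#
# All quantities are derived from four coordinates of a profile-HMM hit:
# hmm_start/hmm_end (match states matched, 1-based inclusive) and
# ali_start/ali_end (sequence residues aligned, 1-based inclusive), plus the
# model length L (number of match states of the family model).  The score at
# a boundary is (D - d)/L: the unmatched model states D at that boundary,
# minus the flanking sequence interval d that could still harbour them,
# over the model length.

#' Unmatched match states at the N-terminal boundary of a hit
#'
#' The number of profile-HMM match states before the first matched state,
#' i.e. the part of the family model with no aligned residues on the
#' N-terminal side of the hit.
#'
#' @param hmm_start First matched HMM match state (1-based), vectorised.
#' @return Integer vector: `hmm_start - 1`.
#' @examples
#' unmatched_states_n(101) # 100 leading model states unaccounted for
#' unmatched_states_n(1)   # complete N boundary
#' @export
unmatched_states_n <- function(hmm_start) {
  stopifnot(is.numeric(hmm_start), all(hmm_start >= 1))
  as.integer(hmm_start) - 1L
}

#' Unmatched match states at the C-terminal boundary of a hit
#'
#' @param hmm_end Last matched HMM match state (1-based), vectorised.
#' @param model_length Match-state count L of the family model.
#' @return Integer vector: `model_length - hmm_end`.
#' @export
unmatched_states_c <- function(hmm_end, model_length) {
  stopifnot(is.numeric(hmm_end), is.numeric(model_length),
            all(hmm_end >= 1), all(hmm_end <= model_length))
  as.integer(model_length) - as.integer(hmm_end)
}

#' Inter-domain interval upstream of a hit
#'
#' Residues between the hit's alignment start and the alignment end of the
#' adjacent upstream domain, or the sequence start.  Negative when hits
#' overlap or nest.
#'
#' @param ali_start Alignment start of the hit (1-based residue index).
#' @param upstream_end Alignment end of the nearest retained upstream hit,
#'   or `0` when the hit is the first on the protein.
#' @return Integer vector: `ali_start - upstream_end - 1`.
#' @examples
#' interval_n(35, 0)    # first domain, 34 free residues before it
#' interval_n(100, 120) # -21: overlap/nesting signal
#' @export
interval_n <- function(ali_start, upstream_end) {
  stopifnot(is.numeric(ali_start), is.numeric(upstream_end),
            all(ali_start >= 1), all(upstream_end >= 0))
  as.integer(ali_start) - as.integer(upstream_end) - 1L
}

#' Inter-domain interval downstream of a hit
#'
#' @param ali_end Alignment end of the hit.
#' @param downstream_start Alignment start of the nearest retained
#'   downstream hit, or `seq_length + 1` when the hit is the last.
#' @return Integer vector: `downstream_start - ali_end - 1`.
#' @export
interval_c <- function(ali_end, downstream_start) {
  stopifnot(is.numeric(ali_end), is.numeric(downstream_start),
            all(ali_end >= 1))
  as.integer(downstream_start) - as.integer(ali_end) - 1L
}

#' Atrophy score (D - d)/L
#'
#' The fraction of the family model that appears to be lost at a domain
#' boundary: the unmatched match states `D`, reduced by the flanking
#' sequence interval `d` (residues that could in principle contain the
#' missing region), relative to the model length `L`.  A score of 0.33 means
#' roughly one third of the domain is missing; zero or negative scores mean
#' a complete boundary; scores above 1 arise only from negative intervals
#' and signal a nested-domain architecture.
#'
#' @param D Unmatched match states at the boundary (integer, `0 <= D <= L`).
#' @param d Inter-domain interval in residues (integer, may be negative).
#' @param L Model length in match states (`L >= 1`).
#' @return Double vector `(D - d)/L`, unclamped.
#' @examples
#' atrophy_score(100, 34, 200) # 0.33: one third of the model lost
#' atrophy_score(0, 49, 100)   # -0.49: complete boundary, no atrophy
#' atrophy_score(80, -21, 90)  # > 1: nesting candidate
#' @export
atrophy_score <- function(D, d, L) {
  stopifnot(is.numeric(D), is.numeric(d), is.numeric(L))
  if (any(L < 1)) {
    stop("atrophy_score(): model length L must be >= 1", call. = FALSE)
  }
  if (any(D < 0 | D > L)) {
    stop("atrophy_score(): D must satisfy 0 <= D <= L", call. = FALSE)
  }
  (as.numeric(D) - as.numeric(d)) / as.numeric(L)
}

#' Exact comparison of an atrophy score against a decimal threshold
#'
#' Scores are rationals (D - d)/L with integer numerator and denominator;
#' comparing them against thresholds such as 0.15 in floating point risks
#' misclassifying exact-boundary cases (e.g. D - d = 30, L = 200).  The
#' comparison is therefore done on integers: the threshold is interpreted as
#' a rational with denominator 10^6 (more precision than any sensible
#' threshold carries) and cross-multiplied.
#'
#' @param num Integer numerator `D - d` (vectorised).
#' @param L Model length.
#' @param threshold Decimal threshold.
#' @param op One of `">="`, `"<="`.
#' @return Logical vector.
#' @keywords internal
score_cmp <- function(num, L, threshold, op = c(">=", "<=")) {
  op <- match.arg(op)
  lhs <- as.numeric(num) * 1e6
  rhs <- round(threshold * 1e6) * as.numeric(L)
  if (op == ">=") lhs >= rhs else lhs <= rhs
}

#' Assemble a score breakdown row
#'
#' @param terminus `"N"`, `"C"` or `"W"` (within-domain).
#' @param D,d,L Score ingredients (see [atrophy_score()]).
#' @return A one-row tibble with columns `terminus`, `D`, `d`, `L`, `score`.
#' @export
score_breakdown <- function(terminus, D, d, L) {
  terminus <- match.arg(terminus, c("N", "C", "W"))
  tibble::tibble(terminus = terminus, D = as.integer(D), d = as.integer(d),
                 L = as.integer(L), score = atrophy_score(D, d, L))
}

#' Distinguish a split domain from a tandem repeat
#'
#' Two same-family hits on one protein are two fragments of a single split
#' domain when the downstream fragment resumes the model where the upstream
#' fragment left off: its start HMM match state is strictly greater than the
#' upstream fragment's end match state.  If instead the downstream hit
#' re-covers model states already matched upstream, the pair is a tandem
#' repeat, not atrophy.
#'
#' @param upstream,downstream One-row data frames (or lists) with fields
#'   `protein_acc`, `family_acc`, `hmm_start`, `hmm_end`, `ali_start`,
#'   `model_length`; `downstream` must start after `upstream` on the
#'   sequence.
#' @return `TRUE` for a split pair, `FALSE` for tandem/ambiguous re-coverage
#'   (a shared boundary match state counts as re-coverage).
#' @export
is_split_pair <- function(upstream, downstream) {
  check_pair(upstream, downstream)
  downstream$hmm_start > upstream$hmm_end
}

check_pair <- function(upstream, downstream) {
  if (!identical(as.character(upstream$protein_acc),
                 as.character(downstream$protein_acc))) {
    stop("pair contract: hits must be on the same protein", call. = FALSE)
  }
  if (!identical(as.character(upstream$family_acc),
                 as.character(downstream$family_acc))) {
    stop("pair contract: hits must be of the same family", call. = FALSE)
  }
  if (!identical(as.integer(upstream$model_length),
                 as.integer(downstream$model_length))) {
    stop("pair contract: model lengths differ within one family",
         call. = FALSE)
  }
  if (!(downstream$ali_start > upstream$ali_start)) {
    stop("pair contract: downstream hit must start after upstream hit",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Within-domain atrophy score of a split pair
#'
#' For two fragments of one split domain, the missing region is the run of
#' model states between the fragments (`D_W = hmm_start2 - hmm_end1 - 1`)
#' credited with the sequence linker between them
#' (`d_W = ali_start2 - ali_end1 - 1`), scored against the model length.
#'
#' @inheritParams is_split_pair
#' @return A one-row tibble as from [score_breakdown()] with
#'   `terminus = "W"`.
#' @export
within_pair_score <- function(upstream, downstream) {
  check_pair(upstream, downstream)
  if (!is_split_pair(upstream, downstream)) {
    stop("pair contract: not a split pair (tandem re-coverage of the model)",
         call. = FALSE)
  }
  D <- downstream$hmm_start - upstream$hmm_end - 1L
  d <- downstream$ali_start - upstream$ali_end - 1L
  score_breakdown("W", D, d, upstream$model_length)
}

#' Adjacency intervals for ordered hits on one protein
#'
#' Given the retained hits of one protein sorted by `(ali_start, ali_end,
#' family_acc)`, computes for each hit the alignment end of its nearest
#' upstream neighbour (0 at the sequence start) and the alignment start of
#' its nearest downstream neighbour (`seq_length + 1` at the sequence end).
#' The upstream boundary is the rightmost alignment end among all preceding
#' hits, so a hit inside another domain sees a negative upstream interval —
#' the nesting signal consumed by [flag_nested()].
#'
#' @param hits Data frame of hits on one protein, already sorted.
#' @param seq_length Protein sequence length.
#' @return The hits with added integer columns `upstream_end`,
#'   `downstream_start`, `d_n`, `d_c`.
#' @export
adjacency_intervals <- function(hits, seq_length) {
  n <- nrow(hits)
  stopifnot(n >= 1, all(hits$ali_end <= seq_length))
  prior_max_end <- c(0L, cummax(hits$ali_end)[-n])
  next_start <- c(hits$ali_start[-1], as.integer(seq_length) + 1L)
  hits$upstream_end <- as.integer(prior_max_end)
  hits$downstream_start <- as.integer(next_start)
  hits$d_n <- interval_n(hits$ali_start, hits$upstream_end)
  hits$d_c <- interval_c(hits$ali_end, hits$downstream_start)
  hits
}
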