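# The automated filter cascade: sequence-level filters (protein existence,
# fragment status), per-protein overlap resolution, and call-level flags
# (clan adjacency, tandem re-coverage, nesting, small models, the candidate
# score window).  A call with an empty flag set whose score falls in the
# window is a candidate for manual triage.

#' Sequence-level filter: protein existence and fragment status
#'
#' Retains proteins whose existence level is in the allowed set (default:
#' level 1 only, experimental evidence at protein level) and that are not
#' annotated as sequence fragments.  Lower-evidence and fragment sequences
#' are enriched in gene-prediction errors that mimic atrophy.
#'
#' @param proteins Protein metadata, as from [read_protein_metadata()].
#' @param pe_allowed Integer vector of retained PE levels.
#' @return Character vector of retained accessions.
#' @export
filter_protein_level <- function(proteins, pe_allowed = 1L) {
  keep <- proteins$pe_level %in% as.integer(pe_allowed) &
    !proteins$is_fragment
  proteins$protein_acc[keep]
}

# TRUE when ranges [s1,e1], [s2,e2] overlap by more than `margin` residues
# and neither contains the other.  Containment is a nested-domain
# architecture, a sanctioned annotation pattern handled by flag_nested().
partial_overlap <- function(s1, e1, s2, e2, margin = 0L) {
  ov <- min(e1, e2) - max(s1, s2) + 1L
  contained <- (s1 <= s2 && e1 >= e2) || (s2 <= s1 && e2 >= e1)
  ov > margin && !contained
}

#' Resolve overlapping different-family hits on one protein
#'
#' Different-family hits whose alignment ranges partially overlap by more
#' than `overlap_margin` residues are resolved in favour of the hit with the
#' better (lower) E-value; ties are broken by longer alignment span, then
#' lexicographic family accession.  Hits are considered in that rank order
#' and flagged when they conflict with an already retained hit.  Full
#' containment (nesting) is exempt, as are same-family overlaps (split and
#' tandem logic applies there instead).  Flagged hits are excluded from both
#' candidacy and adjacency geometry.
#'
#' @param hits Hits of a single protein, sorted by `(ali_start, ali_end,
#'   family_acc)`.
#' @param overlap_margin Residues of tolerated overlap.
#' @return `hits` with an added logical column `overlap_flagged`.
#' @export
resolve_overlaps <- function(hits, overlap_margin = 0L) {
  n <- nrow(hits)
  hits$overlap_flagged <- rep(FALSE, n)
  if (n < 2) return(hits)
  ev <- ifelse(is.na(hits$evalue), Inf, hits$evalue)
  span <- hits$ali_end - hits$ali_start
  rank_order <- order(ev, -span, hits$family_acc)
  kept <- integer(0)
  for (i in rank_order) {
    conflict <- FALSE
    for (j in kept) {
      if (hits$family_acc[i] == hits$family_acc[j]) next
      if (partial_overlap(hits$ali_start[i], hits$ali_end[i],
                          hits$ali_start[j], hits$ali_end[j],
                          overlap_margin)) {
        conflict <- TRUE
        break
      }
    }
    if (conflict) hits$overlap_flagged[i] <- TRUE else kept <- c(kept, i)
  }
  hits
}

#' Flag nested-domain geometry on a scored call
#'
#' A negative inter-domain interval, or equivalently an atrophy score above
#' 1, arises when one domain is nested within another (the flanking
#' "interval" runs backwards into the neighbour).  Such calls are not
#' atrophy and are excluded.  The score comparison is exact:
#' `score > 1` iff `D - d > L` in integers.
#'
#' @param D,d,L Score ingredients (vectorised).
#' @return Logical vector: `TRUE` where the call is nested-flagged.
#' @export
flag_nested <- function(D, d, L) {
  d < 0 | (D - d) > L
}

#' Candidate score window
#'
#' A scored call is a triage candidate when its score lies in
#' `[min_score, max_score]`.  The comparison is performed on the exact
#' rational `(D - d)/L` (integer cross-multiplication), so a call with
#' `20 * (D - d) == 3 * L` sits exactly on the default 0.15 boundary and is
#' a candidate.
#'
#' @param D,d,L Score ingredients (vectorised).
#' @param min_score,max_score Window bounds.
#' @return Logical vector.
#' @export
filter_score_window <- function(D, d, L, min_score = 0.15, max_score = 1.0) {
  if (min_score > max_score) {
    abort_config(sprintf("min_score (%s) exceeds max_score (%s)",
                         min_score, max_score))
  }
  num <- D - d
  score_cmp(num, L, min_score, ">=") & score_cmp(num, L, max_score, "<=")
}

#' Flag small family models
#'
#' For models shorter than `min_model_length` match states (default 30), an
#' above-threshold score corresponds to the loss of at most one secondary
#' structural element, which is not considered atrophy.
#'
#' @param L Model length (vectorised).
#' @param min_model_length Threshold; models with `L < min_model_length`
#'   are flagged.
#' @return Logical vector.
#' @export
filter_small_domain <- function(L, min_model_length = 30L) {
  L < min_model_length
}

#' Flag same-clan adjacent hit pairs
#'
#' Adjacent (consecutive retained) hits whose families belong to the same
#' clan make the boundary between them ambiguous: the interval could belong
#' to either homologous model.  Both boundary calls facing the shared
#' interval are excluded.  A hit without clan membership never fires this
#' filter.
#'
#' @param hits Retained hits of one protein, sorted.
#' @return Integer matrix with one row per flagged pair and columns
#'   `upstream`, `downstream` (row indices into `hits`).
#' @export
filter_clan_adjacency <- function(hits) {
  n <- nrow(hits)
  out <- matrix(integer(0), ncol = 2,
                dimnames = list(NULL, c("upstream", "downstream")))
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    c1 <- hits$clan_acc[i]
    c2 <- hits$clan_acc[i + 1]
    if (!is.na(c1) && !is.na(c2) && c1 == c2) {
      out <- rbind(out, c(i, i + 1L))
    }
  }
  out
}
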