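# End-to-end detection: sequence-level filters -> per-protein overlap
# resolution -> call assembly -> call-level filters -> candidates.

#' Detect candidate domain-atrophy events
#'
#' Runs the full cascade on a hit table and its protein metadata:
#' \enumerate{
#'   \item keep proteins with allowed existence levels that are not
#'     fragments ([filter_protein_level()]);
#'   \item per protein, resolve partially overlapping different-family hits
#'     by E-value ([resolve_overlaps()]);
#'   \item score every retained boundary and split pair and classify it
#'     ([build_calls()]);
#'   \item attach nested / small-model / score-window flags
#'     ([apply_call_filters()]).
#' }
#' Calls with an empty flag set are the triage candidates.
#'
#' @param hits Hit table, as from [read_domain_hits()].
#' @param proteins Protein metadata, as from [read_protein_metadata()].
#' @param config An [atrophy_config()].
#' @return An object of class `atrophy_result`: a list with elements
#'   `calls` (every scored evaluation with flags), `candidates` (the
#'   flag-free subset), `dropped_hits` (overlap-flagged hits), `log`
#'   (a tibble of per-stage input/output counts) and `config`.
#' @export
detect_atrophy <- function(hits, proteins, config = atrophy_config()) {
  stopifnot(inherits(config, "atrophy_config"))
  proteins <- validate_proteins(proteins)
  validate_hits(hits)

  log <- list()
  note <- function(stage, in_n, out_n) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, in_count = as.integer(in_n), out_count = as.integer(out_n))
  }

  retained_acc <- filter_protein_level(proteins, config$pe_allowed)
  note("protein_existence_fragment", nrow(proteins), length(retained_acc))

  hits_pe <- hits[hits$protein_acc %in% retained_acc, , drop = FALSE]
  note("hits_on_retained_proteins", nrow(hits), nrow(hits_pe))

  hits_pe <- sort_hits(hits_pe)
  if (nrow(hits_pe) > 0) {
    per_protein <- split(hits_pe, hits_pe$protein_acc)
    resolved <- lapply(per_protein, resolve_overlaps,
                       overlap_margin = config$overlap_margin)
    hits_res <- tibble::as_tibble(do.call(rbind, unname(resolved)))
  } else {
    hits_res <- hits_pe
    hits_res$overlap_flagged <- logical(0)
  }
  dropped <- hits_res[hits_res$overlap_flagged, , drop = FALSE]
  retained_hits <- hits_res[!hits_res$overlap_flagged, , drop = FALSE]
  retained_hits$overlap_flagged <- NULL
  note("overlap_resolution", nrow(hits_res), nrow(retained_hits))

  calls <- build_calls(retained_hits, proteins)
  note("scored_evaluations", nrow(retained_hits), nrow(calls))

  calls <- apply_call_filters(calls, config)
  candidates <- calls[calls$candidate, , drop = FALSE]
  note("candidate_window", nrow(calls), nrow(candidates))

  structure(list(calls = calls,
                 candidates = candidates,
                 dropped_hits = dropped,
                 retained_hits = retained_hits,
                 log = do.call(rbind, log),
                 config = config),
            class = "atrophy_result")
}

#' @export
print.atrophy_result <- function(x, ...) {
  cat("domain atrophy screen\n")
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("  %-28s %8d -> %d\n", x$log$stage[i],
                x$log$in_count[i], x$log$out_count[i]))
  }
  cat(sprintf("candidates: %d (score window [%g, %g])\n",
              nrow(x$candidates), x$config$min_score, x$config$max_score))
  if (nrow(x$candidates) > 0) {
    tab <- table(factor(x$candidates$atrophy_class, levels = ATROPHY_CLASSES))
    for (cls in names(tab)) {
      cat(sprintf("  %-28s %d\n", cls, tab[[cls]]))
    }
  }
  invisible(x)
}
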