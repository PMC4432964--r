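# Filter configuration.

#' Filter configuration for the atrophy pipeline
#'
#' @param min_score Lower bound of the candidate score window (default 0.15:
#'   events losing less than 15 percent of the model are dominated by
#'   tolerated loss of peripheral elements and are not investigated).
#' @param max_score Upper bound of the window (default 1.0; higher scores
#'   arise only from nested architectures).
#' @param min_model_length Models shorter than this many match states are
#'   flagged `small_domain` (default 30: above-threshold scores on such
#'   models correspond to the loss of at most a single secondary-structure
#'   element).
#' @param overlap_margin Residues of alignment overlap tolerated between
#'   different-family hits before overlap resolution fires (default 0).
#' @param pe_allowed Protein-existence levels retained (default 1:
#'   experimental evidence at protein level).
#' @return A list of class `atrophy_config`.
#' @export
atrophy_config <- function(min_score = 0.15, max_score = 1.0,
                           min_model_length = 30L, overlap_margin = 0L,
                           pe_allowed = 1L) {
  if (!is.numeric(min_score) || !is.numeric(max_score) ||
      length(min_score) != 1 || length(max_score) != 1) {
    abort_config("min_score and max_score must be single numbers")
  }
  if (min_score > max_score) {
    abort_config(sprintf("min_score (%s) exceeds max_score (%s)",
                         min_score, max_score))
  }
  if (!is.numeric(min_model_length) || min_model_length < 1) {
    abort_config("min_model_length must be a positive integer")
  }
  if (!is.numeric(overlap_margin) || overlap_margin < 0) {
    abort_config("overlap_margin must be a non-negative integer")
  }
  pe_allowed <- as.integer(pe_allowed)
  if (length(pe_allowed) < 1 || !all(pe_allowed %in% 1:5)) {
    abort_config("pe_allowed must be a subset of 1:5")
  }
  structure(list(min_score = as.numeric(min_score),
                 max_score = as.numeric(max_score),
                 min_model_length = as.integer(min_model_length),
                 overlap_margin = as.integer(overlap_margin),
                 pe_allowed = pe_allowed),
            class = "atrophy_config")
}

#' Read a filter configuration from a YAML file
#'
#' Keys are the arguments of [atrophy_config()]; missing keys take the
#' defaults, unknown keys are a configuration error.
#'
#' @param path YAML file.
#' @return An `atrophy_config` object.
#' @export
read_atrophy_config <- function(path) {
  if (!file.exists(path)) {
    abort_config(sprintf("config file not found: %s", path))
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(atrophy_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort_config(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  do.call(atrophy_config, vals)
}

#' @export
print.atrophy_config <- function(x, ...) {
  cat("atrophy pipeline configuration\n")
  cat(sprintf("  score window:      [%g, %g]\n", x$min_score, x$max_score))
  cat(sprintf("  min model length:  %d match states\n", x$min_model_length))
  cat(sprintf("  overlap margin:    %d residues\n", x$overlap_margin))
  cat(sprintf("  PE levels kept:    %s\n",
              paste(x$pe_allowed, collapse = ", ")))
  invisible(x)
}
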