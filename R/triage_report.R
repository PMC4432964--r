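# Combining candidate calls with manual triage verdicts into summary
# statistics: per-class verdict tallies with column percentages, failure-mode
# counts, positive predictive value and the atrophy fraction of all scored
# domain instances.

VERDICT_LEVELS <- c("true_atrophy_structure", "putative_atrophy_homolog",
                    "false_positive", "unknown")

FAILURE_MODES <- c("gene_prediction_error", "nested_domain",
                   "multi_domain_family", "small_domain",
                   "circular_permutation", "short_repeat",
                   "disordered_domain", "theoretical_model",
                   "no_reference_structure", "complete_structural_domain")

#' Read a manual-triage verdict table
#'
#' Tab-separated with header `call_id`, `verdict`, `failure_mode`.  The
#' verdict is one of `true_atrophy_structure` (atrophy confirmed in a solved
#' structure), `putative_atrophy_homolog` (inferred by mapping onto a
#' homologous structure), `false_positive` or `unknown` (no structure to
#' judge against).  `failure_mode` must be present exactly when the verdict
#' is `false_positive`, and must be one of the ten recognised labels.
#' An optional `atrophy_class` column is carried through if present.
#'
#' @param path File to read.
#' @return A tibble of verdicts.
#' @export
read_triage_verdicts <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("verdict file not found: %s", path))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = "",
                           quote = "")
  need <- c("call_id", "verdict", "failure_mode")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf("verdict table %s lacks column(s): %s",
                             path, paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(call_id = raw$call_id,
                        verdict = raw$verdict,
                        failure_mode = raw$failure_mode)
  if ("atrophy_class" %in% names(raw)) out$atrophy_class <- raw$atrophy_class
  validate_verdicts(out, source = path)
}

validate_verdicts <- function(verdicts, source = "<verdicts>") {
  bad <- which(!(verdicts$verdict %in% VERDICT_LEVELS))
  if (length(bad)) {
    abort_validation(sprintf("%s: row %d: unknown verdict '%s'",
                             source, bad[1], verdicts$verdict[bad[1]]))
  }
  fp <- verdicts$verdict == "false_positive"
  bad <- which(fp & is.na(verdicts$failure_mode))
  if (length(bad)) {
    abort_validation(sprintf(
      "%s: row %d: false_positive verdict lacks a failure_mode",
      source, bad[1]))
  }
  bad <- which(!fp & !is.na(verdicts$failure_mode))
  if (length(bad)) {
    abort_validation(sprintf(
      "%s: row %d: failure_mode given for a non-false_positive verdict",
      source, bad[1]))
  }
  bad <- which(fp & !(verdicts$failure_mode %in% FAILURE_MODES))
  if (length(bad)) {
    abort_validation(sprintf("%s: row %d: unknown failure_mode '%s'",
                             source, bad[1], verdicts$failure_mode[bad[1]]))
  }
  dup <- verdicts$call_id[duplicated(verdicts$call_id)]
  if (length(dup) > 0) {
    abort_validation(sprintf("%s: duplicate verdict for call %s",
                             source, dup[1]))
  }
  verdicts
}

#' Positive predictive value
#'
#' `true / (true + false)`, rounded to three decimal places.  Unverdicted
#' ("unknown") candidates are excluded from the denominator.
#'
#' @param true_count Confirmed plus putative atrophy calls.
#' @param false_count Failure-mode / false-positive calls.
#' @return A double, or `NA_real_` when both counts are zero.
#' @examples
#' ppv(75, 1287) # 0.055
#' @export
ppv <- function(true_count, false_count) {
  stopifnot(true_count >= 0, false_count >= 0)
  if (true_count + false_count == 0) return(NA_real_)
  round(true_count / (true_count + false_count), 3)
}

#' Summarise manual triage verdicts
#'
#' Builds the triage contingency table: per-class counts of confirmed
#' (structure), putative (homolog), false-positive and unknown verdicts with
#' column percentages (two decimal places), the failure-mode tally, the
#' positive predictive value (three decimal places) and — when the total
#' number of scored domain instances is supplied — the atrophy fraction,
#' `true / total_instances * 100`.
#'
#' The atrophy fraction is truncated (not rounded) to two decimal places:
#' the statistic answers "what fraction of domain instances shows atrophy"
#' and truncation reports the digits actually attained.
#'
#' @param verdicts Verdict table (see [read_triage_verdicts()]); must carry
#'   an `atrophy_class` column or be joinable to `candidates` by `call_id`.
#' @param candidates Optional candidate call table used to resolve each
#'   verdict's `atrophy_class` and to count unverdicted candidates.
#' @param total_instances Optional count of all scored domain instances
#'   (the atrophy-fraction denominator).
#' @return An object of class `triage_summary`.
#' @export
triage_summary <- function(verdicts, candidates = NULL,
                           total_instances = NULL) {
  verdicts <- validate_verdicts(tibble::as_tibble(verdicts))
  unverdicted <- 0L
  if (!is.null(candidates)) {
    missing_ids <- setdiff(verdicts$call_id, candidates$call_id)
    if (length(missing_ids) > 0) {
      abort_validation(sprintf(
        "verdict references unknown call_id: %s",
        paste(utils::head(missing_ids, 5), collapse = ", ")))
    }
    unverdicted <- sum(!(candidates$call_id %in% verdicts$call_id))
    if (!("atrophy_class" %in% names(verdicts))) {
      idx <- match(verdicts$call_id, candidates$call_id)
      verdicts$atrophy_class <- candidates$atrophy_class[idx]
    }
  }
  if (!("atrophy_class" %in% names(verdicts))) {
    abort_validation(paste("verdicts carry no atrophy_class and no",
                           "candidate table was given to resolve one"))
  }
  bad <- which(!(verdicts$atrophy_class %in% ATROPHY_CLASSES))
  if (length(bad)) {
    abort_validation(sprintf("row %d: unknown atrophy_class '%s'",
                             bad[1], verdicts$atrophy_class[bad[1]]))
  }

  cls <- factor(verdicts$atrophy_class, levels = ATROPHY_CLASSES)
  vrd <- factor(verdicts$verdict, levels = VERDICT_LEVELS)
  counts <- table(vrd, cls)
  counts <- matrix(as.integer(counts), nrow = 4,
                   dimnames = list(verdict = VERDICT_LEVELS,
                                   atrophy_class = ATROPHY_CLASSES))
  col_totals <- colSums(counts)
  pct <- counts
  pct[] <- 0
  nz <- col_totals > 0
  pct[, nz] <- round(sweep(counts[, nz, drop = FALSE], 2,
                           col_totals[nz], "/") * 100, 2)

  fm <- verdicts$failure_mode[verdicts$verdict == "false_positive"]
  failure_mode_counts <- table(factor(fm, levels = FAILURE_MODES))
  failure_mode_counts <- stats::setNames(as.integer(failure_mode_counts),
                                         FAILURE_MODES)

  true_n <- sum(counts["true_atrophy_structure", ]) +
    sum(counts["putative_atrophy_homolog", ])
  false_n <- sum(counts["false_positive", ])
  unknown_n <- sum(counts["unknown", ])
  inspected <- true_n + false_n + unknown_n

  frac <- NA_real_
  if (!is.null(total_instances)) {
    stopifnot(is.numeric(total_instances), total_instances > 0)
    frac <- trunc(true_n / total_instances * 100 * 100) / 100
  }

  structure(list(per_class_counts = counts,
                 per_class_percent = pct,
                 class_totals = col_totals,
                 failure_mode_counts = failure_mode_counts,
                 totals = c(inspected = inspected, true = true_n,
                            false = false_n, unknown = unknown_n,
                            unverdicted = as.integer(unverdicted)),
                 ppv = ppv(true_n, false_n),
                 total_instances = if (is.null(total_instances)) NA_real_
                                   else as.numeric(total_instances),
                 atrophy_fraction_percent = frac),
            class = "triage_summary")
}

#' @export
print.triage_summary <- function(x, ...) {
  cat("manual triage summary\n\n")
  short <- c("N-term end", "C-term end", "upstream", "downstream", "within")
  hdr <- sprintf("%-26s %12s %12s %12s %12s %12s", "", short[1], short[2],
                 short[3], short[4], short[5])
  cat(hdr, "\n")
  lab <- c(true_atrophy_structure = "true atrophy (structure)",
           putative_atrophy_homolog = "putative atrophy (homolog)",
           false_positive = "false positive",
           unknown = "unknown")
  for (v in VERDICT_LEVELS) {
    cells <- sprintf("%4d (%6.2f%%)", x$per_class_counts[v, ],
                     x$per_class_percent[v, ])
    cat(sprintf("%-26s %s\n", lab[[v]], paste(cells, collapse = " ")))
  }
  tot <- sprintf("%4d (100.00%%)", x$class_totals)
  cat(sprintf("%-26s %s\n\n", "total", paste(tot, collapse = " ")))
  cat("failure modes\n")
  for (m in names(x$failure_mode_counts)) {
    cat(sprintf("  %-28s %6d\n", m, x$failure_mode_counts[[m]]))
  }
  cat(sprintf("  %-28s %6d\n\n", "total", sum(x$failure_mode_counts)))
  cat(sprintf("inspected: %d  true: %d  false: %d  unknown: %d",
              x$totals[["inspected"]], x$totals[["true"]],
              x$totals[["false"]], x$totals[["unknown"]]))
  if (x$totals[["unverdicted"]] > 0) {
    cat(sprintf("  (unverdicted candidates: %d)", x$totals[["unverdicted"]]))
  }
  cat("\n")
  cat(sprintf("PPV: %s\n", ifelse(is.na(x$ppv), "not available",
                                  sprintf("%.3f", x$ppv))))
  if (!is.na(x$atrophy_fraction_percent)) {
    cat(sprintf("atrophy fraction: %.2f%% of %s scored domain instances\n",
                x$atrophy_fraction_percent,
                format(x$total_instances, big.mark = ",")))
  }
  invisible(x)
}

#' Write a triage summary
#'
#' Emits a TSV of the per-class table (counts and percentages), plus the
#' failure-mode tally, and optionally a JSON dump of the whole summary.
#'
#' @param x A `triage_summary`.
#' @param path Output TSV path for the class table; the failure-mode tally
#'   goes to `<path>` with suffix `.failure_modes.tsv`, the human-readable
#'   rendering to suffix `.txt`.
#' @param json Optional path for a JSON dump.
#' @return Invisibly, `x`.
#' @export
write_triage_summary <- function(x, path, json = NULL) {
  stopifnot(inherits(x, "triage_summary"))
  tab <- data.frame(verdict = rownames(x$per_class_counts),
                    x$per_class_counts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  fm <- data.frame(failure_mode = names(x$failure_mode_counts),
                   n = as.integer(x$failure_mode_counts))
  utils::write.table(fm, paste0(path, ".failure_modes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  txt <- paste0(path, ".txt")
  con <- file(txt, open = "wt")
  sink(con)
  print(x)
  sink()
  close(con)
  if (!is.null(json)) {
    jsonlite::write_json(unclass(x), json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(x)
}

#' Bundled reference triage tallies
#'
#' The package ships, as plain-text fixtures, the marginal tallies of a
#' proteome-wide manual triage of partial Pfam domain annotations
#' (UniProt 2012_06 against Pfam 27.0): per-class verdict counts and the
#' global failure-mode counts.  `reference_triage_verdicts()` expands those
#' marginals into one verdict row per inspected domain instance, with
#' synthetic call identifiers.  The joint allocation of failure modes to
#' classes is not part of the reference tallies; it is filled in by a
#' deterministic greedy allocation that preserves both marginals exactly,
#' which is all the summary arithmetic consumes.
#'
#' @return A tibble of verdicts with columns `call_id`, `verdict`,
#'   `failure_mode`, `atrophy_class`.
#' @export
reference_triage_verdicts <- function() {
  cls_tab <- utils::read.delim(
    system.file("extdata", "reference_class_triage.tsv",
                package = "atrophyscan"),
    sep = "\t", colClasses = c("character", rep("integer", 4)))
  fm_tab <- utils::read.delim(
    system.file("extdata", "reference_failure_modes.tsv",
                package = "atrophyscan"),
    sep = "\t", colClasses = c("character", "integer"))
  stopifnot(identical(cls_tab$atrophy_class, ATROPHY_CLASSES),
            identical(fm_tab$failure_mode, FAILURE_MODES),
            sum(cls_tab$false_positive) == sum(fm_tab$n))

  rows <- list()
  push <- function(class, verdict, n, failure_mode = NA_character_) {
    if (n == 0) return(invisible(NULL))
    rows[[length(rows) + 1]] <<- tibble::tibble(
      verdict = rep(verdict, n),
      failure_mode = rep(failure_mode, n),
      atrophy_class = rep(class, n))
  }
  # greedy allocation of the failure-mode marginal to class quotas
  fp_quota <- stats::setNames(cls_tab$false_positive, cls_tab$atrophy_class)
  for (k in seq_len(nrow(fm_tab))) {
    left <- fm_tab$n[k]
    for (cl in names(fp_quota)) {
      take <- min(left, fp_quota[[cl]])
      if (take > 0) {
        push(cl, "false_positive", take, fm_tab$failure_mode[k])
        fp_quota[[cl]] <- fp_quota[[cl]] - take
        left <- left - take
      }
      if (left == 0) break
    }
    stopifnot(left == 0)
  }
  for (i in seq_len(nrow(cls_tab))) {
    push(cls_tab$atrophy_class[i], "true_atrophy_structure",
         cls_tab$true_structure[i])
    push(cls_tab$atrophy_class[i], "putative_atrophy_homolog",
         cls_tab$putative_homolog[i])
    push(cls_tab$atrophy_class[i], "unknown", cls_tab$unknown[i])
  }
  out <- do.call(rbind, rows)
  out$call_id <- sprintf("ref:%s:%05d", out$atrophy_class,
                         stats::ave(seq_len(nrow(out)), out$atrophy_class,
                                    FUN = seq_along))
  out[, c("call_id", "verdict", "failure_mode", "atrophy_class")]
}

#' Bundled reference dataset counts
#'
#' Named sizes of the reference screen the bundled triage tallies come
#' from: total sequences, sequences with at least one Pfam-A domain, the
#' protein-existence and fragment filter reductions, and the final count of
#' scored domain instances (the atrophy-fraction denominator).
#'
#' @return A named list of counts.
#' @export
reference_dataset_counts <- function() {
  tab <- utils::read.delim(
    system.file("extdata", "reference_dataset_counts.tsv",
                package = "atrophyscan"),
    sep = "\t", colClasses = c("character", "numeric"))
  stats::setNames(as.list(tab$value), tab$quantity)
}
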