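# Reading and validating domain-hit and protein-metadata tables; writing
# candidate tables.  Two input dialects are supported: HMMER3 per-domain
# tabular output (domtblout, hmmsearch orientation: target = protein,
# query = family model, qlen = model length) and a minimal tab-separated
# "regions" dialect mirroring Pfam full-region flat files.

REGIONS_COLUMNS <- c("protein_acc", "family_acc", "clan_acc",
                     "ali_start", "ali_end", "hmm_start", "hmm_end",
                     "model_length", "evalue")

CANDIDATE_COLUMNS <- c("call_id", "protein_acc", "family_acc",
                       "atrophy_class", "score", "D", "d", "L",
                       "ali_start", "ali_end", "hmm_start", "hmm_end",
                       "ali_start2", "ali_end2", "hmm_start2", "hmm_end2",
                       "filter_flags", "candidate")

abort_validation <- function(msg) {
  stop(structure(class = c("atrophy_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_config <- function(msg) {
  stop(structure(class = c("atrophy_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read a domain-hit table
#'
#' Parses per-protein profile-HMM domain hits from either a tab-separated
#' regions table (header: `protein_acc`, `family_acc`, `clan_acc`,
#' `ali_start`, `ali_end`, `hmm_start`, `hmm_end`, `model_length`, `evalue`;
#' empty `clan_acc`/`evalue` allowed) or HMMER3 `--domtblout` output.
#' Coordinates are 1-based and inclusive for both sequence and model.  Rows
#' violating coordinate invariants (`ali_start <= ali_end`,
#' `hmm_start <= hmm_end <= model_length`, all `>= 1`) are rejected with
#' row-addressed diagnostics.  Hits are returned sorted by protein, then
#' `ali_start`, `ali_end`, `family_acc`.
#'
#' @param path File to read.
#' @param dialect `"regions_tsv"` or `"domtblout"`.
#' @return A tibble of hits with the regions columns; `clan_acc` and
#'   `evalue` are `NA` when absent.
#' @export
read_domain_hits <- function(path, dialect = c("regions_tsv", "domtblout")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_validation(sprintf("hits file not found: %s", path))
  }
  hits <- switch(dialect,
                 regions_tsv = parse_regions_tsv(path),
                 domtblout   = parse_domtblout(path))
  validate_hits(hits, source = path)
  sort_hits(hits)
}

parse_regions_tsv <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = "",
                           check.names = FALSE, quote = "")
  missing_cols <- setdiff(REGIONS_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf("regions table %s lacks column(s): %s",
                             path, paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[REGIONS_COLUMNS]
  n <- nrow(raw)
  to_int <- function(col) {
    v <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(v) | suppressWarnings(as.numeric(raw[[col]])) != v)
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "regions table %s: row %d, field '%s': not a positive integer ('%s')",
        path, bad[1], col, raw[[col]][bad[1]]))
    }
    v
  }
  ev_absent <- is.na(raw$evalue) | raw$evalue == "NA"
  ev <- suppressWarnings(as.numeric(raw$evalue))
  bad_ev <- which(!ev_absent & (is.na(ev) | ev < 0))
  if (length(bad_ev) > 0) {
    abort_validation(sprintf(
      "regions table %s: row %d, field 'evalue': not a non-negative real ('%s')",
      path, bad_ev[1], raw$evalue[bad_ev[1]]))
  }
  ev[ev_absent] <- NA_real_
  tibble::tibble(
    protein_acc = raw$protein_acc,
    family_acc = raw$family_acc,
    clan_acc = ifelse(is.na(raw$clan_acc) | raw$clan_acc == "NA",
                      NA_character_, raw$clan_acc),
    ali_start = to_int("ali_start"),
    ali_end = to_int("ali_end"),
    hmm_start = to_int("hmm_start"),
    hmm_end = to_int("hmm_end"),
    model_length = to_int("model_length"),
    evalue = ev
  )
}

# HMMER3 domtblout, hmmsearch orientation.  Whitespace-separated, 22 fixed
# columns plus free-text description; '#' lines are comments.
parse_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(empty_hits())
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  short <- which(vapply(fields, length, 1L) < 22)
  if (length(short) > 0) {
    abort_validation(sprintf(
      "domtblout %s: row %d has %d fields, expected >= 22",
      path, short[1], length(fields[[short[1]]])))
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "domtblout %s: row %d, field '%s': cannot parse '%s'",
        path, bad[1], what, col(i)[bad[1]]))
    }
    v
  }
  fam_acc <- col(5)
  fam <- ifelse(fam_acc == "-", col(4), fam_acc)
  tibble::tibble(
    protein_acc = col(1),
    family_acc = fam,
    clan_acc = NA_character_,
    ali_start = as.integer(num(18, "ali from")),
    ali_end = as.integer(num(19, "ali to")),
    hmm_start = as.integer(num(16, "hmm from")),
    hmm_end = as.integer(num(17, "hmm to")),
    model_length = as.integer(num(6, "qlen")),
    evalue = num(13, "i-Evalue")
  )
}

empty_hits <- function() {
  tibble::tibble(protein_acc = character(), family_acc = character(),
                 clan_acc = character(), ali_start = integer(),
                 ali_end = integer(), hmm_start = integer(),
                 hmm_end = integer(), model_length = integer(),
                 evalue = double())
}

validate_hits <- function(hits, source = "<hits>") {
  if (nrow(hits) == 0) return(invisible(hits))
  fail <- function(row, field, why) {
    abort_validation(sprintf("%s: row %d, field '%s': %s",
                             source, row, field, why))
  }
  bad <- which(hits$ali_start < 1)
  if (length(bad)) fail(bad[1], "ali_start", "must be >= 1")
  bad <- which(hits$ali_start > hits$ali_end)
  if (length(bad)) {
    fail(bad[1], "ali_start/ali_end",
         sprintf("ordering violated (%d > %d)",
                 hits$ali_start[bad[1]], hits$ali_end[bad[1]]))
  }
  bad <- which(hits$hmm_start < 1)
  if (length(bad)) fail(bad[1], "hmm_start", "must be >= 1")
  bad <- which(hits$hmm_start > hits$hmm_end)
  if (length(bad)) {
    fail(bad[1], "hmm_start/hmm_end",
         sprintf("ordering violated (%d > %d)",
                 hits$hmm_start[bad[1]], hits$hmm_end[bad[1]]))
  }
  bad <- which(hits$hmm_end > hits$model_length)
  if (length(bad)) {
    fail(bad[1], "hmm_end",
         sprintf("exceeds model length (%d > %d)",
                 hits$hmm_end[bad[1]], hits$model_length[bad[1]]))
  }
  bad <- which(!is.na(hits$evalue) & hits$evalue < 0)
  if (length(bad)) fail(bad[1], "evalue", "must be non-negative")
  # one model length per family
  ml <- tapply(hits$model_length, hits$family_acc,
               function(x) length(unique(x)))
  if (any(ml > 1)) {
    abort_validation(sprintf(
      "%s: family %s carries inconsistent model lengths",
      source, names(ml)[which(ml > 1)[1]]))
  }
  invisible(hits)
}

sort_hits <- function(hits) {
  hits[order(hits$protein_acc, hits$ali_start, hits$ali_end,
             hits$family_acc), , drop = FALSE]
}

#' Read a protein metadata table
#'
#' Tab-separated with header `protein_acc`, `seq_length`, `pe_level`,
#' `is_fragment`.  Protein-existence level must be 1-5; duplicate accessions
#' are rejected.
#'
#' @param path File to read.
#' @return A tibble of validated protein records.
#' @export
read_protein_metadata <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("metadata file not found: %s", path))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  need <- c("protein_acc", "seq_length", "pe_level", "is_fragment")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf("metadata table %s lacks column(s): %s",
                             path, paste(missing_cols, collapse = ", ")))
  }
  recs <- tibble::tibble(
    protein_acc = raw$protein_acc,
    seq_length = suppressWarnings(as.integer(raw$seq_length)),
    pe_level = suppressWarnings(as.integer(raw$pe_level)),
    is_fragment = parse_flag(raw$is_fragment)
  )
  validate_proteins(recs, source = path)
}

parse_flag <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  out
}

validate_proteins <- function(recs, source = "<metadata>") {
  bad <- which(is.na(recs$seq_length) | recs$seq_length < 1)
  if (length(bad)) {
    abort_validation(sprintf("%s: row %d: seq_length must be >= 1",
                             source, bad[1]))
  }
  bad <- which(is.na(recs$pe_level) | !(recs$pe_level %in% 1:5))
  if (length(bad)) {
    abort_validation(sprintf(
      "%s: row %d: pe_level must be an integer in 1-5 (got '%s')",
      source, bad[1], recs$pe_level[bad[1]]))
  }
  bad <- which(is.na(recs$is_fragment))
  if (length(bad)) {
    abort_validation(sprintf("%s: row %d: is_fragment must be a boolean",
                             source, bad[1]))
  }
  dup <- recs$protein_acc[duplicated(recs$protein_acc)]
  if (length(dup) > 0) {
    abort_validation(sprintf("%s: duplicate protein accession: %s",
                             source, dup[1]))
  }
  recs
}

#' Write candidate atrophy calls to a TSV file
#'
#' Column order is fixed: `call_id`, `protein_acc`, `family_acc`,
#' `atrophy_class`, `score`, `D`, `d`, `L`, `ali_start`, `ali_end`,
#' `hmm_start`, `hmm_end`, `ali_start2`, `ali_end2`, `hmm_start2`,
#' `hmm_end2`, `filter_flags`, `candidate`.  The second coordinate block is
#' filled only for within-domain calls (the downstream fragment).  Scores
#' are serialized with six decimal places; [read_candidates()] reproduces
#' all fields exactly at that precision.
#'
#' @param calls Call table as produced by [build_calls()] or
#'   [detect_atrophy()].
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_candidates <- function(calls, path) {
  out <- as.data.frame(calls)[, setdiff(CANDIDATE_COLUMNS, "score"),
                              drop = FALSE]
  out$score <- sprintf("%.6f", calls$score)
  out <- out[CANDIDATE_COLUMNS]
  out$filter_flags[is.na(out$filter_flags)] <- ""
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write candidates to %s: %s",
                 path, conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' Read back a candidate table written by [write_candidates()]
#'
#' @param path File to read.
#' @return A tibble with the documented candidate columns.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("candidate file not found: %s", path))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = "NA",
                           quote = "")
  missing_cols <- setdiff(CANDIDATE_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf("candidate table %s lacks column(s): %s",
                             path, paste(missing_cols, collapse = ", ")))
  }
  int_cols <- c("D", "d", "L", "ali_start", "ali_end", "hmm_start",
                "hmm_end", "ali_start2", "ali_end2", "hmm_start2",
                "hmm_end2")
  out <- tibble::as_tibble(raw[CANDIDATE_COLUMNS])
  for (cc in int_cols) out[[cc]] <- as.integer(out[[cc]])
  out$score <- as.numeric(out$score)
  out$candidate <- parse_flag(out$candidate)
  out$filter_flags[is.na(out$filter_flags)] <- ""
  out
}
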