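# Assigning scored boundaries to the five atrophy classes and assembling
# call records.
#
# The five classes, by architecture:
#   n_terminal_end_bounded   loss at the N terminus of the first domain
#   c_terminal_end_bounded   loss at the C terminus of the last domain
#   upstream_domain_bounded  loss at the N-terminal side of an inner or last
#                            domain, facing the upstream neighbour
#   downstream_domain_bounded loss at the C-terminal side of an inner or
#                            first domain, facing the downstream neighbour
#   within_domain            loss between two same-family fragments of one
#                            split domain

ATROPHY_CLASSES <- c("n_terminal_end_bounded", "c_terminal_end_bounded",
                     "upstream_domain_bounded", "downstream_domain_bounded",
                     "within_domain")

#' Map a boundary to its atrophy class
#'
#' @param position Position of the hit among the retained hits of its
#'   protein: `"first"`, `"inner"`, `"last"`, or `"single"` for the only hit
#'   of a single-domain protein (where both termini are end-bounded).
#' @param terminus `"N"` or `"C"`.
#' @return One of the five class labels.
#' @export
classify_boundary <- function(position, terminus) {
  position <- match.arg(position, c("first", "inner", "last", "single"))
  terminus <- match.arg(terminus, c("N", "C"))
  if (terminus == "N") {
    if (position %in% c("first", "single")) "n_terminal_end_bounded"
    else "upstream_domain_bounded"
  } else {
    if (position %in% c("last", "single")) "c_terminal_end_bounded"
    else "downstream_domain_bounded"
  }
}

hit_position <- function(i, n) {
  if (n == 1) "single"
  else if (i == 1) "first"
  else if (i == n) "last"
  else "inner"
}

make_call_id <- function(protein_acc, family_acc, start, end, class) {
  sprintf("%s:%s:%d-%d:%s", protein_acc, family_acc, start, end, class)
}

empty_calls <- function() {
  tibble::tibble(call_id = character(), protein_acc = character(),
                 family_acc = character(), atrophy_class = character(),
                 terminus = character(), D = integer(), d = integer(),
                 L = integer(), score = double(),
                 ali_start = integer(), ali_end = integer(),
                 hmm_start = integer(), hmm_end = integer(),
                 ali_start2 = integer(), ali_end2 = integer(),
                 hmm_start2 = integer(), hmm_end2 = integer(),
                 filter_flags = character(), candidate = logical())
}

add_flag <- function(flags, idx, label) {
  cur <- strsplit(flags[idx], ",", fixed = TRUE)
  flags[idx] <- vapply(cur, function(f) {
    f <- sort(unique(c(f[nzchar(f)], label)))
    paste(f, collapse = ",")
  }, "")
  flags
}

#' Build atrophy calls for a set of proteins
#'
#' For every retained hit, both boundary scores are evaluated: the
#' N-terminal boundary against the nearest retained upstream hit (or the
#' sequence start) and the C-terminal boundary against the nearest retained
#' downstream hit (or the sequence end).  For every pair of consecutive
#' same-family hits whose model coordinates pass the split test
#' ([is_split_pair()]), one within-domain call is added.
#'
#' Architectural flags are attached here, where the pair geometry is at
#' hand:
#' \describe{
#'   \item{tandem}{facing boundaries of a same-family consecutive pair that
#'     re-covers the model (not a split domain).}
#'   \item{split_pair_boundary}{facing boundaries of a split pair; the
#'     missing states there are exactly the within-domain call's `D`, so
#'     scoring them again as domain-bounded atrophy would double-count.}
#'   \item{clan_adjacent}{facing boundaries across a same-clan adjacency
#'     (ambiguous boundary assignment); never applied to the within-domain
#'     call itself.}
#' }
#' Score-level flags (`nested`, `small_domain`, `score_outside_window`) and
#' the candidate decision are attached by [detect_atrophy()] or
#' [apply_call_filters()].
#'
#' @param hits Hit table (regions columns) restricted to retained hits;
#'   overlap resolution must already have been applied.
#' @param proteins Protein metadata covering every accession in `hits`.
#' @return A call tibble (one row per boundary or split-pair evaluation)
#'   with empty score-level flags.
#' @export
build_calls <- function(hits, proteins) {
  hits <- sort_hits(hits)
  unknown <- setdiff(unique(hits$protein_acc), proteins$protein_acc)
  if (length(unknown) > 0) {
    abort_validation(sprintf("hits reference unknown protein accession: %s",
                             unknown[1]))
  }
  seq_len_of <- stats::setNames(proteins$seq_length, proteins$protein_acc)
  bad <- which(hits$ali_end > seq_len_of[hits$protein_acc])
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "hit on %s ends at %d, beyond the sequence length %d",
      hits$protein_acc[bad[1]], hits$ali_end[bad[1]],
      seq_len_of[hits$protein_acc[bad[1]]]))
  }
  per_protein <- split(hits, hits$protein_acc)
  calls <- lapply(per_protein, function(ph) {
    build_calls_one(ph, seq_len_of[[ph$protein_acc[1]]])
  })
  out <- do.call(rbind, c(list(empty_calls()), unname(calls)))
  tibble::as_tibble(out)
}

build_calls_one <- function(ph, seq_length) {
  n <- nrow(ph)
  ph <- adjacency_intervals(ph, seq_length)

  boundary_row <- function(i, terminus) {
    pos <- hit_position(i, n)
    cls <- classify_boundary(pos, terminus)
    D <- if (terminus == "N") unmatched_states_n(ph$hmm_start[i])
         else unmatched_states_c(ph$hmm_end[i], ph$model_length[i])
    d <- if (terminus == "N") ph$d_n[i] else ph$d_c[i]
    L <- ph$model_length[i]
    tibble::tibble(
      call_id = make_call_id(ph$protein_acc[i], ph$family_acc[i],
                             ph$ali_start[i], ph$ali_end[i], cls),
      protein_acc = ph$protein_acc[i], family_acc = ph$family_acc[i],
      atrophy_class = cls, terminus = terminus,
      D = D, d = d, L = L, score = atrophy_score(D, d, L),
      ali_start = ph$ali_start[i], ali_end = ph$ali_end[i],
      hmm_start = ph$hmm_start[i], hmm_end = ph$hmm_end[i],
      ali_start2 = NA_integer_, ali_end2 = NA_integer_,
      hmm_start2 = NA_integer_, hmm_end2 = NA_integer_,
      filter_flags = "", candidate = NA)
  }

  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    rows[[2L * i - 1L]] <- boundary_row(i, "N")
    rows[[2L * i]] <- boundary_row(i, "C")
  }
  calls <- do.call(rbind, rows)
  # row index helpers into `calls`: N call of hit i is 2i-1, C call is 2i
  n_call <- function(i) 2L * i - 1L
  c_call <- function(i) 2L * i

  # consecutive same-family pairs: split -> within call + boundary
  # suppression; non-split -> tandem flag on the facing boundaries
  within <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      if (ph$family_acc[i] != ph$family_acc[i + 1]) next
      up <- ph[i, ]
      dn <- ph[i + 1, ]
      # equal starts: no meaningful upstream/downstream order, treat as
      # ambiguous re-coverage like a tandem pair
      if (dn$ali_start > up$ali_start && is_split_pair(up, dn)) {
        br <- within_pair_score(up, dn)
        within[[length(within) + 1]] <- tibble::tibble(
          call_id = make_call_id(up$protein_acc, up$family_acc,
                                 up$ali_start, dn$ali_end, "within_domain"),
          protein_acc = up$protein_acc, family_acc = up$family_acc,
          atrophy_class = "within_domain", terminus = "W",
          D = br$D, d = br$d, L = br$L, score = br$score,
          ali_start = up$ali_start, ali_end = up$ali_end,
          hmm_start = up$hmm_start, hmm_end = up$hmm_end,
          ali_start2 = dn$ali_start, ali_end2 = dn$ali_end,
          hmm_start2 = dn$hmm_start, hmm_end2 = dn$hmm_end,
          filter_flags = "", candidate = NA)
        calls$filter_flags <- add_flag(calls$filter_flags,
                                       c(c_call(i), n_call(i + 1)),
                                       "split_pair_boundary")
      } else {
        calls$filter_flags <- add_flag(calls$filter_flags,
                                       c(c_call(i), n_call(i + 1)),
                                       "tandem")
      }
    }
  }

  # same-clan adjacency: facing boundaries across the shared interval
  pairs <- filter_clan_adjacency(ph)
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      calls$filter_flags <- add_flag(
        calls$filter_flags,
        c(c_call(pairs[k, "upstream"]), n_call(pairs[k, "downstream"])),
        "clan_adjacent")
    }
  }

  do.call(rbind, c(list(calls), within))
}

#' Attach score-level flags and the candidate decision
#'
#' Applies [flag_nested()], [filter_small_domain()] and
#' [filter_score_window()] to a call table and sets `candidate`: a call is a
#' candidate iff it carries no flag and its score lies in the window.
#'
#' @param calls Call table from [build_calls()].
#' @param config An [atrophy_config()].
#' @return The call table with final `filter_flags` and `candidate`.
#' @export
apply_call_filters <- function(calls, config = atrophy_config()) {
  stopifnot(inherits(config, "atrophy_config"))
  if (nrow(calls) == 0) {
    calls$candidate <- logical(0)
    return(calls)
  }
  nested <- flag_nested(calls$D, calls$d, calls$L)
  small <- filter_small_domain(calls$L, config$min_model_length)
  in_window <- filter_score_window(calls$D, calls$d, calls$L,
                                   config$min_score, config$max_score)
  flags <- calls$filter_flags
  if (any(nested)) flags <- add_flag(flags, which(nested), "nested")
  if (any(small)) flags <- add_flag(flags, which(small), "small_domain")
  outside <- !in_window & !nzchar(flags)
  if (any(outside)) {
    flags <- add_flag(flags, which(outside), "score_outside_window")
  }
  calls$filter_flags <- flags
  calls$candidate <- !nzchar(calls$filter_flags)
  calls
}
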