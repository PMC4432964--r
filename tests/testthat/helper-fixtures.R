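# Shared builders and independent oracles for the test suite.

mk_hit <- function(protein = "P1", family = "FAM1", clan = NA_character_,
                   ali_start = 1L, ali_end = 100L, hmm_start = 1L,
                   hmm_end = 100L, model_length = 100L, evalue = 1e-10) {
  tibble::tibble(protein_acc = protein, family_acc = family,
                 clan_acc = clan, ali_start = as.integer(ali_start),
                 ali_end = as.integer(ali_end),
                 hmm_start = as.integer(hmm_start),
                 hmm_end = as.integer(hmm_end),
                 model_length = as.integer(model_length), evalue = evalue)
}

mk_protein <- function(protein = "P1", seq_length = 1000L, pe_level = 1L,
                       is_fragment = FALSE) {
  tibble::tibble(protein_acc = protein, seq_length = as.integer(seq_length),
                 pe_level = as.integer(pe_level), is_fragment = is_fragment)
}

# Independent boundary-score oracle: reconstructs each retained hit's
# upstream/downstream intervals from residue-by-residue occupancy vectors
# (predecessor and successor hits marked on the sequence), then scores with
# plain arithmetic.  `hits` must be the retained hits of ONE protein.
oracle_boundary_scores <- function(hits, seq_length) {
  hits <- hits[order(hits$ali_start, hits$ali_end, hits$family_acc), ,
               drop = FALSE]
  n <- nrow(hits)
  out <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    occ_before <- rep(FALSE, seq_length)
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        occ_before[hits$ali_start[j]:hits$ali_end[j]] <- TRUE
      }
    }
    upstream_end <- if (any(occ_before)) max(which(occ_before)) else 0L
    occ_after <- rep(FALSE, seq_length)
    if (i < n) {
      for (j in seq.int(i + 1, n)) {
        occ_after[hits$ali_start[j]:hits$ali_end[j]] <- TRUE
      }
    }
    # nearest downstream boundary = leftmost start among successors; with
    # sorted starts that is the first marked residue at/after ali_start[i]
    downstream_start <- if (any(occ_after)) min(which(occ_after))
                        else seq_length + 1L
    L <- hits$model_length[i]
    d_n <- hits$ali_start[i] - upstream_end - 1L
    d_c <- downstream_start - hits$ali_end[i] - 1L
    D_n <- hits$hmm_start[i] - 1L
    D_c <- L - hits$hmm_end[i]
    out[[2L * i - 1L]] <- data.frame(
      protein_acc = hits$protein_acc[i], ali_start = hits$ali_start[i],
      ali_end = hits$ali_end[i], family_acc = hits$family_acc[i],
      terminus = "N", D = D_n, d = d_n, L = L, score = (D_n - d_n) / L)
    out[[2L * i]] <- data.frame(
      protein_acc = hits$protein_acc[i], ali_start = hits$ali_start[i],
      ali_end = hits$ali_end[i], family_acc = hits$family_acc[i],
      terminus = "C", D = D_c, d = d_c, L = L, score = (D_c - d_c) / L)
  }
  do.call(rbind, out)
}

# Brute-force overlap-resolution oracle: enumerates every subset of <= 6
# hits, keeps those with no partial different-family overlap beyond the
# margin, and returns the subset that is lexicographically maximal in
# E-value rank order (rank 1 included if feasible, then rank 2, ...).
oracle_overlap_selection <- function(hits, margin = 0L) {
  n <- nrow(hits)
  stopifnot(n <= 6)
  ev <- ifelse(is.na(hits$evalue), Inf, hits$evalue)
  span <- hits$ali_end - hits$ali_start
  rank_of <- order(ev, -span, hits$family_acc)  # rank_of[k] = index of rank k
  conflicts <- function(i, j) {
    if (hits$family_acc[i] == hits$family_acc[j]) return(FALSE)
    s1 <- hits$ali_start[i]; e1 <- hits$ali_end[i]
    s2 <- hits$ali_start[j]; e2 <- hits$ali_end[j]
    ov <- min(e1, e2) - max(s1, s2) + 1L
    contained <- (s1 <= s2 && e1 >= e2) || (s2 <= s1 && e2 >= e1)
    ov > margin && !contained
  }
  feasible <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    for (a in seq_len(length(idx) - 1)) {
      for (b in seq.int(a + 1, length(idx))) {
        if (conflicts(idx[a], idx[b])) return(FALSE)
      }
    }
    TRUE
  }
  best <- integer(0)
  best_key <- -1
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!feasible(idx)) next
    # key: binary string over ranks, high rank-1 bit first
    key <- sum(2^(n - match(idx, rank_of)))
    if (key > best_key) {
      best_key <- key
      best <- idx
    }
  }
  sort(best)
}

# Random small protein for property tests: up to `max_hits` hits over a few
# families so same-family pairs and overlaps occur.
random_protein <- function(acc, max_hits = 6) {
  n <- sample(1:max_hits, 1)
  fams <- sprintf("RF%d", sample(1:3, n, replace = TRUE))
  Ls <- c(RF1 = 80L, RF2 = 150L, RF3 = 300L)
  rows <- lapply(seq_len(n), function(k) {
    L <- Ls[[fams[k]]]
    as_ <- sample(1:400, 1)
    ae <- as_ + sample(10:120, 1)
    hs <- sample(1:(L - 5), 1)
    he <- sample(hs:L, 1)
    ev <- if (stats::runif(1) < 0.1) NA_real_ else 10^-stats::runif(1, 2, 40)
    mk_hit(acc, fams[k], ali_start = as_, ali_end = ae, hmm_start = hs,
           hmm_end = he, model_length = L, evalue = ev)
  })
  hits <- do.call(rbind, rows)
  list(hits = hits,
       protein = mk_protein(acc, seq_length = max(hits$ali_end) +
                              sample(0:50, 1)))
}
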