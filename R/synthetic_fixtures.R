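# Synthetic annotated proteomes with planted ground truth.
#
# Each plant is one protein carrying a hand-constructed domain architecture:
# one of the five atrophy classes with a chosen target score, or one of the
# failure modes the filter cascade must exclude (tandem repeat, nested
# domain, partial overlap, sequence fragment, low protein-existence level,
# same-clan adjacency, small model).  No residues are generated — the
# pipeline consumes coordinate tables only.  Coordinates are built so that
# each plant's intended event is the protein's only above-threshold signal;
# all other boundaries of the plant are complete (score <= 0).

PLANT_KINDS <- c("complete_domain", "n_terminal_atrophy", "c_terminal_atrophy",
                 "upstream_bounded_atrophy", "downstream_bounded_atrophy",
                 "within_atrophy", "tandem_repeat", "nested_domain",
                 "overlap", "fragment_protein", "low_pe_protein",
                 "clan_adjacent_pair", "small_domain")

ATROPHY_KINDS <- c("n_terminal_atrophy", "c_terminal_atrophy",
                   "upstream_bounded_atrophy", "downstream_bounded_atrophy",
                   "within_atrophy")

KIND_CLASS <- c(n_terminal_atrophy = "n_terminal_end_bounded",
                c_terminal_atrophy = "c_terminal_end_bounded",
                upstream_bounded_atrophy = "upstream_domain_bounded",
                downstream_bounded_atrophy = "downstream_domain_bounded",
                within_atrophy = "within_domain")

#' Specify one plant for the synthetic proteome generator
#'
#' @param kind One of the plant kinds: the five atrophy classes
#'   (`n_terminal_atrophy`, `c_terminal_atrophy`, `upstream_bounded_atrophy`,
#'   `downstream_bounded_atrophy`, `within_atrophy`), a clean
#'   `complete_domain`, or a failure mode (`tandem_repeat`, `nested_domain`,
#'   `overlap`, `fragment_protein`, `low_pe_protein`, `clan_adjacent_pair`,
#'   `small_domain`).
#' @param target_score For atrophy kinds, the intended score in (0, 1);
#'   realised as `round(target * L)/L`, i.e. within `1/L` of the target.
#'   `NA` draws one uniformly from \\[0.05, 0.95\\] at generation time.
#' @param model_length Match states of the planted family; `NA` draws
#'   uniformly from \\[50, 600\\] (typical Pfam model sizes), except where the
#'   kind constrains it.
#' @return A one-row tibble.
#' @export
plant_spec <- function(kind, target_score = NA_real_,
                       model_length = NA_integer_) {
  kind <- match.arg(kind, PLANT_KINDS)
  tibble::tibble(kind = kind,
                 target_score = as.numeric(target_score),
                 model_length = as.integer(model_length))
}

#' Default synthetic scenario
#'
#' 220 plants: 24 of each of the five atrophy classes (for each class, one
#' plant at exactly the 0.15 candidate boundary on a length-200 model, one
#' below the window at 0.10, and 22 with random targets in \\[0.05, 0.95\\])
#' plus 20 complete domains and 11-12 of every failure mode, so that every
#' filter and class branch is exercised.
#'
#' @return A tibble of plant specs.
#' @export
default_scenario <- function() {
  specs <- list()
  for (kind in ATROPHY_KINDS) {
    specs[[length(specs) + 1]] <- plant_spec(kind, 0.15, 200L)
    specs[[length(specs) + 1]] <- plant_spec(kind, 0.10, 200L)
    for (j in seq_len(22)) specs[[length(specs) + 1]] <- plant_spec(kind)
  }
  for (j in seq_len(20)) {
    specs[[length(specs) + 1]] <- plant_spec("complete_domain")
  }
  failure_kinds <- c(tandem_repeat = 12L, nested_domain = 12L, overlap = 12L,
                     fragment_protein = 11L, low_pe_protein = 11L,
                     clan_adjacent_pair = 11L, small_domain = 11L)
  for (kind in names(failure_kinds)) {
    for (j in seq_len(failure_kinds[[kind]])) {
      specs[[length(specs) + 1]] <- plant_spec(kind)
    }
  }
  do.call(rbind, specs)
}

#' Generate a synthetic annotated proteome with planted ground truth
#'
#' Emits a hit table (regions dialect), protein metadata and a truth table
#' mapping each plant to its expected class, expected exact score
#' (`expected_D`, `expected_d`, `expected_L` and their ratio), whether it
#' must survive the default filter cascade (`expected_candidate`), and the
#' filter expected to remove it otherwise (`expected_exclusion`).  One
#' protein is generated per plant.  Deterministic given `seed`.
#'
#' @param specs Plant specs, as from [plant_spec()] / [default_scenario()].
#' @param seed Integer seed fixing all randomness.
#' @return A list with tibbles `hits`, `proteins`, `truth`.
#' @export
generate_proteome <- function(specs, seed) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1,
            all(specs$kind %in% PLANT_KINDS))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  hits <- list(); proteins <- list(); truth <- list()
  for (i in seq_len(nrow(specs))) {
    plant <- build_plant(i, specs$kind[i], specs$target_score[i],
                         specs$model_length[i])
    hits[[i]] <- plant$hits
    proteins[[i]] <- plant$protein
    truth[[i]] <- plant$truth
  }
  list(hits = sort_hits(tibble::as_tibble(do.call(rbind, hits))),
       proteins = tibble::as_tibble(do.call(rbind, proteins)),
       truth = tibble::as_tibble(do.call(rbind, truth)))
}

ri <- function(a, b) if (a >= b) as.integer(a) else
  as.integer(sample(seq.int(a, b), 1))

rand_evalue <- function(lo = 6, hi = 40) 10^-stats::runif(1, lo, hi)

plant_infeasible <- function(i, kind, msg) {
  stop(sprintf("generation error: plant %d (%s): %s", i, kind, msg),
       call. = FALSE)
}

# Realise the target score as an integer count of missing match states.
missing_states <- function(i, kind, target, L) {
  if (is.na(target)) target <- stats::runif(1, 0.05, 0.95)
  if (target < 0 || target > 1.5) {
    plant_infeasible(i, kind, sprintf("target score %.3f outside [0, 1.5]",
                                      target))
  }
  D <- as.integer(round(target * L))
  if (D < 1 || D > L - 1) {
    plant_infeasible(i, kind, sprintf(
      "target score %.3f unreachable for model length %d", target, L))
  }
  D
}

hit_row <- function(acc, fam, clan, as_, ae, hs, he, L, ev) {
  tibble::tibble(protein_acc = acc, family_acc = fam,
                 clan_acc = clan, ali_start = as.integer(as_),
                 ali_end = as.integer(ae), hmm_start = as.integer(hs),
                 hmm_end = as.integer(he), model_length = as.integer(L),
                 evalue = ev)
}

protein_row <- function(acc, seq_length, pe_level = 1L,
                        is_fragment = FALSE) {
  tibble::tibble(protein_acc = acc, seq_length = as.integer(seq_length),
                 pe_level = as.integer(pe_level), is_fragment = is_fragment)
}

truth_row <- function(i, kind, acc, fam, class = NA_character_,
                      D = NA_integer_, d = NA_integer_, L = NA_integer_,
                      candidate = FALSE, exclusion = NA_character_) {
  tibble::tibble(plant_id = sprintf("PL%04d", i), kind = kind,
                 protein_acc = acc, family_acc = fam,
                 expected_class = class,
                 expected_D = as.integer(D), expected_d = as.integer(d),
                 expected_L = as.integer(L),
                 expected_score = ifelse(is.na(D), NA_real_,
                                         (as.numeric(D) - as.numeric(d)) /
                                           as.numeric(L)),
                 expected_candidate = candidate,
                 expected_exclusion = exclusion)
}

build_plant <- function(i, kind, target, L) {
  acc <- sprintf("SYN%05d", i)
  fam <- sprintf("FAM%05d", i)
  nbr <- sprintf("NBR%05d", i)
  if (is.na(L)) {
    L <- switch(kind,
                small_domain = ri(15, 29),
                nested_domain = ri(120, 400),
                overlap = ri(100, 400),
                tandem_repeat = ri(50, 600),
                ri(50, 600))
  }
  L <- as.integer(L)
  ev <- rand_evalue()

  atrophy_truth <- function(D, d = 0L) {
    cand <- filter_score_window(D, d, L)
    truth_row(i, kind, acc, fam, class = KIND_CLASS[[kind]],
              D = D, d = d, L = L, candidate = cand,
              exclusion = if (cand) NA_character_ else "score_window")
  }

  switch(kind,
    complete_domain = {
      nl <- ri(0, 40); cl <- ri(0, 40)
      list(hits = hit_row(acc, fam, NA, nl + 1, nl + L, 1, L, L, ev),
           protein = protein_row(acc, nl + L + cl),
           truth = truth_row(i, kind, acc, fam, exclusion = "score_window"))
    },
    n_terminal_atrophy = {
      D <- missing_states(i, kind, target, L)
      matched <- L - D
      cl <- ri(5, 40)
      list(hits = hit_row(acc, fam, NA, 1, matched, D + 1, L, L, ev),
           protein = protein_row(acc, matched + cl),
           truth = atrophy_truth(D))
    },
    c_terminal_atrophy = {
      D <- missing_states(i, kind, target, L)
      matched <- L - D
      nl <- ri(5, 40)
      list(hits = hit_row(acc, fam, NA, nl + 1, nl + matched, 1, L - D, L, ev),
           protein = protein_row(acc, nl + matched),
           truth = atrophy_truth(D))
    },
    upstream_bounded_atrophy = {
      D <- missing_states(i, kind, target, L)
      matched <- L - D
      L2 <- ri(50, 300); g <- ri(0, 30); cl <- ri(5, 40)
      h1 <- hit_row(acc, nbr, NA, g + 1, g + L2, 1, L2, L2, rand_evalue())
      h2 <- hit_row(acc, fam, NA, g + L2 + 1, g + L2 + matched,
                    D + 1, L, L, ev)
      list(hits = rbind(h1, h2),
           protein = protein_row(acc, g + L2 + matched + cl),
           truth = atrophy_truth(D))
    },
    downstream_bounded_atrophy = {
      D <- missing_states(i, kind, target, L)
      matched <- L - D
      L2 <- ri(50, 300); nl <- ri(5, 40); cl <- ri(5, 40)
      h1 <- hit_row(acc, fam, NA, nl + 1, nl + matched, 1, L - D, L, ev)
      h2 <- hit_row(acc, nbr, NA, nl + matched + 1, nl + matched + L2,
                    1, L2, L2, rand_evalue())
      list(hits = rbind(h1, h2),
           protein = protein_row(acc, nl + matched + L2 + cl),
           truth = atrophy_truth(D))
    },
    within_atrophy = {
      D <- missing_states(i, kind, target, L)
      if (L - D < 2) {
        plant_infeasible(i, kind, sprintf(
          "model length %d leaves no room for two fragments around %d missing states",
          L, D))
      }
      h1e <- max(1L, as.integer(floor((L - D) / 2)))
      matched2 <- L - h1e - D
      h1 <- hit_row(acc, fam, NA, 1, h1e, 1, h1e, L, ev)
      h2 <- hit_row(acc, fam, NA, h1e + 1, h1e + matched2,
                    h1e + D + 1, L, L, rand_evalue())
      list(hits = rbind(h1, h2),
           protein = protein_row(acc, h1e + matched2),
           truth = atrophy_truth(D))
    },
    tandem_repeat = {
      e1 <- as.integer(round(0.75 * L)); s2 <- as.integer(round(0.5 * L))
      nl <- ri(0, 30); cl <- ri(5, 40)
      m2 <- L - s2 + 1L
      h1 <- hit_row(acc, fam, NA, nl + 1, nl + e1, 1, e1, L, ev)
      h2 <- hit_row(acc, fam, NA, nl + e1 + 1, nl + e1 + m2, s2, L, L,
                    rand_evalue())
      list(hits = rbind(h1, h2),
           protein = protein_row(acc, nl + e1 + m2 + cl),
           truth = truth_row(i, kind, acc, fam, exclusion = "tandem"))
    },
    nested_domain = {
      Dc <- max(1L, as.integer(round(0.3 * L)))
      M <- L - Dc
      L2 <- ri(30, min(60L, M - 10L))
      b1 <- ri(2, M - L2 - 1)
      host <- hit_row(acc, fam, NA, 1, M, 1, L - Dc, L, ev)
      guest <- hit_row(acc, nbr, NA, b1, b1 + L2 - 1, 1, L2, L2,
                       rand_evalue())
      list(hits = rbind(host, guest),
           protein = protein_row(acc, M + ri(5, 40)),
           truth = truth_row(i, kind, acc, fam, exclusion = "nested"))
    },
    overlap = {
      D <- max(1L, as.integer(round(0.4 * L)))
      matched <- L - D
      L1 <- ri(100, 300); g <- ri(0, 30); ov <- ri(5, 30)
      h1 <- hit_row(acc, nbr, NA, g + 1, g + L1, 1, L1, L1,
                    rand_evalue(30, 40))
      as2 <- g + L1 - ov + 1L
      h2 <- hit_row(acc, fam, NA, as2, as2 + matched - 1L, D + 1, L, L,
                    rand_evalue(3, 8))
      list(hits = rbind(h1, h2),
           protein = protein_row(acc, as2 + matched - 1L + ri(5, 40)),
           truth = truth_row(i, kind, acc, fam, exclusion = "overlap"))
    },
    fragment_protein = {
      D <- missing_states(i, kind, if (is.na(target)) 0.4 else target, L)
      matched <- L - D
      list(hits = hit_row(acc, fam, NA, 1, matched, D + 1, L, L, ev),
           protein = protein_row(acc, matched + ri(5, 40),
                                 is_fragment = TRUE),
           truth = truth_row(i, kind, acc, fam, exclusion = "fragment"))
    },
    low_pe_protein = {
      D <- missing_states(i, kind, if (is.na(target)) 0.4 else target, L)
      matched <- L - D
      list(hits = hit_row(acc, fam, NA, 1, matched, D + 1, L, L, ev),
           protein = protein_row(acc, matched + ri(5, 40),
                                 pe_level = ri(2, 5)),
           truth = truth_row(i, kind, acc, fam, exclusion = "pe_level"))
    },
    clan_adjacent_pair = {
      clan <- sprintf("CLN%04d", i)
      D <- missing_states(i, kind, if (is.na(target)) 0.4 else target, L)
      matched <- L - D
      L2 <- ri(50, 300); g <- ri(0, 30); cl <- ri(5, 40)
      h1 <- hit_row(acc, nbr, clan, g + 1, g + L2, 1, L2, L2, rand_evalue())
      h2 <- hit_row(acc, fam, clan, g + L2 + 1, g + L2 + matched,
                    D + 1, L, L, ev)
      list(hits = rbind(h1, h2),
           protein = protein_row(acc, g + L2 + matched + cl),
           truth = truth_row(i, kind, acc, fam,
                             exclusion = "clan_adjacent"))
    },
    small_domain = {
      D <- max(3L, as.integer(round(0.4 * L)))
      matched <- L - D
      list(hits = hit_row(acc, fam, NA, 1, matched, D + 1, L, L, ev),
           protein = protein_row(acc, matched + ri(5, 30)),
           truth = truth_row(i, kind, acc, fam, exclusion = "small_domain"))
    }
  )
}

#' Write a generated proteome to a directory
#'
#' Writes `hits.tsv` (regions dialect), `metadata.tsv` and `truth.tsv`.
#' Scores in the truth table are serialized with six decimal places; the
#' exact rational is recoverable from `expected_D`, `expected_d`,
#' `expected_L`.
#'
#' @param proteome List from [generate_proteome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_proteome <- function(proteome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hp <- file.path(dir, "hits.tsv")
  mp <- file.path(dir, "metadata.tsv")
  tp <- file.path(dir, "truth.tsv")
  hits <- as.data.frame(proteome$hits)
  hits$evalue <- ifelse(is.na(hits$evalue), "NA",
                        sprintf("%.6e", hits$evalue))
  utils::write.table(hits, hp, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(as.data.frame(proteome$proteins), mp, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  truth <- as.data.frame(proteome$truth)
  truth$expected_score <- ifelse(is.na(truth$expected_score), "NA",
                                 sprintf("%.6f", truth$expected_score))
  utils::write.table(truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(hits = hp, metadata = mp, truth = tp))
}
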