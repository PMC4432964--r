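# The filter cascade: sequence-level filters, overlap resolution, call
# flags, and the exact score window.

test_that("only PE-1, non-fragment proteins are retained", {
  proteins <- rbind(mk_protein("KEEP", pe_level = 1, is_fragment = FALSE),
                    mk_protein("FRAG", pe_level = 1, is_fragment = TRUE),
                    mk_protein("PE2", pe_level = 2, is_fragment = FALSE),
                    mk_protein("PE5", pe_level = 5, is_fragment = FALSE))
  expect_identical(filter_protein_level(proteins), "KEEP")
  expect_setequal(filter_protein_level(proteins, pe_allowed = 1:2),
                  c("KEEP", "PE2"))
})

test_that("same-clan adjacency flags both facing boundaries, clanless hits never fire", {
  same_clan <- rbind(
    mk_hit(family = "A", clan = "CL0123", ali_start = 1, ali_end = 100),
    mk_hit(family = "B", clan = "CL0123", ali_start = 150, ali_end = 250,
           hmm_start = 41, model_length = 100))
  pairs <- filter_clan_adjacency(same_clan)
  expect_identical(nrow(pairs), 1L)

  diff_clan <- same_clan
  diff_clan$clan_acc <- c("CL0123", "CL0999")
  expect_identical(nrow(filter_clan_adjacency(diff_clan)), 0L)

  no_clan <- same_clan
  no_clan$clan_acc <- c("CL0123", NA)
  expect_identical(nrow(filter_clan_adjacency(no_clan)), 0L)

  # through the pipeline: the facing calls are flagged, outer calls are not
  calls <- build_calls(same_clan, mk_protein(seq_length = 300))
  facing <- calls[(calls$ali_start == 1 & calls$terminus == "C") |
                    (calls$ali_start == 150 & calls$terminus == "N"), ]
  expect_true(all(grepl("clan_adjacent", facing$filter_flags)))
  outer <- calls[(calls$ali_start == 1 & calls$terminus == "N") |
                   (calls$ali_start == 150 & calls$terminus == "C"), ]
  expect_false(any(grepl("clan_adjacent", outer$filter_flags)))
})

test_that("nested geometry is flagged via negative intervals or scores above 1", {
  expect_true(flag_nested(D = 10, d = -21, L = 100))
  expect_true(flag_nested(D = 80, d = -21, L = 90))   # score 101/90 > 1
  expect_false(flag_nested(D = 40, d = 0, L = 100))   # score 0.4
  expect_false(flag_nested(D = 100, d = 0, L = 100))  # score exactly 1
})

test_that("the candidate window holds the 0.15 boundary exactly", {
  # 20 * (D - d) == 3 * L: exactly on the default lower bound
  expect_true(filter_score_window(D = 30, d = 0, L = 200))
  expect_true(filter_score_window(D = 33, d = 3, L = 200))
  expect_false(filter_score_window(D = 149, d = 0, L = 1000))  # 0.149
  expect_false(filter_score_window(D = 29, d = 0, L = 200))
  expect_true(filter_score_window(D = 200, d = 0, L = 200))    # exactly 1
  expect_false(filter_score_window(D = 90, d = -12, L = 100))  # 1.02
  expect_error(filter_score_window(30, 0, 200, min_score = 0.5,
                                   max_score = 0.2),
               class = "atrophy_config_error")
  # exactness over a sweep of model lengths at the rational boundary
  for (L in seq(20L, 600L, by = 20L)) {
    expect_true(filter_score_window(D = 3L * L / 20L, d = 0, L = L))
    expect_false(filter_score_window(D = 3L * L / 20L - 1L, d = 0, L = L))
  }
})

test_that("small family models are flagged below 30 match states", {
  expect_true(filter_small_domain(25))
  expect_false(filter_small_domain(30))  # boundary: "less than 30"
  expect_false(filter_small_domain(300))
})

test_that("partial different-family overlaps resolve by E-value", {
  hits <- atrophyscan:::sort_hits(rbind(
    mk_hit(family = "A", ali_start = 10, ali_end = 100, evalue = 1e-30),
    mk_hit(family = "B", ali_start = 90, ali_end = 180, evalue = 1e-5,
           model_length = 100)))
  res <- resolve_overlaps(hits)
  expect_identical(res$overlap_flagged, c(FALSE, TRUE))

  abutting <- atrophyscan:::sort_hits(rbind(
    mk_hit(family = "A", ali_start = 10, ali_end = 100),
    mk_hit(family = "B", ali_start = 101, ali_end = 180)))
  expect_false(any(resolve_overlaps(abutting)$overlap_flagged))

  # containment is nesting, not overlap
  nested <- atrophyscan:::sort_hits(rbind(
    mk_hit(family = "A", ali_start = 10, ali_end = 500, evalue = 1e-5),
    mk_hit(family = "B", ali_start = 200, ali_end = 300, evalue = 1e-30)))
  expect_false(any(resolve_overlaps(nested)$overlap_flagged))

  # same-family overlaps are left to split/tandem logic
  samefam <- atrophyscan:::sort_hits(rbind(
    mk_hit(family = "A", ali_start = 10, ali_end = 100, evalue = 1e-30),
    mk_hit(family = "A", ali_start = 90, ali_end = 180, evalue = 1e-5)))
  expect_false(any(resolve_overlaps(samefam)$overlap_flagged))
})

test_that("greedy overlap resolution matches the brute-force rank oracle", {
  set.seed(31)
  for (rep in 1:150) {
    p <- random_protein(sprintf("OV%03d", rep))
    hits <- atrophyscan:::sort_hits(p$hits)
    res <- resolve_overlaps(hits)
    expect_identical(which(!res$overlap_flagged),
                     oracle_overlap_selection(hits))
  }
})

test_that("protein-level and call-level filters commute", {
  pr <- generate_proteome(default_scenario(), seed = 17)
  cfg <- atrophy_config()
  # filter proteins first, then score
  keep <- filter_protein_level(pr$proteins, cfg$pe_allowed)
  pre <- detect_atrophy(pr$hits[pr$hits$protein_acc %in% keep, ],
                        pr$proteins[pr$proteins$protein_acc %in% keep, ],
                        cfg)
  # score everything, protein filter applied inside
  post <- detect_atrophy(pr$hits, pr$proteins, cfg)
  expect_identical(pre$candidates$call_id, post$candidates$call_id)
  expect_equal(as.data.frame(pre$candidates), as.data.frame(post$candidates))
})

test_that("tandem pairs are excluded while split pairs score within-domain", {
  tandem <- atrophyscan:::sort_hits(rbind(
    mk_hit(family = "A", ali_start = 1, ali_end = 150, hmm_start = 1,
           hmm_end = 150, model_length = 200),
    mk_hit(family = "A", ali_start = 151, ali_end = 251, hmm_start = 100,
           hmm_end = 200, model_length = 200)))
  calls <- apply_call_filters(build_calls(tandem, mk_protein(seq_length = 300)))
  expect_false(any(calls$candidate))
  expect_true(any(grepl("tandem", calls$filter_flags)))
  expect_false(any(calls$atrophy_class == "within_domain"))

  split <- atrophyscan:::sort_hits(rbind(
    mk_hit(family = "A", ali_start = 1, ali_end = 80, hmm_start = 1,
           hmm_end = 80, model_length = 200),
    mk_hit(family = "A", ali_start = 81, ali_end = 150, hmm_start = 131,
           hmm_end = 200, model_length = 200)))
  calls <- apply_call_filters(build_calls(split, mk_protein(seq_length = 150)))
  w <- calls[calls$atrophy_class == "within_domain", ]
  expect_identical(nrow(w), 1L)
  expect_equal(w$score, 0.25)
  expect_true(w$candidate)
  # the facing boundaries are suppressed, not double-counted
  expect_identical(sum(calls$candidate), 1L)
})
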