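# atrophyscan

Detection of **domain atrophy** — the loss of a significant number of core
secondary-structure elements from a protein domain — in profile-HMM domain
annotations.

Most partial matches of a Pfam-style profile HMM are artefacts: sequence
fragments, gene-prediction errors, tandem repeats annotated in pieces,
nested domains, overlapping hits. A small remainder are real: domains that
lost a large part of their structural core and still fold and function.
`atrophyscan` is for annotation curators and protein-evolution researchers
who want to screen an annotated proteome for those rare events and to keep
honest books over the manual triage that must follow.

## The score

For every domain hit, at each boundary,

```
AS = (D - d) / L
```

where `L` is the family model length in match states, `D` the unmatched
match states at that boundary (`hmm_start - 1` at the N terminus,
`L - hmm_end` at the C terminus), and `d` the inter-domain interval — the
residues between the hit and its nearest retained neighbour or the sequence
terminus, credited against the missing region. `AS = 0.33` means roughly one
third of the domain is missing; `AS <= 0` is a complete boundary; `AS > 1`
arises only from negative intervals and signals a nested domain. For a
domain split into two same-family fragments whose model coordinates leave an
internal gap (`hmm_start₂ > hmm_end₁`), the same score is computed across
the gap (within-domain atrophy); re-covered model coordinates mean a tandem
repeat instead.

Candidates are positive boundaries with `0.15 <= AS <= 1` that survive the
filter cascade: protein-existence level 1 only, no fragments, overlap
resolution by E-value, same-clan-adjacency exclusion, nested-geometry
exclusion (`d < 0` or `AS > 1`), and models of at least 30 match states.
Threshold comparisons are exact on the rational `(D - d)/L`. Each candidate
is classified by architecture into one of five classes: N-/C-terminal
end-bounded, upstream/downstream domain-bounded, or within-domain.

## Worked example

Generate a synthetic proteome with 220 planted events and failure modes,
run the cascade, and check the planted truth:

```r
library(atrophyscan)
pr  <- generate_proteome(default_scenario(), seed = 42)
res <- detect_atrophy(pr$hits, pr$proteins)
res
#> domain atrophy screen
#>   protein_existence_fragment        220 -> 198
#>   hits_on_retained_proteins         339 -> 317
#>   overlap_resolution                317 -> 305
#>   scored_evaluations                305 -> 634
#>   candidate_window                  634 -> 104
#> candidates: 104 (score window [0.15, 1])
#>   n_terminal_end_bounded       18
#>   c_terminal_end_bounded       22
#>   upstream_domain_bounded      21
#>   downstream_domain_bounded    22
#>   within_domain                21
```

The stage log mirrors the screen's bookkeeping: 22 proteins fall to the
existence/fragment filter, 12 hits to overlap resolution, and 634 scored
boundary/split evaluations reduce to 104 candidates — exactly the planted
clean events with target scores in the window, each recovered with its exact
class and score:

```r
expected <- pr$truth[pr$truth$expected_candidate, ]
m <- merge(expected, res$candidates,
           by.x = c("protein_acc", "expected_class"),
           by.y = c("protein_acc", "atrophy_class"))
nrow(m) == nrow(expected) && all(m$score == m$expected_score)
#> [1] TRUE
```

The report stage tallies manual verdicts. With the bundled reference tallies
of a proteome-wide screen (UniProt 2012_06 × Pfam 27.0):

```r
s <- triage_summary(reference_triage_verdicts(),
                    total_instances =
                      reference_dataset_counts()$domain_instances_scored)
s$totals
#>   inspected        true       false     unknown unverdicted
#>        1636          75        1287         274           0
s$ppv
#> [1] 0.055
s$atrophy_fraction_percent   # truncated, not rounded
#> [1] 0.06
```

75 of 1,636 inspected candidates were confirmed or putative atrophy (PPV
0.055); against all 114,303 scored domain instances that is 0.06% — atrophy
is rare.

## Command line

```sh
atrophyscan simulate --out fixtures/ --seed 1
atrophyscan score  --hits fixtures/hits.tsv --metadata fixtures/metadata.tsv \
                   --out calls.tsv [--min-score 0.15] [--config cfg.yaml]
atrophyscan report --candidates calls.tsv --verdicts verdicts.tsv --out summary.tsv
```

(installed under the package's `exec/` directory). Exit codes: 0 success,
2 input/validation error, 3 configuration error. Input dialects: a tabular
regions TSV (`protein_acc, family_acc, clan_acc, ali_start, ali_end,
hmm_start, hmm_end, model_length, evalue`) or HMMER3 `--domtblout` output
(hmmsearch orientation).

## Documentation

The methods vignette (`vignettes/domain-atrophy-detection.Rmd`) describes
the score, the adjacency and nesting geometry, every filter with its default
and rationale, the synthetic generator's scope and blind spots, and known
limitations.
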