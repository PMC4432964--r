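---
title: "Detecting domain atrophy from profile-HMM annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting domain atrophy from profile-HMM annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrophyscan)
```

## The problem

Protein domains routinely gain or lose peripheral secondary-structure
elements, but occasionally a domain loses a *large* part of its structural
core and still folds and functions — domain atrophy. In sequence data such
events show up as partial matches of a family's profile HMM: only a
contiguous block of the model's match states aligns, and the unmatched block
abuts either a protein terminus or a neighbouring domain, leaving no room on
the sequence for the missing region to hide.

Partial HMM matches are, however, dominated by artefacts: sequence
fragments, gene-prediction errors, tandem repeats annotated in pieces,
domains nested inside other domains, families whose models really cover two
structural domains, and so on. `atrophyscan` implements the scoring,
classification and filtering machinery to separate plausible atrophy
candidates from these mechanical failure modes, and the bookkeeping to
summarise a subsequent manual triage.

## The atrophy score

Every hit carries four coordinates: matched model states
`hmm_start..hmm_end` out of a model of length $L$, and aligned residues
`ali_start..ali_end` on the protein. At each boundary of the hit we compute

$$\mathrm{AS} = \frac{D - d}{L}$$

where $D$ is the number of unmatched match states at that boundary
($D_N = \mathrm{hmm\_start} - 1$ at the N terminus,
$D_C = L - \mathrm{hmm\_end}$ at the C terminus) and $d$ is the
inter-domain interval: the residues between the hit's alignment boundary and
the nearest retained neighbouring hit, or the sequence terminus. The
interval is *credited* against the missing states — residues sitting next to
the partial match could in principle contain the unmatched region, they just
failed to align. A score of 0.33 therefore means about one third of the
domain is genuinely missing; zero or negative scores mean a complete
boundary.

When one domain of a family is reported as two fragments, the same score is
computed across the internal gap: $D_W$ is the run of model states between
`hmm_end` of the upstream fragment and `hmm_start` of the downstream one,
and $d_W$ the sequence linker between the fragments. The pair qualifies only
if the downstream fragment *resumes* the model
(`hmm_start2 > hmm_end1`, strictly); if the model states are re-covered the
pair is a tandem repeat, not a split domain. A shared boundary match state
counts as re-coverage — the rule is strict because one shared state already
means the two hits describe the same model position twice.

## The five classes

A positive boundary score is classified by architecture:

| class | where the loss sits |
|---|---|
| `n_terminal_end_bounded` | N-terminal region of the first domain |
| `c_terminal_end_bounded` | C-terminal region of the last domain |
| `upstream_domain_bounded` | N-terminal region of an inner (or last) domain |
| `downstream_domain_bounded` | C-terminal region of an inner (or first) domain |
| `within_domain` | between two fragments of one split domain |

For a single-domain protein both termini are end-bounded. End-bounded and
domain-bounded events matter because the bounding feature is what prevents
the "missing" region from simply being an unaligned extension.

## Adjacency, overlaps and nesting

The interval $d$ needs a definition of "adjacent domain" that survives messy
architectures. After sorting a protein's retained hits by
`(ali_start, ali_end, family)`:

* the upstream boundary of a hit is the **rightmost alignment end among all
  preceding hits** (0 at the sequence start);
* the downstream boundary is the alignment start of the next hit
  (`seq_length + 1` at the sequence end).

For non-overlapping architectures this is simply the nearest neighbour. When
a domain sits inside another, the inner hit sees the host's end *upstream*
of its own start and the host sees the guest's start *before* its own end —
both intervals go negative, which is exactly the nesting signal: a negative
$d$ inflates the score, possibly above 1 (more model "missing" than the
model is long). Any call with $d < 0$ or score $> 1$ is flagged `nested` and
excluded; nesting is a legitimate annotation pattern, not atrophy.

Partial (crossing) overlaps between different families are a different
failure mode: they are resolved before scoring, keeping the hit with the
better E-value (ties: longer span, then lexicographic family accession) in
rank order and flagging conflicting hits, which then take no part in
adjacency. Full containment is deliberately *not* resolved this way — it is
the nested architecture above — and same-family overlaps are left to the
split/tandem logic. The E-value rule is this package's choice: curated
region files are largely overlap-free by construction, so the resolution
procedure has no published counterpart to follow.

Two further pair-geometry flags keep the candidate set honest:

* `tandem` — the facing boundaries of a same-family consecutive pair that
  re-covers the model. The unmatched states at those boundaries are present
  in the partner hit, so they are repeat structure, not loss.
* `split_pair_boundary` — the facing boundaries of a split pair. The missing
  states there are exactly the within-domain call's $D_W$; scoring them
  again as domain-bounded atrophy would count one event twice.

## The filter cascade

Filters run in this order (each is also available as a standalone function):

1. **Protein existence / fragment** (`filter_protein_level`): keep PE level
   1, drop UniProt-style fragment sequences. Lower-evidence tiers are
   enriched in exactly the truncation artefacts this method must avoid.
2. **Overlap resolution** (`resolve_overlaps`), margin 0 residues by
   default: any shared residue between different families counts. The margin
   is configurable because annotation pipelines differ in the overlap they
   tolerate within clans.
3. **Scoring and classification** (`build_calls`): every retained hit gets
   an N and a C evaluation; qualifying consecutive same-family pairs get a
   within-domain evaluation.
4. **Clan adjacency**: consecutive hits whose families share a clan make the
   shared boundary ambiguous (the interval could extend either homologous
   model), so both facing calls are flagged. A hit without clan membership
   never fires this filter. The flag applies to boundary calls only — a
   split pair's fragments share a clan by construction, and flagging the
   within-domain call would make that whole class undetectable.
5. **Nested / small-domain / window** (`apply_call_filters`): `nested` as
   above; `small_domain` for models under 30 match states (an
   above-threshold score there is the loss of roughly one secondary
   structural element, not atrophy); finally the candidate window
   `0.15 <= AS <= 1`.

A call with an empty flag set is a candidate for manual triage.

### Numerical choices

Scores are rationals with integer numerator $D - d$ and denominator $L$.
All threshold comparisons are done by integer cross-multiplication (the
threshold is taken as a rational over $10^6$), so a call with
$20(D - d) = 3L$ sits exactly on the 0.15 boundary and is always a
candidate, and score-1 calls are included while anything above 1 is nested
by construction. Serialized scores carry six decimal places; the exact
rational is always recoverable from the `D`, `d`, `L` columns. Abutting
domains give $d = 0$ with no pseudo-count. When more than two fragments of
one family occur, consecutive pairs in alignment order are evaluated
independently; fragments separated by a foreign domain are not paired, since
the intervening architecture makes the "internal gap" reading unsafe.

## Manual triage and the report stage

The failure modes that genuinely require a human (gene-prediction errors,
multi-domain family models, circular permutations, short repeats, disorder,
missing reference structures, complete structural domains mis-flagged) enter
the pipeline as verdict labels, not computations. `triage_summary()` builds
the class-by-verdict contingency table with column percentages (rounded to
2 decimal places), the failure-mode tally, and

$$\mathrm{PPV} = \frac{\text{true}}{\text{true} + \text{false}}$$

to 3 decimal places, where "true" counts structure-confirmed plus
homolog-inferred putative cases and unverdicted/unknown calls are excluded
from the denominator. The atrophy fraction — true cases over all scored
domain instances, as a percentage — is *truncated* to 2 decimal places
rather than rounded: the reference value of this statistic is quoted in the
literature with truncated digits (0.0656% quoted as 0.06%), and the package
reproduces that convention for this one number.

The package bundles the marginal tallies of the reference proteome-wide
screen (UniProt 2012_06 against Pfam 27.0; 1,636 candidates inspected, 75
confirmed or putative, 1,287 failure modes over 114,303 scored domain
instances) under `inst/extdata/`. The joint class-by-failure-mode breakdown
was never published; `reference_triage_verdicts()` fills it with a
deterministic greedy allocation that preserves both marginals exactly, which
is all the summary arithmetic consumes.

## The synthetic proteome generator

`generate_proteome()` plants one protein per specification: each of the five
atrophy classes at a chosen target score (realised as `round(target * L)/L`,
so within $1/L$ of the target, with the planted interval fixed at 0), plus
complete domains and each failure mode — tandem pairs, nested pairs, partial
overlaps, fragments, PE 2–5 sequences, same-clan adjacent pairs and small
models. Model lengths default to uniform draws from 50–600 match states,
spanning typical family-model sizes; linkers are short uniform draws. The
truth table records each plant's expected class, exact score ingredients and
expected filter outcome.

The default scenario (`default_scenario()`) has 220 plants — 24 per atrophy
class, including one exactly on the 0.15 boundary and one below it at 0.10,
plus 20 complete domains and 11–12 of each failure mode — enough to exercise
every class and filter branch while keeping a full end-to-end run under a
couple of seconds.

What the generator does **not** emulate: no residues are produced (the
pipeline never reads sequence), there are no alignment insertions or
deletions (planted hits map model states 1:1 to residues), no E-value noise
correlated with hit quality, no multi-plant proteins, and no
gene-prediction-error or circular-permutation geometry (those are
manual-triage labels, not mechanical plants). Passing the planted-recovery
tests therefore demonstrates that the scoring, classification and filter
logic is implemented correctly — not that the 0.15 threshold or the PE
filter have any particular sensitivity or specificity on real proteomes,
which is a property of real annotation noise the fixtures do not model.

Test problem sizes were chosen to keep the default suite fast while covering
the combinatorics: 220-plant scenarios for end-to-end checks, 1,000 random
proteins of up to 6 hits for the occupancy-map oracle comparison, and a few
hundred random draws per algebraic property.

## Worked example

```{r example}
pr <- generate_proteome(default_scenario(), seed = 42)
res <- detect_atrophy(pr$hits, pr$proteins)
res
```

All planted clean events are recovered with their exact scores:

```{r recovery}
expected <- pr$truth[pr$truth$expected_candidate, ]
m <- merge(expected, res$candidates,
           by.x = c("protein_acc", "expected_class"),
           by.y = c("protein_acc", "atrophy_class"))
nrow(m) == nrow(expected) && all(m$score == m$expected_score)
```

And the report stage reproduces the reference screen's summary:

```{r reference}
s <- triage_summary(reference_triage_verdicts(),
                    total_instances =
                      reference_dataset_counts()$domain_instances_scored)
s$ppv
s$atrophy_fraction_percent
```

## Known limitations

* The sequence-level class is taken at face value: a case called N-terminal
  end-bounded here may turn out, on structural comparison, to be
  within-domain atrophy (the reference screen documents exactly such a
  reinterpretation). Structural confirmation is out of scope.
* Envelope coordinates are ignored; intervals use alignment coordinates
  throughout. Envelope-based intervals would be systematically smaller and
  scores correspondingly higher.
* E-value-based overlap resolution is a pragmatic stand-in for curated
  overlap-free region files; on raw search output it can discard the
  biologically relevant hit when a spurious hit scores better.
* Circular permutations and short sequence repeats are not auto-detected;
  they surface only through manual verdicts.
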