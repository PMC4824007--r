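---
title: "Methods: tracing the emergence of the endocytic machinery"
author: "CMETrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing the emergence of the endocytic machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Clathrin-mediated endocytosis (CME) in animals is carried out by a machine of
several dozen proteins — clathrin itself, the AP2 adaptor complex, muniscins
(FCHO), scaffolds such as Eps15 and intersectin, dynamin, and a set of
cargo-specific adaptors (CLASPs). Which parts of this machine were already
present in the last eukaryotic common ancestor, and which were added later on
the lineage leading to animals? CMETrace implements a comparative-proteomics
survey that answers this question for any set of query families and
proteomes: homologs are detected with profile hidden Markov models, validated
by domain-architecture comparison and a reciprocal-best-hit test, summarised
as a presence/absence (phyletic) matrix, and mapped to **emergence epochs**
on a labelled taxonomy. Around this core the package scans disordered
protein tails for short linear interaction motifs, assembles
evidence-filtered protein-interaction networks, and computes
alignment-anchored conservation and residue-contact statistics.

Because the survey's correctness cannot be judged on real proteomes (there is
no ground truth), the package ships a first-class synthetic-data module that
evolves protein families along a labelled taxonomy with planted events —
domain gains and losses, motif plants, duplications — and records the truth
table that the pipeline must recover.

# The detection model

## Profile hidden Markov models

Each query family is represented by a profile HMM built from a seed
alignment (`buildProfile()`). The architecture is a simplified Plan7: per
match position a match state (estimated emissions), an insert state (fixed
to the background distribution), and a delete state; single-hit scoring
only. Two scoring modes exist:

* **local** (the scanning mode): uniform entry over match states with weight
  $1/M$, free exit from any match state, and cost-free background flanks.
  This mirrors how a search tool scores a domain anywhere in a longer
  protein.
* **glocal** (the closed-form test mode): the model accounts for the whole
  sequence, `begin -> M_1` through `M_M -> end`. For a no-indel profile the
  probabilities of all length-$M$ sequences sum to exactly 1, which anchors
  the normalization tests.

Scores are log-odds in bits against the background (the BLOSUM62 marginal
frequencies). `X` emits the background in every state, so it contributes 0
bits everywhere. The forward recursion runs in linear probability space with
per-row rescaling (the classic scaled forward), which is exactly equivalent
to log-space summation but roughly an order of magnitude faster; the Viterbi
recursion stays in log space and is only run on reported hits to obtain
envelopes.

Construction rules, stated because seed alignments are small (four model
organisms): a column with less than 50% gaps becomes a match column (a tie
is an insert column); match emissions are smoothed with
background-proportional pseudocounts of total mass 1.0,
$e_j(a) = (n_{ja} + q_a) / (n_j + 1)$; transitions get a Laplace pseudocount
of 0.1 over each allowed transition set. Plan7 forbids I–D and D–I
transitions; the rare seed-alignment transitions of that kind are simply not
counted.

## E-values

The package supplies its own e-value calibration (`calibrateProfile()`):
`nNull` i.i.d. background sequences, lengths resampled from the target
proteomes' empirical length distribution, are scored with the local forward
algorithm, and a Gumbel (type-I extreme value) distribution is fitted by
maximum likelihood (method-of-moments start). A hit's e-value is
$E = Z \cdot P(S \ge s)$ under the fitted null with $Z$ the number of
sequences scanned. Across a pipeline run a single pooled length distribution
is used so that e-values are comparable across proteomes; calibrations are
computed once per profile per run. The fitted tail is validated on held-out
nulls: at $p \le 0.01$ the empirical fraction must lie within three binomial
standard errors of the nominal level (the acceptance suite checks
[0.007, 0.013] at $n = 10{,}000$).

Defaults: `nNull = 500` inside pipeline runs (10,000 in the dedicated
calibration checks), sequence and domain inclusion thresholds 0.01 — the
thresholds the survey design prescribes.

## Domain architectures

`annotateDomains()` scans a protein with every calibrated domain profile.
The single-hit engine is applied iteratively: the best hit's envelope is
masked with `X` and the scan repeated, so tandem repeats (e.g. multiple SH3
copies) are all recovered. Hits must clear the 0.01 domain e-value **and**
span at least half of the domain model (`minCoverage = 0.5`). The coverage
rule exists because chance matches of six or seven residues against a sharp
profile column run can clear an e-value threshold while representing no
domain; suppressing fragments is standard practice in domain-architecture
annotation and the planted-truth tests demonstrate why it is needed.
Overlaps between surviving hits are resolved greedily by ascending e-value.

Architecture comparison (`matchArchitecture()`) is exact ordered equality of
domain ids, with a run-length tolerance for tandem repeats (`collapseRepeats`,
default on): a run of $k \ge 1$ copies of one domain matches a reference run
of that domain, so a two-SH3 and a five-SH3 form of the same scaffold both
count as full matches. A hit sharing at least one domain without full
equality is `partial`; disjoint architectures are `none`.

## The homolog decision

For one family in one proteome (`callHomologs()`):

1. every forward-search hit with $E \le 0.01$ is annotated with its domain
   architecture;
2. unless the family relaxes it, each full- or partial-architecture hit is
   submitted to the reciprocal-best-hit test: Smith–Waterman ranking
   (BLOSUM62, gap open 11, extend 1 — the standard protein-search defaults)
   of the hit against the reference proteome must place one of the family's
   designated members first. The designated set is the family's full
   reference paralog set, so any paralog ranked first passes;
3. a hit is **accepted** iff its architecture is `full` and (relaxation
   aside) the reciprocal test passes. At least one accepted hit makes the
   family a `homolog` there, and every accepted hit counts as a paralog;
4. with no accepted hit, a reciprocal-passing `partial` hit makes the call
   `analog_ancestor` — the dynamin-related-protein situation, where an
   earlier-branching relative shares part of the architecture and still
   points back to the query family;
5. otherwise `absent`. Partial hits that fail reciprocity are reported
   absent with their evidence retained.

The reciprocal ranking deliberately uses pairwise local alignment rather
than a second profile search: what the step needs is a deterministic
best-hit ranking against the reference proteome, and Smith–Waterman with
fixed tie-breaking (score, then lexicographic id) provides it
reproducibly.

A relaxed family (`relaxReciprocal`) accepts typical architecture alone —
the escape hatch used for extremely distant homologs where reciprocal
ranking is uninformative.

## Emergence epochs

The emergence epoch of a family is the smallest named clade on the
taxonomy's focal path — root included — that contains **all** organisms
where the family's homolog was found (`emergenceEpoch()`). A family found in
one excavate and one holozoan therefore maps to the root, matching the
convention that scattered deep presences indicate ancestral origin followed
by losses. An organism count of one suffices to mark a clade
(`minOrganisms` raises that bar if desired). Adding an organism to the
presence set can only move the epoch rootward — a monotonicity property the
suite checks.

# Motif scanning

The three built-in motif classes are scanned as amino-acid regular
expressions: `DP[WF]|F.D.F|WV.F|F.F.[FL]` (AP2-binding),
`L[FILMV].[FILMV][DE]|L[FILMV].[DE][FILMV]` (clathrin box) and `NPF`
(EH-domain binding). Only the disordered terminal tail outside all resolved
domain envelopes is scanned — the C-terminal tail by default, the N-terminal
tail for stonin-type families; inter-domain linkers are excluded (a
`full`-region policy exists for sensitivity analysis). Every match start
position counts, overlaps included, and a position matching two alternatives
counts once; this convention is fixed because greedy non-overlapping scans
are order-dependent under alternation. Per taxon group the package reports
the occurrence (organisms with the motif in the family's protein over all
organisms of the group — absentees stay in the denominator, with a
possessors-only switch) and the median motif count over motif-containing
proteins.

The activator-region (APA-style) search is a profile search, not a regex:
a profile built from a three-sequence seed of activator regions scores each
candidate protein, and a record passes iff its e-value is at most 0.01 —
equivalently $-\log_{10} E \ge 2$, the dashed threshold line of an e-value
bar diagram.

# Interaction networks

Interaction records (PSI-MI-TAB-like TSV) are filtered by an evidence
policy: affinity purification of complexes, protein-fragment
complementation, reconstituted complexes, Far Western blotting and
biochemical activity are retained; high-throughput screens, colocalization,
cofractionation and two-hybrid are always removed; unlisted methods are
dropped conservatively with an audit message. Matching is case-insensitive
substring over method names, which covers both free text and
controlled-vocabulary codes listed verbatim — the exact vocabulary differs
between source databases, so the policy ships as editable configuration.
The surviving records build an undirected graph (parallel records collapse
onto one edge that keeps its support list; self-loops are retained but
flagged) whose nodes are annotated with emergence epochs and functional
classes. GraphML export is lossless; SIF keeps the edge list only.

# Conservation and contacts

Sequence-logo mathematics: per column, frequencies over non-gap characters,
Shannon entropy $H$ in bits and information content
$IC = \log_2 20 - H - e_n$, with the small-sample correction
$e_n = 19/(2 \ln(2) n)$ (togglable; off in closed-form tests, on for
logo-style reporting), clipped at zero. Columns are addressed through
reference-sequence numbering: alignment column $c$ maps to reference
position $p$ iff the reference row's $p$-th non-gap character sits in
column $c$.

Residue contacts in coordinate models: the minimal heavy-atom distance
decides contact at a default cutoff of 4.5 Å; opposite-charge pairs (K/R/H
vs D/E) with charged-group atoms within 4.0 Å are `electrostatic`,
hydrophobic pairs (A/V/L/I/M/F/W/Y/P) with side-chain carbons within 4.5 Å
are `hydrophobic`, everything else `other`. These cutoffs are this package's
operationalization of "deduced contacts" — common structural-biology
practice, config-exposed, not a published criterion.

# The synthetic study conditions

The generator's defaults define the conditions every end-to-end test runs
under, and they are fixed:

* **Taxonomy**: a nested clade series LECA → Obazoa → Opisthokonta →
  Holozoa → Metazoa → Vertebrata plus two basal outgroup clades (Excavata,
  Archaeplastida), two organisms per clade (16 organisms), branch length 1.
* **Families**: eight, emulating the canonical scenarios — two ancient core
  components (clathrin-heavy-chain-like, AP2-mu-like), an opisthokont
  muniscin-like family that gains an activator region in Holozoa, a
  dynamin-like family whose PH-domain gain in Holozoa leaves
  partial-architecture relatives (analog/ancestors) everywhere else, an
  intersectin-like family with an SH3 expansion from two to five copies in
  Metazoa, a CALM-like family with planted NPF motifs and a vertebrate
  triplication, an Eps15-like family born in Obazoa that gains AP2-binding
  motifs in Metazoa, and a stonin-like family with N-terminal motifs.
* **Rates**: 0.1 substitutions per site per unit branch in tails and
  linkers, halved inside domain and region blocks; family blocks diverge by
  0.25 from the shared domain library at birth; duplicated copies jolt by
  0.05. At these values the most distant planted homolog retains roughly
  two-thirds identity in its domains — comfortably inside profile
  sensitivity, which is the regime the recovery guarantees are stated for.
  Substitutions follow an equal-exchangeability model (replacement uniform
  over the other 19 residues), giving the closed-form expected divergence
  $(19/20)(1 - e^{-(20/19)t})$ that the generator tests verify.
* **Decoys**: 200 background sequences of length 80–300 per proteome.
* **Seeds**: the default fixture is generated at seed 42; seed alignments
  come from the four model-organism leaves (the two metazoan and two
  vertebrate organisms), which are ungapped by construction because domains
  never receive indels.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: indels inside domains, rate heterogeneity among
sites and lineages, compositional bias, convergent domain architectures,
alignment error in the seeds, and incomplete or mispredicted proteomes.
The planted-truth results certify the pipeline's logic, not HMMER-parity
sensitivity on diverged real proteomes.

# Numerical and design choices

* Coordinates and residue positions are 1-based inclusive everywhere a user
  sees them.
* Selenocysteine/pyrrolysine are mapped to `X` with a warning on input;
  sequences are validated against the 20-letter alphabet plus `X` and
  parsing fails loudly otherwise. The only silent drops are documented ones
  (hydrogens and non-`A` altlocs in coordinate files, `#` comment lines).
* Tie-breaks are fixed: proteome ranking by score then lexicographic id;
  scan output by e-value then id; overlap resolution by e-value then start.
  Pairwise-alignment traceback delegates to the alignment backend's
  deterministic traceback; scores are the tested contract.
* All randomness flows from explicit seeds (`calibrateProfile`,
  `evolveFamily`, `generateSurveyFixture`); helper seeding never perturbs
  the caller's RNG state. Identical inputs and seeds reproduce identical
  outputs, file-for-file; pipeline outputs are written via
  write-then-rename so failed runs leave no truncated files.
* Problem sizes in the shipped tests — 16 proteomes of ~210 sequences, 200
  instances of the path-enumeration oracle, 500 alignment-oracle cases,
  10,000-sequence calibration checks — were chosen so the whole suite
  validates every contract in about two minutes on one core.

# Known limitations

Single-hit scoring means one profile hit per sequence per scan; repeated
domains are recovered by iterative masking during annotation, but a protein
containing two separated copies of a whole *family* region reports only the
better one at the sequence level. The Gumbel fit is a single distribution
over a pooled length mixture; per-length calibration would be sharper.
Multihit alignment modes, MSV/SSV-style acceleration filters, DNA profiles,
coiled-coil prediction, tree inference, homology modelling and any graphical
rendering are out of scope; alignments, coordinate models and interaction
records are consumed, never generated, by the analysis modules.
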