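---
title: "Detecting and confirming horizontal gene transfer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and confirming horizontal gene transfer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtscreen)
```

## The problem

Similarity-based screens are the workhorse of horizontal gene transfer
(HGT) detection in animals: a gene whose best database hits are bacterial
rather than animal is suspicious. But a high similarity score can also
arise from gene loss in other animals, rate variation, or — most
insidiously — contamination, either of the assembly being screened or of
the reference databases themselves. `hgtscreen` implements a two-stage
framework: a fast alien-index screen over BLAST-style tabular output, and
a phylogenetic confirmation stage that asks, with explicit hypothesis
tests, whether the data *reject* the topology in which the candidate is
simply an animal gene (a monophyletic Metazoa containing the query).
Follow-up screens — spliceosomal intron checks, reciprocal best hits
across related transcriptomes, developmental expression — address
contamination and biological relevance.

## Alien index and HGT index

For each query gene we take the best (smallest) E-value among animal hits
and among non-animal hits, after removing hits from the query organism's
own phylum (so the assembly being screened cannot vouch for itself). The
alien index is

$$\mathrm{AI} = \ln(E_\text{animal} + \varepsilon) -
               \ln(E_\text{non-animal} + \varepsilon),
  \qquad \varepsilon = 10^{-200},$$

and a gene is an HGT candidate when $\mathrm{AI} > 45$ (strict). A class
with no hit at all contributes $E = 1$: the worst plausible hit, which
keeps the index finite and directionally correct. The HGT index — the
difference between the best non-animal and animal bit scores, with absent
hits contributing 0 — is reported alongside but never filtered on; bit
scores grow with alignment length, so the E-value-based index is the
screen. The exact base and offset of the logarithm are conventions of the
original alien-index software rather than quantities stated with the
threshold; the natural-log form above is this package's assumption,
chosen to be consistent with the threshold's scale.

The screen is deliberately permissive: its output is a candidate list for
phylogenetic confirmation, not a verdict.

## The likelihood engine

Confirmation requires maximum-likelihood gene trees, metazoan-constraint
trees, and per-site log-likelihoods. These are provided by an internal
20-state amino-acid likelihood engine (C++ core) rather than an external
ML program, so that the whole framework is reproducible from R and
testable against enumeration oracles.

* **Model.** General time-reversible: $Q = S\,\mathrm{diag}(\pi)$ with a
  symmetric exchangeability matrix $S$ and stationary frequencies $\pi$,
  normalized to one expected substitution per site per unit branch
  length. The default is the Poisson model (equal exchangeabilities,
  uniform frequencies) — cheap, adequate for simulation studies, and free
  of any claim about which published matrix a user should prefer; WAG- or
  LG-style tables load via `read_exchangeability_matrix()`. Rate
  heterogeneity uses the discrete-gamma approximation with
  equal-probability categories represented by their means. Gaps and
  ambiguity codes are fully ambiguous states (partial vectors of ones),
  the standard pruning convention.
* **Per-site log-likelihoods** come from Felsenstein pruning with
  per-pattern rescaling; site patterns are compressed before evaluation.
  Transition probabilities use the symmetrized eigendecomposition
  $P(t) = V e^{\Lambda t} V^{-1}$.
* **Branch-length optimization** sweeps the edges, maximizing each
  edge's profile likelihood by safeguarded Newton steps. The profile of
  one edge given the rest of the tree is
  $a_s(t) = u_s^\top P(t)\, d_s$ per site pattern $s$, where $u$ is the
  exclusive up-message at the parent and $d$ the down-partial at the
  child; in the eigenbasis $a_s(t)$ and its derivatives are sums of 20
  exponentials, so a Newton iteration costs almost nothing once the
  messages are cached. A joint sweep (all edges updated from the same
  messages, with backtracking) is tried first; if it stalls — which can
  happen on symmetric starting points — the optimizer falls back to
  strictly monotone per-edge sweeps with refreshed messages. Lengths are
  clamped to $[10^{-8}, 20]$; convergence is declared when a sweep gains
  less than `tol` (default $10^{-6}$) log units, with at most 20 sweeps.
* **Tree search.** Up to 7 leaves, all unrooted topologies are
  enumerated (by recursive edge insertion); each is screened by its
  likelihood at a common data-scaled starting branch length (a quarter of
  the mean corrected pairwise distance), and the top `refine_k` (default
  5; all of them when at most 10 exist) are fully optimized. Above 7
  leaves the search hill-climbs by nearest-neighbour interchange from a
  neighbour-joining start on Poisson-corrected distances, ranking NNI
  neighbours by their likelihood at carried-over branch lengths and
  optimizing only the top-ranked few — the standard lazy strategy.
  Constrained searches (a leaf set forced monophyletic) filter the
  enumeration, or reject NNI moves that break the constraint, starting
  from a tree in which the constraint set is grafted together. All
  searches are deterministic given their inputs.
* **Simulation.** `simulate_alignment()` draws root states from $\pi$
  and walks transitions down the tree, drawing a gamma category per site
  when enabled; it backs both the SOWH test's parametric replicates and
  the synthetic scenarios.

The engine is validated against closed forms and enumeration: the sum of
pattern likelihoods over all $20^4$ four-leaf patterns equals 1 to
$10^{-8}$; two-sequence ML distances match the 20-state distance
correction $-\tfrac{19}{20}\ln(1 - \tfrac{20}{19}p)$ to $10^{-4}$;
likelihoods are invariant to re-rooting to $10^{-9}$; and optimized
likelihoods agree with an independent engine (phangorn) in the test
suite.

## Contaminant pruning on gene trees

Reference databases contain mislabeled (contaminant) sequences, so a
couple of "animal" sequences falling inside a bacterial clade should not
sink an otherwise clean candidate. `prune_to_monophyly()` removes the
smallest set of at most `max_prune = 2` group members whose deletion
makes the remaining group monophyletic on the unrooted tree (monophyly =
some edge bipartitions the leaves into exactly group vs complement).
Subsets are tried size 0, 1, 2, lexicographically within a size, so
results are deterministic. Genes needing more than two removals are
discarded — the screening rule this package implements. In the pipeline
the "main animal clade" is allowed to either contain the query (vertical
inheritance) or exclude it (transfer); both readings are tried and the
smaller removal set wins. A group reduced to a single member is treated
as trivially monophyletic.

## The SOWH test

The SOWH parametric bootstrap asks whether the data reject the
constrained topology (query inside a monophyletic Metazoa). The statistic
is $\delta = \ln L_\text{ML} - \ln L_\text{constrained}$, both terms from
full searches. The null distribution comes from `n_reps` alignments
simulated on the constrained tree with its optimized branch lengths, each
re-analyzed by exactly the same dual search; the p-value is
$(1 + \#\{\delta^* \ge \delta\}) / (n_\text{reps} + 1)$ (add-one
correction, so finite replicates never yield $p = 0$). Because the
constrained optimum is also a candidate for the unconstrained search,
$\ln L_\text{ML}$ is floored at $\ln L_\text{constrained}$ and
$\delta \ge 0$ always.

Two properties of this test are worth knowing. First, when the
constraint is *true* and internal branches are long, the ML tree almost
always satisfies the constraint, $\delta = 0$, and $p = 1$: the test is
conservative at the boundary, which is a documented property of the SOWH
design (the constrained hypothesis is the closure of its neighbours
through zero-length edges), not an artifact. The p-value remains *valid*
(super-uniform). Second, meaningful calibration checks therefore need a
null whose internal edges are short enough that topology estimation is
genuinely uncertain. The package's calibration study uses a 6-taxon
constrained tree with terminal edges 0.15 and internal edges 0.005
substitutions/site (about one expected change per internal edge over the
200-site alignments), 99 replicates per test, 100 tests: the rejection
rate at $\alpha = 0.05$ sits inside the exact binomial band, and the
excess-rejection (one-sided Kolmogorov–Smirnov) distance from uniform
stays below 0.15. The two-sided KS distance is dominated by the
conservative atom at $p = 1$ and is not a meaningful check here.

## The AU test via multiscale RELL

The approximately-unbiased test resamples per-site log-likelihoods
(RELL) at several scales $r$: each replicate draws
$\lceil r \cdot n_\text{sites} \rceil$ sites with replacement, sums the
per-site values per tree, and awards the replicate to the argmax tree
(ties split equally). The focal tree's bootstrap proportion
$\mathrm{BP}_r$ is transformed to $z_r = \Phi^{-1}(1 - \mathrm{BP}_r)$
(after clamping to $[1/(2B), 1 - 1/(2B)]$ at $B$ replicates per scale),
and the signed distance $d$ and curvature $c$ are estimated by weighted
least squares from $z_r \approx d\sqrt{r} + c/\sqrt{r}$ with
binomial-variance weights; then $p_\mathrm{AU} = 1 - \Phi(d - c)$.
Scales where the focal tree essentially always or never wins are
*saturated*: their $z$ values sit at the clamp boundary and carry no
curvature information, and fitting through them misreads flatness as
curvature and inflates the p-value. The fit therefore uses only the
informative (non-saturated) scales; when fewer than two exist the
p-value degenerates to the saturated side ($p = 0$ for a tree that
never wins, $p = 1$ for one that always wins) and is flagged. Defaults: ten scales $0.5, 0.6, \dots, 1.4$ and
10{,}000 replicates per scale, the standard settings of the multiscale
bootstrap; tests and the pipeline's reduced runs use smaller replicate
counts, stated where used.

Two suboptimal-tree sets feed two AU runs, mirroring the two reported AU
columns: (a) nonparametric bootstrap trees (quick ML re-searches on
resampled columns), deduplicated by bipartition-set identity; (b)
deliberately suboptimal trees made by cyclically exchanging the
attachment points of three random disjoint clades of at most three
leaves ("shuffling clades of three" — the cyclic-exchange realization is
this package's interpretation of that procedure). The focal tree of both
runs is the metazoan-constraint tree: a small $p_\mathrm{AU}$ means the
constraint tree is outside the confidence set, i.e. evidence for HGT.

A candidate is **confirmed** when the SOWH test and both AU runs are
significant at $\alpha \le 0.05$, boundary inclusive — the
all-three-tests rule. Applied to the published p-value table shipped with
the package (`published_test_pvalues()`), the rule reproduces the
original confirmed/unconfirmed partition exactly (7 of 12).

For visualization, likelihood proportions divide each tree's
log-likelihood by the mean log-likelihood of the suboptimal set (the
reported "likelihood scores" of ML programs are log-likelihoods, which is
this package's reading); `plot_likelihood_proportions()` draws the violin
summary in which confirmed candidates show their constraint tree outside
the bootstrap cloud.

## Expression, splice sites, and provenance screens

* **Expression.** 3'-tag (CEL-Seq-style) counts are normalized per
  million with no length term; the developmental score of a gene is the
  sum over distinct time points of the median normalized value across
  replicates (midpoint median for even counts), and `score >= 100` flags
  the gene as developmentally expressed — inclusive, per the stated
  rule. The 25 time points spanning 0–20 hours post fertilization are
  the default fixture shape, not a hard-coded assumption.
* **Splice sites.** Introns are inter-exon gaps in transcript
  orientation (1-based inclusive GFF3 coordinates); on the minus strand
  dinucleotides are read from the reverse complement. Canonical U2
  spliceosomal introns (GT donor, AG acceptor) are eukaryote-specific,
  so their presence argues against bacterial contamination.
* **Reciprocal best hits** across related transcriptomes (E-value
  cutoff 0.1, ties by bit score then rank) show a candidate is present in
  independently collected samples — contamination of all of them by the
  same organism being implausible.
* **Close relatives.** A top RefSeq-style hit from Choanoflagellatea or
  Filasterea (the closest protistan relatives of animals) leaves vertical
  inheritance plausible, so such candidates are removed.
* **Taxon selection** for gene trees keeps the top 10 hits per group
  (bacteria with archaea, non-fungal non-metazoan eukaryotes, fungi,
  animals), one per genus within a group, plus forced inclusion of named
  reference organisms. Archaea ride with bacteria because the original
  four-group selection lists no archaeal group; genus deduplication is
  applied within groups.
* **Branching rule.** After the database screen, a candidate with no
  animal hits at `E <= 0.1` is treated as an HGT absent from other
  animals (no tree is possible); one or two animal hits mean possible
  contamination and the candidate is discarded (the one-hit case is
  assigned to the discard branch — more conservative than the weakest
  retained evidence); three or more go to phylogenetic testing.

## Synthetic scenarios

`simulate_hgt_scenario()` builds ground-truthed fixtures: three domain
clades (bacteria, non-metazoan eukaryotes, metazoans) with
exponential within-clade branch lengths (mean $0.15 \times$
`divergence_scale`) joined by long stems ($0.4 \times$ scale plus an
exponential tail), and a ctenophore query grafted per scenario kind
(inside the donor clade for transfers, inside Metazoa for vertical
genes; contamination scenarios relabel bacterial leaves as metazoan in
the class map). Default clade sizes of 10 mirror a top-10-per-group
taxon selection; tests use smaller clades (stated per test) to keep
runtimes in seconds. The similarity-table synthesizer maps query–subject
identity to bits and E-values with a Karlin–Altschul-shaped convention
($\lambda = 2$, $E = n^2 2^{-\text{bits}}$, clamped to
$[10^{-180}, 10]$) — fixture conventions, not claims about any search
program. Expression fixtures draw negative-binomial counts (dispersion
0.2) around maternal / zygotic-spike / cyclic / silent profile means over
a constant background transcriptome of 500 genes, so per-million values
are realistic.

What these fixtures do *not* emulate: alignment error and trimming,
compositional heterogeneity across lineages, rate variation across
branches, gappy real alignments, and database taxon sampling biases.
Passing the synthetic recovery checks therefore demonstrates the
machinery is correct and calibrated under its own model, not that the
biological error rates on real data equal the synthetic ones.

## Problem sizes used by the checks

The statistical acceptance checks run: the scoring oracle on ~1,000
synthetic gene tables; the likelihood enumeration oracle on 50 random
4-leaf trees ($20^4$ patterns each); the pruning oracle on 200 random
12-leaf trees; SOWH calibration at 100 null tests × 99 replicates
(6 taxa, 200 sites) and power at 20 strong-signal tests (500 sites);
AU behaviour at $10^4$ RELL replicates; and the end-to-end pipeline on
20 transfer + 20 vertical scenarios (clades 3/2/4 + query, 300 sites,
19 SOWH replicates, 10 bootstrap and 15 shuffled suboptimal trees, 1,000
RELL replicates). `scripts/acceptance.R` recomputes the same quantities
at slightly reduced replication and writes them as JSON. These sizes are
the package's chosen desk-scale study conditions; the underlying
functions default to the larger standard settings named above.

## Known limitations

* The engine fits branch lengths but not model parameters
  (exchangeabilities, frequencies, gamma shape are taken as given).
* NNI hill-climbing can stop at local optima on large or conflicted
  alignments; the exhaustive path is exact but capped at 7 leaves.
* The SOWH replicate searches inherit whatever bias the search heuristic
  has, in both the observed and null statistics — which is exactly why
  the calibration study is part of the test suite.
* Donor-lineage assignment, functional annotation, and alignment
  construction are out of scope; alignments arrive ready-made.
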