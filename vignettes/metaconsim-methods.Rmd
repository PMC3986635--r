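---
title: "Simulating diverse metagenomes and measuring assignment consistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating diverse metagenomes and measuring assignment consistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaconsim)
```

This vignette is the package's own account of its models and the design
choices behind them: what is simulated and how, what each tunable
parameter means, what the mock-data generator does and does not emulate,
and where the numerics required a decision that the underlying ideas
left open.

## Community design from a Shannon-diversity target

A simulated metagenome starts from three ecological controls: the number
of species `max_taxa` (S), a target Shannon diversity `H_target`
(H′ = −Σᵢ pᵢ ln pᵢ, in nats), and a `dominance_cap` — the maximum
relative abundance any single species may reach (the two built-in
scenario families use 0.05 and 0.80).

H′ alone does not determine an abundance vector, so a one-parameter
rank-abundance family is needed. `design_community()` uses a geometric
series, pᵢ ∝ θ^(i−1), because it is the minimal monotone family that
spans the entire feasible entropy range with a single invertible
parameter: θ → 0 concentrates the community, θ = 1 is uniform
(H′ = ln S). The cap is enforced by water-filling: entries that would
exceed the cap are pinned to it and the excess mass is redistributed
proportionally over the geometric tail (since the weights are
decreasing, the pinned set is always a prefix). θ is then solved by
bisection on the *capped* profile's entropy so that the realized H′
matches the target to within 10⁻³ nats — the tolerance the test suite
asserts.

Feasibility is a theorem, not a convention: any distribution with all
pᵢ ≤ c has H′ ≥ ln⌊1/c⌋ (up to the remainder term), and H′ ≤ ln S
always. `design_community()` therefore rejects targets outside
[H_min(c, S), ln S] with a configuration error rather than silently
missing them. At cap 0.05 the floor is ln 20 ≈ 3.0 nats, which is why
the non-dominant scenarios ship with H′ targets above 3.

The built-in `scenario_config()` values (40 or 30 taxa; H′ = 3.4 / 3.2
non-dominant, 1.5 dominant; 60,000 reads) are package defaults chosen
as realistic for moderately diverse host-associated communities; the
community sizes and diversity indices of any particular study are
inputs, not constants, and every field can be overridden.

## Rarefaction anchoring

`fit_rarefaction()` computes the exact expected accumulation curve
E[S(n)] = Σᵢ (1 − (1 − pᵢ)ⁿ) and summarizes it by a three-anchor
logarithmic fit S(n) = a·ln(1 + b·n): the origin, the "maximum linear
point", and the end point (n_reads, max_taxa). Two choices here were
genuinely open:

* **The maximum linear point.** "The last point where species discovery
  per read is still linear" is not a formula. We operationalize it as
  the largest n at which the analytic slope dE[S]/dn = Σᵢ −ln(1−pᵢ)(1−pᵢ)ⁿ
  is still ≥ 1/e of its initial value. The slope is strictly decreasing,
  so binary search finds the point exactly; the 1/e fraction is a
  configurable argument (`slope_fraction`).
* **The functional form.** a·ln(1 + b·n) is the simplest two-parameter
  curve through the origin that is increasing and concave. The fit is
  nonlinear least squares (`minpack.lm::nlsLM`) through the three
  anchors.

A single-taxon profile makes the accumulation curve constant after the
first read; the fit is then degenerate. Rather than letting least
squares pick an arbitrary compromise (which can overshoot 1), the curve
is returned with `degenerate = TRUE` and parameters set analytically so
it passes through (n_reads, 1) and stays ≤ 1 on the sampled range, with
a warning.

## Read sampling and the error model

Fragment lengths are uniform on [`fragment_min`, `fragment_max`]
(350–600 bp by default — "a range" does not pin a distribution, and
uniform adds no shape assumptions); start positions are uniform over
valid positions; strands are Bernoulli(0.5) with minus-strand reads
reverse-complemented. Coordinates are 0-based half-open on the forward
strand and stated as such in the truth-table header. Per-genome read
counts are a multinomial draw on the abundances, so the total is exactly
`n_reads` while genome proportions fluctuate realistically.

The error model separates the two characteristic pyrosequencing error
modes:

* **Point substitutions** — each base independently with probability
  `substitution_rate` (default 0.001), uniform over the three
  alternatives; applied first.
* **Homopolymer edits** — each maximal run of length ≥ 2 in the
  *substituted* sequence is lengthened or shortened by one base (equal
  odds) with probability min(1, `homopolymer_rate` · run length)
  (default rate 0.01 per run-length unit), so longer runs are more
  error-prone, as on real 454-type platforms.

Both rates are configuration keys; the defaults are plausible for
quality-filtered pyrosequencing data but are deliberately mild — real
per-platform rates vary by chemistry and base caller and should be set
by the user when fidelity matters. Pre-error fragment lengths are
recorded in the truth table; post-error lengths differ only by the
homopolymer edits, and both edit types are counted per read.

All randomness flows from one root seed through named substreams
(`derive_seed(seed, "community")`, `".../errors"`, one per genome for
fragment sampling), so each stage is independently replayable and a
whole run is byte-identical under the same configuration and seed — the
pipeline writes an MD5 manifest to make this checkable.

## Mock references and novel taxa

`make_mock_genomes()` generates i.i.d. genomes at a target GC content
under a balanced taxonomy covering all seven canonical ranks (binary
grouping above species). This is a *fixture generator*: i.i.d. genomes
are compositionally well-separated, which makes classifier self-recovery
tests sharp, but they lack everything that makes real assignment hard —
shared ancestry, conserved genes, repeats, horizontal transfer, skewed
GC. Passing tests on mock data therefore demonstrate that the machinery
is correct, not that any method will reach similar accuracy on real
communities; on real data, inter-genome similarity is exactly what
drives the disagreement patterns this package measures.

`diverge_genome()` provides a simplified novel-taxon generator:
independent per-base substitutions and single-base indels at given
rates. Excluding the diverged genome from the training set yields a
"known unknown" whose reads probe behavior on taxa absent from the
references. It makes no attempt to respect coding structure or
phylogenetic realism.

## Assignment methods

* **BLAST + LCA**: outfmt-6 tables are filtered at an e-value cutoff
  (default 10⁻⁵), surviving hits are mapped to taxa, and the read is
  assigned their lowest common ancestor; no surviving hits means
  `UNASSIGNED`. All hits passing the cutoff participate (not only a
  top-score window); the cutoff is an argument.
* **Naive Bayes k-mer classifier**: per-genome log-probability tables
  over the 4^k k-mer space, strand-collapsed (forward plus
  reverse-complement counts), add-one smoothed. A read's score under a
  genome is the sum of log-probabilities of its k-mers; the argmax
  genome's taxon is the call. k defaults to 8 — strong separation on
  mock fixtures at 1/16 of the memory of k = 10 — and is configurable
  within [4, 12]. Argmax ties are broken by lexicographic genome id and
  reported, keeping outputs deterministic.
* **ε cutoff**: the per-genome log-likelihoods are softmaxed to a
  posterior and the call is retained iff the best posterior mass is at
  least ε. ε = 0 retains everything, ε = 1 only reads with posterior
  exactly 1, and the retained count is non-increasing in ε. This is a
  posterior-floor semantic defined by this package; external
  implementations of ε-style cutoffs differ in details, so treat ε
  values as comparable only within one tool.
* **BLAST-restricted combination**: candidate genomes are limited to
  those with surviving BLAST hits for the read before the classifier
  argmax; reads without hits are never assigned. This is what makes
  contaminant-like reads (no reference relative) stay unclassified
  under the combined mode — a property the tests assert directly.
* **Roster stand-ins**: where only one real classifier is available,
  `nbc_lca_classify()` (LCA over all genomes within a log-likelihood
  margin of the best) and `nbc_noisy_classify()` (Gaussian noise on the
  log-likelihoods) provide deterministic LCA-flavored and degraded
  roster members so three-method consistency machinery can be exercised
  end to end. They are labeled as what they are and carry their own
  method ids.

External classifier outputs (e.g. Markov-model based tools) enter
through `ingest_external_assignments()`, which resolves scientific
names against the taxonomy and never re-implements those tools'
scoring.

## Agreement classes and consensus

Per read and rank, all method calls are projected onto the canonical
rank (nearest ranked ancestor; `NO_RANK` when the lineage lacks the
level — e.g. viruses at phylum; projection never descends). The class
rules, in order of precedence:

1. strict majority `UNASSIGNED` → `UNASSIGNED_MAJORITY` — consensus on
   absence is not an assignment;
2. all equal ranked taxa → `ALL_SAME`;
3. all `NO_RANK` → `NO_RANK` (reported separately, not as agreement on
   a taxon);
4. at genus rank, a disagreement between the two designated
   composition-based methods listed in the confused-genera set →
   `CONFUSED` (the set is a configuration input and empty by default:
   which genera a given pair of classifiers swap is a property of
   those external tools, not of this package);
5. some but not all methods share a ranked taxon → `TWO_SAME`, with the
   modal pair recorded;
6. strict majority `NO_RANK` (with no agreeing ranked pair) →
   `NO_RANK`;
7. otherwise `ALL_DIFFERENT`.

Rule 6 is a completion this package had to choose: mixed patterns like
two `NO_RANK` plus one taxon contain no agreeing ranked pair, and
counting them as `ALL_DIFFERENT` would overstate disagreement. The
rules generalize to K > 3 methods (m-of-K semantics); the three-method
case is the canonical configuration. Every read lands in exactly one
class per rank, so class counts always sum to the read count — a
conservation law the tests enforce, alongside equivalence with an
independently written rule-table classifier over exhaustively
enumerated patterns.

The consensus call is the ranked taxon shared by ≥ 2 methods after
projection (ties at the threshold, possible only with K ≥ 4, resolve by
higher count then lexicographic order).

## Sensitivity, precision, and conventions

Per rank and method: sensitivity = 100 · correct / all reads,
precision = 100 · correct / assignments made. A call and the truth are
compared after projecting both; matching `NO_RANK` counts as correct
(the method correctly reported that the level does not exist), and
reads whose truth lacks the rank stay in the denominator — the
denominators are whole datasets. Two conventions are deliberate and
documented rather than silently chosen:

* **Zero assignments** yield precision `NA` (0/0 is undefined); the raw
  counts (`n_correct`, `n_assigned`, `n_total`) are always emitted so
  any other convention can be recomputed.
* **The combined strategy's** "assigned" denominator is the number of
  reads with a consensus taxon, not the number where at least two
  methods said anything.

`true_false_split()` partitions each agreement class by correctness.
Classes with a consensus taxon compare that consensus to the truth; for
the remaining classes a read counts as a true positive when any
method's projected call matches the projected truth — a deliberate,
lenient representative rule, stated here because the class has no
single call to score.

## Length curves and threshold lengths

`length_consistency()` bins reads by length (default 25 bp — fine
enough to resolve the rise of the curve at a few thousand reads per
dataset, coarse enough to keep bin proportions stable) and fits a
weighted OLS polynomial (default degree 3) of the ≥2-method-consistency
proportion on the bin midpoint. `threshold_length()` reads off the
smallest length, on a 1-bp grid, at which the fitted curve reaches a
level *and stays there for the rest of the observed range*. The
sustained-crossing rule exists because polynomials of degree ≥ 2 can
dip back below a level after crossing it, making "first crossing"
ill-defined; demanding sustainment makes the answer unique and
conservative. On synthetic logistic constructions the 75% threshold is
recovered within one bin width across seeds — the package's own
parameter-recovery check, and the reason the defaults are trusted.

## Numerical notes and degenerate inputs

* Entropy bisection runs 200 iterations on θ ∈ (10⁻¹², 1]; the capped
  profile's entropy is continuous and monotone in θ, so this is robust
  far beyond the 10⁻³ tolerance.
* Posterior masses use a log-sum-exp; with hundreds of k-mers per read
  the best posterior is usually numerically 0 or 1, which is why ε
  sweeps on clean data look step-like.
* Empty read sets, single-taxon profiles, single-method rosters, reads
  shorter than k, subjects without taxon mappings, and unresolvable
  taxon names all have defined behaviors (empty outputs, degenerate
  flags, skipped stages with a notice, `UNASSIGNED` with a flag,
  dropped hits with a warning, `UNASSIGNED` with a warning,
  respectively) rather than errors, except where the input is
  contradictory (duplicate read ids, missing truth rows, infeasible
  diversity targets).
* Problem sizes in the test suite are chosen for statistical sharpness
  at interactive speed: 10-genome / 50-kb fixtures for classifier
  self-recovery, 500-read batches for accuracy estimates, 3,000-read
  constructions for threshold recovery, and one full 60,000-read
  scenario for the simulator's configuration contract.

## Known limitations

* Mock genomes are compositionally independent; real-data difficulty
  (shared ancestry, conserved regions) is out of reach of the fixture
  generator by design.
* The ε semantic is a package definition; numeric ε values are not
  transferable to other tools.
* Interpolated-Markov-model scoring is not implemented; such methods
  participate only via ingested tables.
* The rarefaction fit is a three-anchor summary, not an estimator of
  the accumulation curve from data.
* FASTA parsing accepts the IUPAC alphabet; records are flagged, not
  rejected, when they contain non-ACGT characters, and k-mer counting
  skips windows containing them.
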