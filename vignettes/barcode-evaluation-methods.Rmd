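---
title: "Evaluating DNA barcodes within genera: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcodes within genera: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

A DNA barcode is useful for a set of species when specimens can be assigned
to species from the sequence alone. Within a genus of recently diverged
plants this fails in two characteristic ways: *incomplete lineage sorting*
leaves an ancestral haplotype segregating in two descendant species, and
*chloroplast capture* (hybridisation followed by plastid introgression)
places a haplotype class, deeply divergent from the rest, inside a species.
Both processes make haplotypes non-private and erode the "barcoding gap" —
the separation between intra- and interspecific distance distributions —
that assignment methods rely on. `barcodegap` quantifies all of this per
genus and per locus combination, and ships a simulator that generates
exactly these pathologies with known ground truth.

Every analysis is run within one genus at a time, by construction: the API
takes a single genus' alignments. Non-coding spacers in particular cannot
be aligned reliably across genera, and pooling genera would mix
incommensurable distance scales.

## Haplotypes and single-step event coding

The unit of assignment is the *haplotype*: a distinct aligned sequence over
the loci of a combination. Two specimens share a haplotype when their
aligned sequences are identical at every locus of the combination; only
specimens sequenced at *all* loci of a combination enter it, so the sample
size `n_sequenced` legitimately varies between combinations under
sequencing dropout (a missing row means "no sequence", never "all gaps").

Indels carry real signal in spacers, so `code_alignment()` applies simple
indel coding: every maximal gap run with a distinct (start, end) pair
becomes one binary presence/absence character — a 10 bp deletion is one
mutation step, like a substitution. A gap run strictly nested inside a
longer gap of another specimen is *unobservable* for the specimen with the
longer gap and is scored missing rather than absent. Inversions cannot be
detected automatically from a gapped alignment; an annotation table turns
each annotated region into a single multistate character (its distinct
sequence variants) and masks those columns from substitution and indel
coding so no event is counted twice.

Two identity rules are offered for ambiguity codes (`ambiguity=`):

* `"strict"` (default): `N` is a distinct token, so sequences differing
  only at an `N` are *not* merged. Merging on compatibility is
  order-dependent in general; strictness is the reproducible choice.
* `"compatible"`: sequences agreeing wherever neither has `N` are merged,
  with the relation closed transitively (union–find), which removes the
  order dependence at the cost of occasionally chaining distinct
  haplotypes through an ambiguous intermediate.

A haplotype is *private* when all its carriers belong to one species;
`assignment_success()` reports the percentage of individuals carrying
private haplotypes, and `best_barcode()` ranks combinations by that
percentage, breaking ties toward fewer loci and then larger `n_sequenced`.
Adding a locus can only split haplotype classes, so on a fixed specimen set
assignment is monotone in the locus set; observed decreases after adding a
locus are always attributable to the shrinking specimen intersection, and
the test suite asserts exactly this decomposition.

## Distances and the barcoding gap

Pairwise divergences use the Kimura 2-parameter model,
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$, with transition and
transversion proportions computed over sites where neither sequence has a
gap or `N` (*pairwise deletion*, the common default of distance software;
complete deletion would discard most of an indel-rich spacer). Saturated
pairs, where a logarithm argument is non-positive, and pairs with no
comparable sites are *flagged undefined*, never silently zeroed; gap
diagnostics drop them with a logged count, and tree building refuses them
outright so the user decides between exclusion and imputation.

K2P sees substitutions only. That is a known limitation — indel-rich
spacers discriminate better than their K2P distances suggest — and it is
deliberate: the distance-based diagnostics describe what a standard
K2P-based workflow would see, while the haplotype/assignment layer gives
indels full single-step weight.

For each species the gap diagnostic compares its maximum intraspecific
distance against its nearest-neighbour distance, defined as the minimum
over other species of the *mean* interspecific distance; the gap is present
when the nearest neighbour is farther. Species with one specimen have no
intraspecific distance: their maximum is reported as undefined, not 0, and
the gap verdict is undefined. Pooled intra/inter distributions are binned
at 0.001 substitutions/site by default (`bin_width=`), fine enough to
resolve single-step differences at typical locus lengths.

## Trees, bootstrap and monophyly

`nj_tree()` implements Saitou–Nei neighbour joining on the Q criterion.
Two numerical conventions are fixed so results are exactly reproducible:
ties in the Q minimisation are broken by the lowest (row, column) index
pair in the current node order, and a negative estimated branch length is
clamped to zero with the deficit transferred to its sister branch, which
preserves the path length through the joined pair. On additive matrices
the algorithm recovers topology and all path lengths to numerical
precision (asserted against a generate-tree/round-trip oracle, with
`ape::nj` as an independent topology cross-check).

The bootstrap (default 100 replicates, seeded) resamples nucleotide
alignment columns with replacement; coded indel characters are not
resampled because the tree is built from K2P, which ignores them.
Replicates whose resampled matrix contains undefined distances are redrawn
up to 10 times, then counted as supporting nothing and logged. Support is
the percentage of replicates containing each original bipartition; on an
invariant alignment supports are reported undefined with a warning rather
than fabricating 100s.

Species monophyly is tested rooting-free: a species is monophyletic when
some edge bipartition of the unrooted tree separates exactly its specimens
from the rest. Midpoint rooting is used only to produce the human-readable
intruder list (foreign specimens inside the smallest clade spanning the
species); single-specimen species are trivially monophyletic and flagged
as such.

## Median-joining networks

`mj_network()` implements the Bandelt–Forster–Röhl construction over the
coded characters, all equally weighted: iteratively build the
epsilon-relaxed minimum spanning network (at the default epsilon = 0, the
union of all minimum spanning trees), add for every connected node triple
its quasi-medians (per character the majority state; where no majority
exists every observed state is a resolution and all combinations are
enumerated), and finally discard median vectors lying on no shortest path
between observed haplotypes, iterating to a fixpoint. Published
descriptions leave tie handling among equal-weight medians open; exhaustive
enumeration with a hard cap (`max_nodes = 10000`, a clear error rather than
a silent truncation) is this package's rule. Edges record their step counts
split into substitution, indel and structural steps so a plotting layer can
render the conventional full-line/double-line distinction; node records
carry member counts for frequency-proportional symbols. Correctness is
asserted against a brute-force quasi-median-closure oracle on small cases
and an MST-containment property on larger random sets.

## Rarefaction and correlations

Sequence richness uses frequency-aware rarefaction:
$R_s = \sum_k [1 - \binom{N-N_k}{g}/\binom{N}{g}]$, the expected number of
distinct haplotypes in a subsample of $g$ individuals. The default
$g = 3$ reflects the sampling depth at which many reference libraries
operate. Binomials are evaluated through `lchoose`, which is exact to
double precision at these scales and well-defined ($\binom{a}{b}=0$ for
$a<b$); the closed form is asserted equal to exhaustive subset enumeration
for every frequency partition up to $N = 12$. A direct consequence worth
knowing: whenever any haplotype has two or more carriers, $R_s(3) < 3$ —
three individuals essentially never exhaust a variable species.

Sampling-size correlations report the Pearson coefficient with Fisher
r-to-z intervals, $\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$.
Because conventions differ between tools, both two-tailed (default) and
one-tailed normal-theory probabilities are reported. The transform needs
$n \ge 4$; genera with fewer species yield a flagged undefined result
rather than an error, and perfect correlations return the degenerate
interval $[r, r]$ with a floor probability instead of an infinite z.

## The simulator: what it emulates, and what it does not

`simulate_genus()` evolves haplotypes along a user-given species tree under
an *infinite-sites* model: every substitution hits a previously untouched
alignment column and every indel is carved from a fresh region (geometric
lengths, mean 3 bp, with a one-column spacer so each gap run keeps its
exact boundaries). Counts per branch are `round(rate × length × branch)`
by default (`counts = "exact"`) so every designed step count is a
deterministic function of the configuration; a Poisson mode adds count
noise. The transition:transversion ratio is fixed at 2:1, keeping the data
inside K2P's model class. Sharing is injected by explicit events rather
than coalescent machinery, because the claims under test concern the
resulting *patterns*:

* `ils_events` give both named species carriers of their ancestor's
  haplotype;
* `capture_events` insert into the recipient a haplotype exactly
  `steps` mutations from the recipient's modal haplotype, constructed
  through the donor's modal haplotype (donor modal plus the difference
  between `steps` and the donor–recipient distance), so the captured class
  is simultaneously deeply divergent within the recipient and close to the
  donor — the chloroplast-capture signature. A `steps` value below the
  donor–recipient distance is a configuration error;
* `sharing_events` place a near-root haplotype into arbitrary species;
* `variants` add within-species classes at fixed step distances;
* `dropout` removes per-locus rows with a given probability.

Because each event occupies fresh columns, designed pairwise step counts
equal observed coded-character Hamming distances exactly, and designed
private fractions equal measured assignment success — both asserted across
seeds. Indels are realised as deletion events only; under infinite sites an
insertion would merely relabel columns, and between-locus length contrasts
are configured directly. What the simulator does *not* reproduce: rate
heterogeneity and homoplasy (multiple hits), back-mutation, alignment
error, base-composition bias, and coalescent stochasticity of sharing
fractions. Green tests therefore certify the pipeline's bookkeeping and
algorithms, not robustness of biological conclusions to misalignment or
model violations on real data.

The four presets are genus archetypes: `lonicera_like` (deep divergence,
private variation only — the one scenario where everything works: gap,
complete assignment, full monophyly), `salix_like` (a shallow star tree
with three haplotypes shared by all four species and 10 of 69 specimens —
14.5% — on private sequences), `gentiana_like` (capture placing two
classes exactly 63 steps apart inside the recipient, the captured class one
step from the donor), and `acer_like` (both sister pairs sharing their
ancestral haplotype while the outgroup species stays discriminated).
Specimen numbers (67, 69, 135, 103) and locus lengths follow the scale of
genus-level barcoding studies of this kind.

## Numerical and testing choices

Distance matrices for all pairs are computed via indicator-matrix
crossproducts (four 0/1 matrices give match, transition and comparable-site
counts for every pair at once), so bootstrapping hundreds of replicates on
a 135-specimen genus stays cheap. Site percentages are computed against the
full aligned length by default (`site_denominator = "all"`), matching how
such tables are conventionally reported against aligned length; an
`"ungapped"` dialect is available since tools differ on whether
gap-containing columns count. Reported percentages should be rounded to
one decimal, as the CLI does; the API returns full precision.

Test problem sizes were chosen to exercise each oracle thoroughly while
keeping the default suite quick on a laptop: 100 random additive matrices
(up to 8 leaves) for NJ; every frequency partition to N = 12 for
rarefaction; every 3-row gap configuration to length 5 plus 400 random
longer ones for indel coding; 40 quasi-median-closure and 50
MST-containment cases for networks; 20 simulator seeds for the
monotonicity and end-to-end scenario recoveries.

## Known limitations

* K2P distances ignore coded indels by design; the optional
  indel-inclusive view lives in the haplotype/network layer, not in the
  distance metric.
* Automatic indel coding can differ from a careful manual coding of
  complex overlapping gaps or inversions; the annotation mechanism exists
  precisely to override it.
* Median-joining enumeration can explode on many-state characters with
  heavy missingness; the node cap fails loudly and star-contraction-style
  preprocessing is left to the user (collapse near-identical haplotypes
  first).
* The monophyly intruder list depends on midpoint rooting and is
  descriptive only; the monophyly verdict itself is rooting-free.
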