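---
title: "Deconvolving a host–symbiont co-assembly and tracing gene provenance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving a host-symbiont co-assembly and tracing gene provenance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(symbiophylo)
library(dplyr)
tax <- toy_taxonomy()
```

Algal cultures are rarely axenic. When a strain that has hosted a
bacterial commensal for decades is shotgun-sequenced, the assembly is a
simple two-organism metagenome, and every downstream claim — genome size,
gene content, horizontal gene transfer (HGT) — depends on first deciding
which contig belongs to whom and where each gene came from. This
vignette describes the models and decision rules this package uses for
that analysis, the defaults and why they were chosen, and what the
synthetic benchmarks bundled with the package do and do not demonstrate.

## The taxonomy and LCA labelling

All classification operates over a user-supplied hierarchical category
system: leaf *sub-categories* (the units of the homology search, e.g.
individual diatom subgroups or bacterial orders) grouped under named
lineage nodes, supergroups and domains. `load_taxonomy()` validates the
tree (single root, consistent parents and depths) and the per-category
flags (diatom ⇒ stramenopile ⇒ eukaryote; alpha-proteobacterium ⇒
prokaryote; eukaryote and prokaryote mutually exclusive). Because the
"major lineage" of a category is not always its immediate parent (a
category that is its own lineage sits directly under a supergroup), the
flags column accepts an explicit `lineage=<node>` token; the default is
the leaf's parent.

The bundled toy taxonomy spans four diatom subgroups, two other
stramenopiles, three other eukaryote categories and four prokaryote
lineages. It carries two sub-categories in every lineage that the
generators can plant as an HGT donor (alpha-proteobacteria, chlorobi,
verrucomicrobia, haptophytes), because the first-two-hit rule below can
only resolve a lineage that contains at least two sub-categories. Real
analyses are expected to supply a much richer map (on the order of a
hundred or more sub-categories); nothing in the code depends on the toy
roster.

`lca()` returns the deepest node whose subtree contains all inputs,
computed by depth-aligned parent walking; the tests check it against an
independent path-intersection oracle on hundreds of random taxonomies.

## Binning: GC mixture + LCA consensus

The host and symbiont fractions differ markedly in GC content (medians
around 51% and 64% in the motivating system). Since per-read coverage is
not available at this stage, the separation model is deliberately
minimal: a two-component univariate normal mixture on per-contig GC,
fitted by EM.

Numerical choices: means initialized at the 25th/75th percentiles of the
data (which cannot miss a bimodal split and makes the fit fully
deterministic — there is no random restart), equal initial weights, a
common initial standard deviation of half the sample SD, convergence at
an absolute log-likelihood change below `1e-8`, component SDs floored at
`1e-6`, and components re-ordered by ascending mean after the fit so the
`low_gc`/`high_gc` labels never switch between runs. Identical inputs
are rejected as degenerate, and a fitted mean separation below 0.02
raises a "unimodal" warning rather than silently splitting one mode.
Contigs are assigned by posterior (≥ 0.5 for the high-GC component), and
a posterior within 0.1 of 0.5 marks the contig low-confidence; 0.1 is an
explicit, testable boundary, exposed as an argument. Contigs are
weighted equally rather than by length — length weighting would be easy
to add but changes nothing in well-separated mixtures and would make the
posterior harder to interpret per contig.

The second channel labels each contig with the LCA of its genes'
single best hits (best hit per gene, e-value at most `1e-5`). Using only
the best hit keeps the channel simple and symmetric with how the origin
classifier ranks evidence; multi-hit voting schemes were considered and
left out because they need additional tie-break policy without changing
the domain-level vote in practice.

The consensus is a small total function: agreement wins; a
domain-confident LCA (a label wholly within the eukaryote or wholly
within the prokaryote side) overrides a low-confidence GC call; a
confident GC call wins over an abstaining LCA; a confident conflict — or
no confident evidence at all — is `ambiguous`. Ambiguous contigs are
deliberately *kept* in the downstream provenance fraction: discarding
them would silently drop exactly the contigs (e.g. a contaminant contig
with host-like GC) that the contig-context filter exists to adjudicate.

## Origin classification from ranked hits

For each gene, hits are deduplicated to the best hit per sub-category
(lowest e-value, then highest bitscore, then lexicographic subject id —
a total order, so the result is invariant to input order) and ranked.
"Non-redundant" is interpreted per sub-category rather than per source
library, since the decision rule reads the sub-category identity of the
first two hits; the alternative would only matter for categories split
across libraries and is trivial to emulate by relabelling.

The call is then a function of the top two categories:

- two sub-categories of one lineage → that lineage (level `lineage` for
  eukaryotic lineages, `prokaryote-lineage` for prokaryotic ones, or
  `sub-category` when the pair coalesces strictly below the lineage
  node);
- a same-lineage pair outside the host (diatom) clade additionally flags
  the gene as an HGT candidate;
- diatom + non-diatom stramenopile → `stramenopile`; diatom (or other
  stramenopile) + other eukaryote → `eukaryote`;
- host + prokaryote pairs, and prokaryote pairs crossing lineages, stay
  `unresolved` at the shared ancestor. This is the conservative end of
  the ladder: a transfer is only ever called when the top evidence
  concentrates in a single non-host lineage.

Lineage-specific genes are those whose significant hits (e-value
strictly below `1e-5`; the strictness follows the rule's wording) all
fall inside a focal clade, with at least one such hit. Chimeric
"S-genes" are detected from positioned hits: single-linkage clustering
on > 50% reciprocal overlap of query ranges, same-call clusters bridged
across gaps of at most 10 residues, segments shorter than 50 residues
dropped, and a gene is chimeric when two confident segments coalesce
only at the root or a domain node (e.g. a verrucomicrobial N-terminus
against a diatom C-terminus). The 50%/50/10 values are detector
parameters, not biology; all three are exposed as arguments. In the
pipeline the chimera screen runs *before* whole-gene candidacy, because
a whole-gene call on a chimera is an artefact of whichever segment
happens to score better.

The contig-context filter retains an HGT candidate only when its contig
carries at least one other gene with a confident host-clade call —
a transfer into the host genome should be physically linked to host
sequence, whereas a contaminant contig has none.

## Tree-topology rules

Candidates are confirmed on single-gene trees. `sister_group()` reads
the sibling leaf set of the query in a rooted tree (a polytomous parent
contributes all non-query children, so unresolved nodes reject mixed
evidence rather than picking an arbitrary child) and the bootstrap label
on the query's parent split. `confirm_hgt()` requires every sister leaf
to match the predicted donor category and support strictly greater
than 50; a missing support annotation is treated as unsupported and
rejects, which is the conservative reading. Rooting, when needed, is on
the edge subtending the smallest bipartition side that contains all
outgroup leaves and excludes the query, with midpoint rooting (and a
warning) as the fallback; support labels stay attached to the edges they
describe.

The commensal screen uses the paraphyly rule: a query is of probable
alpha-proteobacterial origin when some edge of the unrooted tree
separates the query, at least one alpha-proteobacterial leaf and any
eukaryote leaves from *all* non-alpha prokaryote leaves. Eukaryote
leaves are allowed on the query side (the group is expected to be
paraphyletic precisely because eukaryote commensal sequences nest within
it); requiring their presence would be a stricter rule than the evidence
demands. A library is called positive when at least 2 markers of the
27-marker single-copy panel pass — one marker can be a mis-rooted or
contaminated tree, two independent markers rarely are.

## Supermatrix construction

Marker selection applies two strict thresholds to a status matrix:
presence (complete or fragmented) in more than 60% of taxa, and mean
copy number below 1.5. The mean is taken over *all* taxa, with missing
taxa contributing zero — "average copy number per species" most
naturally spans the sampled species; the present-only alternative is a
switch. Terminus trimming keeps the span between the first and last
column whose identity exceeds 0.70, where identity is the modal non-gap
residue frequency among non-gap residues and columns with fewer than two
residues never qualify (identity of a single residue is vacuous). Gap
trimming keeps columns with a non-gap fraction of at least the
threshold (boundary kept, matching the usual "minimum fraction without
gaps" semantics). Concatenation takes the taxon union, fills absent taxa
with gaps so the matrix stays rectangular, and records 1-based inclusive
partition bounds; the canonical three-marker check (1,616 + 1,473 +
1,132 = 4,221 positions) is in the tests.

## Domain repertoires

Presence/absence of each focal domain across reference genomes defines
the regions of a Venn diagram from the focal genome's point of view;
counts only enter the separate copy-threshold report (strictly more than
5 focal copies, absent everywhere else, by default). Term
over-representation uses the one-sided hypergeometric tail with
Benjamini–Hochberg adjustment — the minimal fully-specified choice for a
set-vs-background test; the tests verify it against exhaustive draw
enumeration for small backgrounds.

## The synthetic-data generators

Every stage has a seeded generator that plants ground truth:

- **Metagenome.** Contig GC is realized constructively — the G+C count
  of each contig is fixed at `round(gc * length)` and bases are shuffled
  — so the empirical GC equals the target up to integer rounding and the
  medians are exact by construction rather than by sampling luck.
  Defaults encode the study conditions: 500 + 500 contigs, GC medians
  0.51/0.64 with SDs 0.02/0.03, log-normal contig lengths (median 4 kb),
  and on average two genes tiled per contig without overlap.
- **Hit tables.** E-value exponents are drawn on the log scale, strictly
  decreasing, with planted hits always strictly better than optional
  noise hits; ties are never generated (tie-breaking is tested on
  hand-built fixtures instead, which keeps those tests independent of
  generator behaviour).
- **Gene trees.** Built by grafting the query (and its planted sister
  clade) onto a random scaffold, which *guarantees* the planted
  topology; a birth–death simulation would only reproduce it with some
  probability.
- **Marker matrices and alignments.** Pass/fail structure and conserved
  blocks are constructed to sit strictly on the correct side of each
  threshold, including exact-boundary failures (presence exactly 60%,
  mean copy exactly 1.5), so the strict inequalities are genuinely
  exercised.

One master seed fans out to per-generator child streams through a fixed
derivation, so stages can be re-run independently and all outputs are
byte-deterministic under a fixed seed.

## The end-to-end benchmark

`run_synthetic_pipeline()` plants host background genes of diatom
origin, symbiont background genes with *cross-lineage* prokaryote
affinities, eight transfers (donors spanning chlorobi,
alpha-proteobacteria, verrucomicrobia and a haptophyte; seven on
host contigs with diatom context, one without) and two chimeras, then
runs binning, classification, tree confirmation, the context filter and
the chimera screen, reporting the recovered counts.

Two generator choices deserve comment. Scenario genes are planted on
host contigs whose GC lies within 0.03 of the host median, so the
planted contigs bin deterministically under the study conditions and the
benchmark measures the provenance rules rather than tail luck in the GC
draw. And symbiont background genes are emulated with top hits scattered
across prokaryote lineages — realistic once self-library hits are
excluded, and it means a rare mis-binned symbiont contig contributes
`unresolved` calls rather than spurious transfer candidates. The
benchmark therefore demonstrates *rule correctness and bookkeeping*, not
robustness to adversarial noise: real hit tables have ties, truncated
alignments, and genuinely ambiguous candidates that no synthetic default
reproduces.

Problem sizes used by the tests and the acceptance script — 1,000
contigs, 200 random taxonomies × 20 LCA queries, 500 simulated gene
trees, 200 random alignments, 20 screened libraries — were chosen so the
full suite runs comfortably on a laptop while keeping every rule's
boundary cases (support 50 vs 51, presence exactly 60%, e-value exactly
at threshold) explicitly covered.

## Known limitations

- Coverage-aware and k-mer-composition binning are out of scope; the
  mixture model needs a genuine GC difference between the organisms.
- The classifier trusts the category assignment of each subject
  sequence; mislabelled reference libraries propagate directly.
- The chimera detector segments by hit coordinates only; it cannot see a
  chimera whose segments are covered by a single full-length hit.
- Tree rules consume trees with supports; they do not assess alignment
  quality or infer trees.

```{r example}
res <- run_synthetic_pipeline(seed = 1)
res$counts
```
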