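---
title: "Methods: annotating co-occurrence networks with metabolic interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating co-occurrence networks with metabolic interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossnet)
```

# Scope and model

`crossnet` predicts, for every pair of genomes mapped onto a microbial
co-occurrence network, two independent lines of evidence for metabolic
interaction and attaches them to the network as directed
donor-to-beneficiary edges. Both predictions are *potentials*, not observed
fluxes: they state what the gene/reaction content of the genomes would
permit, under the assumptions spelled out below.

## Module grammar and alternatives

A KEGG module `DEFINITION` is a boolean expression over KO (KEGG Orthology)
terms. The grammar implemented by `parse_module_definition()`:

* space-separated **steps** at the top level are ANDed;
* inside any parenthesized expression, the comma (OR over **options**) has
  the *lowest* precedence, then the space (AND), then `+`/`-`;
* `+` joins subunits of a complex (AND);
* a leading `-` marks an optional subunit — optional KOs are excluded from
  alternatives entirely, since their absence never blocks completion;
* the token `--` is a gap step, satisfied by any genome and contributing no
  KOs.

An **alternative** is the KO set obtained by realizing every step in
exactly one way; `enumerate_alternatives()` expands the full cross-product
of per-step realizations and de-duplicates identical KO sets. The shipped
snapshot of the two glycolysis modules is the arithmetic sanity check: the
core module enumerates to $1\cdot3\cdot4\cdot1\cdot2 = 24$ alternatives and
the full module to $7\cdot4\cdot4\cdot5\cdot1\cdot3\cdot4\cdot1\cdot2 =
13{,}440$, and removing the animal-specific pyruvate kinase K12406 halves
the core module's count to 12.

```{r}
defs <- read_module_definitions(
  system.file("extdata", "kegg_modules_snapshot.tsv", package = "crossnet"))
length(enumerate_alternatives(defs[["M00002"]]))
```

Enumeration is capped (default `cap = 50000`) with a *projected* count
computed before expansion, so pathological definitions fail fast instead of
exhausting memory.

## Pathway complementarity

Genome B complements genome A on a module when, for some alternative with
KO set $S$, the missing set $M = S \setminus \mathrm{KOs}(A)$ satisfies
$M \neq \emptyset$ and $M \subseteq \mathrm{KOs}(B)$. Modules already
complete in A are skipped. Assumptions and consequences:

* Completion-in-trans is a *potential*: gene transfer or metabolite
  exchange is plausible but not demonstrated.
* Every incomplete alternative is reported (one row per alternative per
  pair); `unique_complements()` de-duplicates on (module, missing-KO set)
  and counts multiplicity, `minimal_complements()` drops strict supersets,
  and `max_missing` bounds the donated-set size (complements needing many
  KOs are biologically less plausible).

## Seed sets

Each genome's metabolic network becomes a compound digraph: one edge
substrate → product for every (substrate, product) pair of every reaction,
both directions if the reaction is reversible; self-loops are dropped and
parallel edges collapsed. The **seed set** is the union of the strongly
connected components (SCCs) with zero in-degree in the condensation DAG —
compounds the network cannot synthesize from anything else and must acquire
exogenously. Each seed carries a confidence $C = 1/|SCC|$.

*Design decision:* the confidence is attached per-compound with per-SCC
normalization (each source SCC contributes total weight 1). Members of a
large interdependent source component are individually weaker evidence of
an external requirement — any one member being available renders the rest
reachable.

Assumptions: the reaction list is complete and reversibility annotations
are correct; transport, compartments and cofactor ubiquity are not
modeled beyond a configurable compartment-suffix strip
(`_[a-z][0-9]*$`) and pseudo-reaction drop (`^(bio|EX_|DM_|SK_)`).

## Interaction indices

For beneficiary A and donor B:

$$\mathrm{MI}_{\mathrm{compl}}(A,B) =
  \frac{|\mathrm{Seeds}_A \cap \mathrm{NonSeeds}_B|}{|\mathrm{Seeds}_A|},
\qquad
\mathrm{MI}_{\mathrm{compet}}(A,B) =
  \frac{\sum_{c \in \mathrm{Seeds}_A \cap \mathrm{Seeds}_B} C_A(c)}
       {\sum_{c \in \mathrm{Seeds}_A} C_A(c)}.$$

*Design decision:* competition is weighted by the **beneficiary's**
confidences on both numerator and denominator, making the index a proper
fraction in $[0,1]$ with the exact identities
$\mathrm{MI}_{\mathrm{compl}}(A,A)=0$ and
$\mathrm{MI}_{\mathrm{compet}}(A,A)=1$ (enforced by the acceptance tests).
Both indices compare *identifiers*, so the two networks must share a
compound namespace. Seed-complement *listings* (which compounds could be
cross-fed) are additionally restricted to compounds translatable to KEGG
ids and linked to at least one module — an interpretability whitelist that
deliberately does not affect the indices.

## Taxon-to-genome mapping

Network nodes are mapped to genomes by exact normalized-lineage match
first, then fuzzy matching on the deepest lineage field with the
normalized Levenshtein ratio

$$\mathrm{sim}(a,b) = 100\left(1 - \frac{d(a,b)}{\max(|a|,|b|)}\right),$$

case-insensitive, accepted at `threshold = 90` (default). *Design
decisions:* the ratio normalizes by the longer string so the score is
symmetric and bounded; threshold 90 tolerates roughly one edit per ten
characters — enough for orthographic variants, tight enough to avoid
congeneric species collisions. Ties are broken to the lexicographically
smallest candidate, with a message. Mapping is gated at species/strain
level: coarser taxa would make genome-level metabolic claims meaningless.

## Cluster–trait enrichment

For each (cluster, trait) cell with background size $N$, trait-positive
background $K$, cluster size $n$ and trait-positive cluster count $k$, the
enrichment p-value is the upper hypergeometric tail $P[X \ge k]$ and the
depletion p-value the lower tail $P[X \le k]$. Unknown (`NA`) trait values
are excluded per-test; all-negative traits are skipped with a message
(their tests would be powerless). All cluster × trait × direction tests
form **one** Benjamini–Hochberg family — controlling FDR jointly rather
than per-trait is the conservative choice when clusters and traits are both
numerous.

# Synthetic generators: realism and limits

All fixtures are generated with planted ground truth and one explicitly
seeded Mersenne–Twister stream per call (the caller's RNG state is saved
and restored):

* `gen_module_definition()` uses globally unique KOs, so the planted
  alternative count is exactly the product of per-step realization counts.
  Real modules share KOs across steps; the generator trades that realism
  for an exactly checkable count (set-equality against an exhaustive
  oracle covers the shared-KO logic separately).
* `gen_genome_pair()` plants a complement of known size `k_missing` and
  draws donor decoys from a disjoint identifier range (K7xxxx vs K9xxxx),
  so recovery is exact by construction.
* `gen_metabolic_network()` builds each SCC as a reversible chain or an
  irreversible cycle and wires SCCs along a user-specified or random DAG;
  planted seeds are the source-SCC members at confidence 1/size. Real
  compound graphs have heavy-tailed degree distributions and currency
  metabolites; the generator targets topological correctness, not
  biochemical realism.
* `gen_annotated_community()` plants one enriched trait
  (`trait_effect = 0.8` inside the first cluster vs `background_prob =
  0.2` elsewhere); with both probabilities equal it is an exact null.

# Numerical choices and problem sizes

* Hypergeometric tails are computed by `stats::phyper` (log-space stable);
  the tests cross-check every configuration with $N \le 25$ against
  explicit `choose()` sums.
* BH adjustment wraps `stats::p.adjust(method = "BH")` behind input
  validation.
* Levenshtein distances come from `utils::adist`; the test oracle is an
  independent dynamic-programming implementation.
* Graph algorithms (SCCs, condensation, reachability, GraphML I/O) use
  `igraph`; the SCC test oracle is a matrix-power mutual-reachability
  partition.
* Acceptance-scale problem sizes: 200 seeded definitions (≤ 10,000
  alternatives each), 500 planted genome pairs, 100 planted networks of up
  to 200 compounds, and 100 enrichment replicates each for null
  calibration (false-positive rate ≤ 5% plus three-sigma Monte Carlo
  slack) and power (≥ 90% at `trait_effect = 0.8`).

# End-to-end run

```{r}
dir <- tempfile()
write_fixture_dir(dir, seed = 1L)
ann <- run_annotation_pipeline(
  network_path      = file.path(dir, "network.tsv"),
  nodes_path        = file.path(dir, "nodes.tsv"),
  genome_index_path = file.path(dir, "genome_index.tsv"),
  ko_table_path     = file.path(dir, "genomes.tsv"),
  modules_path      = file.path(dir, "modules.tsv"),
  reactions_dir     = file.path(dir, "reactions"),
  mapping_path      = file.path(dir, "mapping.tsv"))
nrow(ann$edges)                   # co-occurrence edges, conserved
nrow(ann$complementarity_edges)   # directed donor -> beneficiary edges
```
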