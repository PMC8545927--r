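---
title: "Methods: phi-correlation disease networks, interactome backbones and miRNA hubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phi-correlation disease networks, interactome backbones and miRNA hubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
library(dplyr)
```

# The comorbidity model

A phenotypic disease network (PDN) treats diseases as nodes and strong
pairwise comorbidity correlations as links. For two diseases $i$ and $j$
observed in a population of $N$ patients, with prevalence counts $N_i$,
$N_j$ and co-occurrence count $N_{ij}$, the link weight is the
$\phi$-correlation

$$\phi_{ij} = \frac{N\,N_{ij} - N_i N_j}
  {\sqrt{N_i N_j (N - N_i)(N - N_j)}},$$

which is exactly the Pearson correlation of the two binary
disease-indicator vectors. The statistic is undefined when a disease is
absent from or universal in the population ($N_i \in \{0, N\}$);
`phi_correlation()` raises an explicit error rather than returning
`NaN`, because such codes carry no comorbidity information in that
stratum.

**Counting assumptions.** A patient contributes at most once to any
$N_i$ or $N_{ij}$ regardless of how many hospitalizations repeat a code
(`count_prevalences()` deduplicates per patient). Main and side
diagnoses are treated identically: once the claims schema is read, the
position of a code in the record carries no weight. Diabetes type is a
patient-level property derived from the union of a patient's codes via
the 5th digit of 250.xx (1/3 type 1, 0/2 type 2; precedence
T1D > T2D > other).

**Node granularity.** PDN nodes are ICD-9-CM codes truncated to a
configurable digit level (`node_level`), 3 digits by default. Published
PDN drawings never state the level used, so node/link counts of any
real-data PDN are not comparable across levels; the default is the
coarsest (disease-family) level, which is the most robust to coding
variation in claims data.

**Thresholding.** Candidate links are all unordered pairs with
$N_{ij} \ge 1$ and defined $\phi$. They are ranked by $\phi$ descending
and the top `threshold_fraction` (default 0.006, i.e. 0.6%) are kept:
$k = \lceil f \cdot n_{\text{cand}} \rceil$ links, *extended through ties*
at the cutoff value, plus their endpoint nodes. The candidate universe
and tie policy are genuinely open design points (the source analyses do
not define them); we chose the observed-pair universe because pairs never
co-observed have $\phi < 0$ only through their marginals and would inflate
the candidate count without ever being retained, and tie extension because
dropping an arbitrary subset of equal-$\phi$ links would make the network
depend on sort order. Raising the fraction never removes a previously
retained link (monotonicity), and every retained link has $\phi$ at least
that of every non-retained candidate; both properties are enforced by
tests.

**Categories.** Nodes map into 13 ICD-9 chapter categories
(001–139, 140–239, 240–279, 280–289, 290–319, 320–389, 390–459, 460–519,
520–579, 580–629, 680–709, 710–739, 740–759); codes from the pregnancy
(630–679), perinatal (760–779), symptoms (780–799) and injury/poisoning
(800–999) chapters plus E- and V-codes are excluded before profiling.
This boundary table is a reconstruction — the original category table was
published only as supplementary material we do not package — so edge
cases at chapter boundaries may differ from the original; the perinatal
chapter is excluded because it matches none of the 13 published category
themes.

**Comparing two PDNs.** `compare_profiles()` applies, per category, the
pooled-variance two-sample proportion z-test without continuity
correction (two-sided). "Two-sample proportion test" admits several
variants; the pooled z is the textbook default and its square equals the
uncorrected chi-square statistic, which the tests verify against
`prop.test()`. Categories empty in both profiles have an undefined
statistic and are flagged rather than dropped. No multiple-testing
correction is applied by default (per-category significance is reported,
matching how such comparisons are usually published); a Bonferroni option
exists via `adjust = "bonferroni"`.

# The synthetic cohort generator

`simulate_claims()` emulates hospitalization claims: per-patient
demographics, a diabetes-typing 250.xx code drawn from `dm_type_mix`,
independent Bernoulli background diseases, and *planted pairs* drawn
jointly from the 2×2 table implied by $(p_i, p_j, \phi)$:
$p_{11} = p_i p_j + \phi\sqrt{p_i(1-p_i)p_j(1-p_j)}$. Specs whose implied
joint probability violates the Fréchet bounds
$[\max(0, p_i+p_j-1), \min(p_i, p_j)]$ are rejected at validation time
with an error naming the pair. Dependence is pairwise only — the
$\phi$ statistic is pairwise, so higher-order comorbidity structure is
deliberately out of scope — and each disease may join at most one planted
pair.

Each patient's codes are assigned once at patient level and then split
uniformly across 1–3 claims of at most five diagnosis codes each, with
admission dates uniform over 2002–2008. The split is cosmetic realism:
downstream counting deduplicates per patient, so only the patient-level
disease sets matter. A single integer seed drives the whole draw through
a locally scoped RNG (`withr::local_seed`), so equal seeds give
byte-identical tables and the global RNG state is untouched.

**Default conditions.** The packaged demonstration cohort
(`default_cohort_spec()`) uses ~20 background diseases from chapters
common among diabetic comorbidities (anemia 285, hypertension 401,
vitreous/retinal 379/362, renal 585/403, atherosclerosis 440, ...) with
prevalences between 2% and 12%, two planted pairs at $\phi = 0.30$ and
$0.20$, a 50/50 sex ratio, age-band weights proportional to the packaged
inpatient counts per decade, and an all-T1D type mix. No published
magnitudes exist for pairwise comorbidity prevalences, so these defaults
are a documented free choice of plausible inpatient values; they are the
fixed study conditions of the test suite, not tuning knobs.

**What the generator does not emulate:** longitudinal disease
progression, age- or sex-dependent incidence, coding noise, and
higher-order dependence. Passing tests therefore demonstrate that the
pipeline recovers *pairwise* planted structure from schema-faithful
claims; they do not validate behavior under real-world coding artifacts.

At 50,000 patients the planted-$\phi$ recovery error is well below the
0.03 property bound used by the tests (the binomial standard error of
$\hat\phi$ at these prevalences is ≈ 0.006), and the suite checks the
4$\sqrt{p(1-p)/n}$ convergence band across ten seeds, requiring ≥ 9 hits.

# Graph metrics and the backbone

Centralities and global measures are computed with igraph under pinned
conventions, each of which changes the numbers if chosen otherwise:

* betweenness is normalized by $(n-1)(n-2)/2$ (undirected, endpoints
  excluded), putting it on the $[0,1]$ scale of the published backbone
  table;
* closeness is the strict $(n-1)/\sum_u d(v,u)$, not the harmonic
  variant;
* the average clustering coefficient includes degree-0/1 nodes as zeros
  (the common Gephi/networkx convention);
* graphs are made undirected and simple on load, with a message counting
  dropped self-loops and parallel edges.

The test suite validates these against an independent brute-force oracle
that enumerates *all simple paths* between every node pair on random
connected graphs of up to 8 nodes — 40 graphs per run in the acceptance
suite plus 30 in the unit suite — and against closed forms on stars,
paths and triangles. Centrality functions refuse disconnected input and
direct the user to `giant_component()` (ties between equal-size
components break toward the one containing the lexicographically
smallest node id, for determinism).

`extract_backbone()` keeps the top `backbone_fraction` (default 20%) of
nodes by betweenness — rank-based, $k = \lceil f n \rceil$, extended
through ties — with their induced edges; the result may legitimately be
disconnected. `classify_roles()` applies the same rank-with-ties
semantics to degree (hubs, default top 10%) and betweenness
(bottlenecks, default top 10%), expressed as value thresholds so results
are auditable ("DC ≥ 12" style). Roles are computed on whatever
population the records table holds — for published-style analyses that is
the giant component, not backbone-internal ranks, which is what makes a
10% rule on a 230-node component correspond to 23 nodes and a concrete
BC cutoff. Explicit value overrides (`hub_min_degree`,
`bottleneck_min_bc`) reproduce published cutoffs exactly.

**A documented discrepancy.** On the packaged 46-protein centrality
table with the published cutoffs (DC ≥ 12, BC ≥ 0.0344), the stated rule
classifies 16 date-hubs: the 13 proteins listed as date-hubs in the
source *plus* CTNNB1 (DC 15), CREBBP (DC 14) and PTPN11 (DC 19), which
the source lists among "bottlenecks but not hubs" despite satisfying
DC ≥ 12 as printed. The package implements the stated rule and does not
guess the unstated exception; the fixture test asserts containment (all
13 listed date-hubs classify as date-hubs), not set equality.

# The bipartite protein–miRNA network

miRNA names arrive in mixed spellings (`miR-192-5p`, `mir-181a`,
`hsa-miR-155-5p`, and the evident typo `leg-7g-3p`).
`canonicalize_mirna()` case-folds, strips the `hsa-` prefix and applies
a packaged, editable alias table as family-prefix substitutions; only
`leg-7g → let-7g` is corrected by default. Unsuffixed names are *not*
merged with `-5p`/`-3p` arms — merging would silently change degree
counts — and `miR-34a-4p` (a possible typo for `-5p`, unknowable from
the printed table) is preserved verbatim. Canonicalization is idempotent,
which a property test checks on randomized spellings.

`intersect_mirna_sets()` keeps targeting edges whose miRNA belongs to
the disease-associated set and retains proteins with zero surviving
edges as isolated nodes (the packaged network contains one, AGT). Hubs
use strict "more than" thresholds: proteins with ≥ 11 miRNA partners,
miRNAs with ≥ 13 protein targets. On the packaged 243-edge network these
rules yield 6 hub proteins and 7 hub miRNAs, while the source text lists
7 and 8: CASP3 has exactly 10 partners and miR-23a-3p exactly 12 targets
as printed, so both sit one unit below their own stated rule. As with
the date-hubs, the package implements the stated rule and the tests
assert containment of the computed hubs in the published lists.

Pathway annotation (`annotate_pathways()`) is pure set intersection
against packaged membership lists (or user GMT files), upper-casing both
sides; no enrichment statistic is computed because the published result
is a membership count, not a p-value.

# Pipeline, problem sizes and limitations

`run_pipeline()` chains simulate → PDN per sex → category comparison and
fixtures → roles → bipartite hubs → pathway overlap, writing TSV/GraphML
outputs and a `manifest.json` with the configuration, seed, package
version and output checksums — the manifest suffices to re-execute the
run bit-identically. The demo configuration uses a 4,000-patient cohort;
the test suite uses 500–50,000 patients depending on what each property
needs (50,000 for $\phi$ recovery, where the Monte-Carlo error must sit
below the 0.03 band; ~1,000–3,000 for schema and bookkeeping checks).
These sizes were chosen so each check is decisively powered while the
whole suite runs in well under a minute.

Known limitations:

* real PDN node/link counts from nationwide claims, and giant-component
  or backbone link counts from a specific interaction-database export,
  cannot be reproduced without those restricted inputs — fixture
  regression, not recomputation, is the check for published centrality
  values;
* relative-risk comorbidity measures, temporal progression ordering and
  ICD-10 are out of scope;
* directed/weighted centralities and community detection behind the
  date-/party-hub metaphor are not implemented;
* pathway lists are static snapshots; no live database queries are made,
  by design, for reproducibility.
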