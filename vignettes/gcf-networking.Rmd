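---
title: "Gene cluster family networking: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene cluster family networking: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcfkit)
```

# The model

`gcfkit` groups biosynthetic gene clusters (BGCs) into gene cluster
families (GCFs) under the working assumption that clusters producing
similar metabolites share two signals: their backbone enzymes (NRPS, PKS,
DMAT and relatives) are homologous at the domain level, and their overall
protein-domain content overlaps. Both signals are combined into one
number per cluster pair:

$$ S(a,b) \;=\; w_{id}\, I(a,b) \;+\; w_{jac}\, J(a,b), \qquad
   w_{id} = 0.8,\; w_{jac} = 0.2 . $$

* $I(a,b)$ is the **median sequence identity of backbone enzyme
  domains**. For each backbone domain type present in both clusters
  (default whitelist: AMP-binding, Condensation, PCP/PP-binding, PKS\_KS,
  PKS\_AT, DMAT, TE — the core scaffold-building domains), copies are
  matched greedily by best pairwise identity, each copy used at most
  once; the median is taken over all matched pairs across types. If the
  clusters share no backbone type, $I = 0$.
* $J(a,b)$ is the **Jaccard similarity** of the deduplicated
  protein-domain sets, $|A \cap B| / |A \cup B|$, defined as 0 when both
  sets are empty.

Families are then the density-connected groups of the distance
$d = 1 - S$: DBSCAN with radius $\varepsilon = 0.55$ (equivalently, an
edge wherever $S \ge 0.45$) and minPts = 2. With minPts = 2 DBSCAN
degenerates, by construction, into the connected components of the
threshold graph, and that is intentional: a family is a subgraph of the
cluster network, and clusters with no neighbour are reported as
singletons rather than forced into a family. The identity-heavy
weighting means two clusters cannot enter the same family on shared
accessory domains alone ($J = 1, I = 0$ gives $S = 0.2$), while strong
backbone homology almost suffices ($I = 1, J = 0$ gives $S = 0.8$).

UPGMA dendrograms over the same distance visualise within- and
between-family structure. The implementation follows the textbook
recurrence — merge the closest pair, place the new node at half the merge
distance, update distances as size-weighted averages — with a
deterministic tie-break (lexicographically smallest leaf labels), so
output is reproducible byte for byte. `hclust(method = "average")` is
used as an independent cross-check in the test suite, never as the
implementation.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `wId`, `wJac` | 0.8, 0.2 | — | the defining weights of the combined score |
| `epsilon` | 0.55 | distance | family radius; score threshold 0.45 |
| `minMembers` | 2 | clusters | families are network subgraphs; 1-member groups are singletons |
| gap open / extend | 10 / 0.5 | score | BLOSUM62 affine scheme; a length-$L$ gap costs $10 + 0.5L$ |
| `modelAccession` | PF01231 | — | the IDO profile family |
| `minSubjectLength` | 350 | residues | full-length IDOs; fragments excluded |
| `maxEvalue` | 1e-30 | — | profile-hit stringency |
| `stachelhausPositions()` | 235…517 | GrsA numbering | canonical A-domain pocket positions |

Threshold conventions, chosen once and applied everywhere: *minimum* and
*maximum* are read inclusively (length ≥ 350, E ≤ 1e-30, score ≥ 0.45,
$d \le \varepsilon$), so stated boundary values sit inside the kept
region. "Subject sequence length" is the full protein length (the
HMMER `tlen` column), not the envelope length, and the E value used is
the full-sequence E value — both are the quantities hmmsearch reports
most prominently; borderline counts would change under the alternative
readings, which is why both choices are stated here and configurable in
`FilterPolicy`.

## Sequence identity: definition and alignment

Percent identity is **identical columns / total alignment columns of the
global alignment, end gaps included**. This penalises length mismatch
between backbone domains, which is what one wants when deciding whether
two adenylation domains are interchangeable parts of the same family.
Alignments are pairwise (Needleman–Wunsch via `Biostrings`), not taken
from a joint multiple alignment: pairwise alignment is deterministic,
testable against a brute-force dynamic-programming oracle, and on
backbone domains of realistic similarity the difference to MSA-derived
identity is small (third decimal); near heavy gaps it can shift
individual residues, which also bounds how exactly A-domain codes from
`extractCode()` can be expected to match codes read off a curated
multiple alignment.

When the two clusters carry different copy numbers of a domain type, the
greedy best-first matching is used rather than an optimal assignment:
it is order-independent for distinct identities, deterministic always,
and on small cases (checked exhaustively in the tests) coincides with
the best full matching whenever within-type copies are not nearly
interchangeable — and when they are, the median barely moves.

# Mass and isotope bookkeeping

Monoisotopic masses use a fixed element table (C = 12 exactly,
H = 1.0078250319, N = 14.0030740052, O = 15.9949146221, plus 13C and 2H).
`[M+H]+` defaults to the **H-atom convention** (add 1.0078250319 Da); the
electron-corrected proton convention (add 1.0072764666 Da) is selectable.
The H-atom convention is the default because it is the one that
reproduces, at four decimals, the printed calculated mass of the
C17H15N3O3 worked example (310.1192); the two conventions differ by
0.00055 Da and `ppmError()` is always reported against the package's own
stated convention.

Labelled-precursor scenarios are **explicit data, not inferred
chemistry**: each shipped scenario lists, per label, the element, heavy
isotope, atoms labelled and atoms retained, with a prose note giving the
biochemical reasoning (for ring-pentadeuterated tryptophan: IDO cleaves
the indole 2,3-bond, ring C2 becomes the N-formyl carbon of
N-formyl-kynurenine and is lost with its deuterium on deformylation, so
4 of 5 deuteria survive). The package computes nominal (= retained atom
count) and exact (= retained × isotope mass difference) shifts from that
map; it does not attempt atom-mapping through arbitrary transformations.

# What the synthetic generator emulates — and what it does not

`simulateFamilies()` builds families whose members are point-substituted
copies of a family archetype, which is itself a point-substituted copy of
a common root. Rates are solved from the targets: members mutate at
$1 - \sqrt{w}$ and archetypes at $1 - \sqrt{b/w}$, so member–member
identity is $w$ within a family and $b$ across families in expectation.
Domain sets are a per-family core (size 8) plus per-member private
domains plus a background shared by all clusters (the backbone type names
count toward it), with sizes solved from the within/between Jaccard
targets in expectation. Defaults — within identity 0.9, between 0.1,
within Jaccard 0.8, between 0.1, backbone architecture A-T-C-A-T-C-T
(the two-module NRPS with a terminal extra thiolation domain), backbone
domain lengths 300–600 residues — are the regime the scoring model
assumes: families share backbone sequence and domain content, singletons
share neither.

Deliberate simplifications, which bound what a passing test says about
real data:

* **no indel process** — members differ by substitutions only, so
  alignments of related sequences are gap-free and identity control is
  exact; real domains differ in length and gap placement interacts with
  the identity denominator;
* **uniform substitution, no rate heterogeneity or BLOSUM-biased
  exchanges** — realized identity is binomial around its target;
* **between-family Jaccard has a floor** of roughly
  $3/(3 + 2(k+p)) \approx 0.12$ from the shared backbone type names when
  the requested target is lower — realistic (all NRPS clusters share
  those annotations) and inside the separated regime used for recovery
  tests;
* **domain names are opaque tokens** — no domain-order or synteny signal
  exists to be exploited, matching the model, which ignores order too.

Under the default separated regime the pipeline must recover the planted
partition exactly (adjusted Rand index 1.0); that demonstrates
correctness of the scoring/clustering machinery, not that ε = 0.55
optimally separates real fungal GCFs — the radius is taken as given, not
tuned here.

`simulateHitTable()` plants rows that satisfy the filter policy and
decoys violating exactly one criterion each, including a true row exactly
at (350, 1e-30) and a decoy just past the E-value boundary
(1e-30 × 1.0000001), so the inclusive-threshold convention is exercised
from file, through parsing, to filtering.

# Numerical and degenerate-input choices

* The distance $1 - S$ is **not a metric** (triangle inequality can
  fail); DBSCAN and UPGMA therefore operate on the precomputed matrix
  only, never on embedded coordinates.
* Tie handling: UPGMA picks the lexicographically smallest label pair
  among minimal-distance candidates; greedy matching breaks identity
  ties by row/column index; both make reruns byte-identical.
* Degenerate inputs are defined, not errors: empty domain arrays
  (Jaccard 0 against everything), no shared backbone types (identity 0),
  both components absent (score 0), empty hit tables (empty filter
  result), single-member families (one-leaf Newick `label;`).
* Malformed inputs fail loudly with located messages (line numbers for
  domtblout rows, field names for manifest records, offsets for formula
  strings); readers never silently drop rows.
* Newick branch lengths are written with up to 10 significant digits,
  trimmed, so hand-checkable trees print exactly (`((A:0.1,B:0.1):0.25,C:0.35);`).

# Problem sizes used by the shipped tests

The test suite and worked examples run at desk scale, chosen to exercise
every code path while keeping a full run in minutes on one core: family
recovery on 2–5 families of 3–4 members (8–18 clusters, backbone domains
at the realistic 300–600 residue default) across three seeds; the
DBSCAN-versus-components equivalence on hundreds of random matrices with
up to 7 clusters; the alignment oracle on random pairs up to length 8;
hit tables of ~20 rows. Survey-scale numbers (thousands of genomes,
tens of thousands of clusters) require external genome data and are out
of scope by design.

# Known limitations

* Backbone identity from pairwise, not multiple, alignment (above).
* The greedy copy matching can differ from the optimal assignment when a
  cluster carries many near-identical copies of one domain type.
* No substrate prediction: A-domain codes and code identities are
  reported, the biological call ("binds anthranilate") is left to the
  analyst with reference codes at hand — the package ships reference
  *positions*, and the reference synthetase sequence is user-supplied.
* The IDO screen counts profile hits; it does not place hits into
  phylogenetic clades (that needs an ML tree, out of scope).
* Isotope bookkeeping covers single-isotopologue nominal/exact shifts;
  no fine-structure isotope pattern simulation, no mzML parsing.
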