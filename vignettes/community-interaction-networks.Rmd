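---
title: "Reduced interaction networks from community metabolic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced interaction networks from community metabolic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(communet)
```

## The problem and the model conventions

A community genome-scale metabolic model stitches several organisms'
reconstructions into one stoichiometric matrix. Each member keeps its own
compartments (cytosol, periplasm, ...), and all members meet in a single
shared external compartment through which metabolites are exchanged with
each other and with the environment. `communet` relies on two widely used
conventions for such models:

1. every member-owned metabolite and compartment ID carries the member ID
   as a prefix (`memberId_metaboliteId`, `memberId_compartmentId`), and
2. the shared external compartment is called `medium`, unless the SBML
   parameter `shared_compartment_id` names another compartment.

Transport reactions across the shared compartment boundary are assumed to
move a single metabolite. Reactions touching two or more shared-compartment
metabolites are excluded from the network with a warning rather than
rejected outright, so real-world models with a few stray reactions still
visualize; a reaction whose member-side metabolites belong to two
different members is a hard error, because its edge would be ambiguous.

Member inference deserves a note, because member IDs may themselves
contain underscores. For every non-shared compartment, each underscore is
a candidate boundary; candidates inconsistent with the compartment's
species IDs are discarded, the longest surviving candidate is taken, and a
final pass shortens a compartment's prefix only when a shorter candidate
is already another compartment's member ID. This keeps `m_x_c`/`m_y_c`
communities as members `m_x` and `m_y` while merging an oddly suffixed
`alpha_c_special` into an existing member `alpha`. When inference cannot
work (truly ambiguous naming), `member_override` bypasses it entirely.

The SBML reader itself is intentionally minimal — compartments, species,
reactions, stoichiometry, FBC flux bounds, parameters — which is all the
reduction needs. Bounds come from FBC parameter references; reactions
without resolvable bounds fall back to (−1000, 1000) with a warning, the
de-facto default of constraint-based models.

## Reduction

The reduced network is strictly bipartite: member nodes and external
metabolite nodes, one edge per member transport reaction. Two choices are
worth making explicit:

* **Boundary exchanges are node attributes, not edges.** A community
  boundary exchange (medium ↔ environment) has no member endpoint, so
  drawing it as an edge would break bipartiteness; it is recorded on the
  metabolite node (`has_boundary_exchange`, `boundary_reaction_ids`) and
  still counted in the summary's `n_reaction_records`, so both readings of
  "number of reactions in the reduced network" are checkable.
* **Parallel transporters stay parallel edges.** Flux files key on
  reaction IDs, so two transporters moving the same metabolite for the
  same member must remain distinguishable.

Hiding (inactive-edge dropping, the cross-feeding toggle) only ever edits
a `hidden` set; nodes and edges are never deleted, and summaries count the
full network.

## Layout

Nodes sit on four concentric circles, outermost to innermost: private
metabolites (member-degree 1), members, two-member metabolites, hubs
(member-degree ≥ 3). Defaults that the drawing depends on:

* radii (400, 280, 180, 90) arbitrary units — chosen so rings do not
  overlap at the default node sizes, overridable per call;
* members evenly spaced, the first member of the order at angle 0,
  counter-clockwise;
* private metabolites spread evenly in the angular sector of half-width
  π/m centred on their member;
* two-member metabolites at the mid-angle of the shorter arc between
  their members — for adjacent members that is the midpoint between them.
  Metabolites of non-adjacent pairs stay on circle 3 at their shorter-arc
  mid-angle rather than being demoted inward, preserving the
  degree-to-circle rule;
* hub metabolites evenly spaced on the innermost circle;
* a minimum angular separation of 2° per circle, enforced by
  deterministic nudging: nodes sharing a slot are spread symmetrically
  around it, then a sweep pushes later (by angle, then ID) nodes outward;
  an overcrowded circle falls back to even spacing.

The circular member order maximizes the number of two-member metabolites
whose members end up adjacent (the only nodes whose placement benefits).
Communities of up to 8 members are solved exactly by exhaustive search —
covering the sizes typically visualized — with a greedy heaviest-pair
insertion above that; ties break lexicographically, so the layout is fully
deterministic and seed-free. Positions are computed in a canonical frame
(lexicographically smallest member at angle 0) and globally rotated to the
requested order, which makes rotation equivariance exact by construction:
rotating the member order by k rotates every coordinate by 2πk/m.

Coordinates are mathematical (y up, angles counter-clockwise); exporters
that target screen conventions (`.cyjs`, SVG) flip y at write time.

## Flux contextualization

The sign convention doing the work everywhere is the *signed production
rate* `p = external_coefficient × flux`: positive means the member
releases the metabolite into the shared compartment, negative means
uptake, independently of the direction the reaction happens to be written
in. For flux ranges, the production interval is order-corrected
(`sort(c × min, c × max)`) so negative coefficients behave.

Classification against the zero-flux tolerance ε (default 1e−6 flux
units, the scale of LP solver noise; configurable):

| state | FBA (single flux) | FVA (range) |
|---|---|---|
| INACTIVE | \|p\| ≤ ε | whole range within ±ε |
| PRODUCTION | p > ε | p_min > ε |
| CONSUMPTION | p < −ε | p_max < −ε |
| BIDIRECTIONAL | — | range exceeds ε on both sides |

Classification is exhaustive and exclusive, and the FBA classification of
a flux vector equals the FVA classification of the degenerate range
(v, v). Inactive edges are hidden ("reactions without flux are dropped"),
and a metabolite whose edges are all hidden is hidden; members never are.
Reactions missing from a flux file are treated as inactive with a
warning; flux entries for unknown reactions are ignored with a warning.

Edge width is log-compressed by default —
`w = w_min + (w_max − w_min)·log10(1 + m/m_ref)/log10(1 + m_max/m_ref)`
with `m_ref` the smallest non-zero magnitude — because genome-scale flux
magnitudes span orders of magnitude and a linear map collapses most edges
to hairlines; a linear mode is available. Widths are strictly monotone in
magnitude with `w(0) = w_min`, `w(m_max) = w_max`.

## Cross-feeding and bidirectionality

A metabolite is cross-fed when at least one member produces it and a
*different* member consumes it; more than two members may take part, and
whether the metabolite also enters or leaves the community through the
boundary is irrelevant. The two modes differ in what "produces" means:
FBA mode uses the realized state (PRODUCTION/CONSUMPTION edges of the
given flux vector), FVA mode uses feasibility (could produce:
p_max > ε; could consume: p_min < −ε). Detection is equivariant under
member relabelling and is checked in the tests against a brute-force
member × metabolite signed-production oracle.

The cross-feeding toggle hides all metabolites that are not cross-fed
(with their edges) and, on cross-fed metabolites, edges whose member is
neither producer nor consumer. It snapshots the visibility state, so the
second call restores it exactly — an involution, matching its use as a
toggle in interactive viewers.

`bidirectionalityStats()` partitions member transports by whether their
metabolite is cross-fed and counts BIDIRECTIONAL classifications in each
group. The association test is a two-sided Fisher exact test on the
resulting 2×2 table — a natural choice for small count tables; the tests
verify its p-value against an independent hypergeometric enumeration.
Because it is genuinely ambiguous whether boundary exchanges count as
"external reactions", the result reports both denominators (member
transports only, and including boundary exchanges).

## Export and rendering

GraphML and Cytoscape JSON writers emit every node/edge attribute, sort
elements by ID and format numbers at 15 significant digits, so output is
byte-identical across runs — network files are research artifacts and
should diff cleanly. Arrow orientation is derived from the direction
class (production: member → metabolite; consumption: the reverse;
bidirectional: both) and enforced by the `StyledNetwork` validity method.
The SVG renderer writes plain deterministic text (one `<line>` per
visible edge, one `<circle>` per visible node, `<polygon>` arrowheads);
PNG re-draws the same primitives through the `png()` device at 300 dpi
equivalent. Members are drawn at 3× the metabolite diameter and always
labelled; metabolite labels appear only when at most 50 metabolites are
visible, a declutter rule for larger communities.

## The fixture generator

`generateToyCommunity()` emulates exactly the conventions above: one
internal compartment per member, a `medium` compartment, a reversible
single-metabolite transfer per member/metabolite incidence, one boundary
exchange per external metabolite, and an internal source/sink pseudo
reaction making every transfer feasible. Internal feasibility via
pseudo-reactions rather than realistic metabolism is deliberate: the
package visualizes states, it does not simulate them, so thermodynamic or
pathway realism would add nothing testable. Topology is a deterministic
function of the counts (members m, private p, pairwise q, core c), giving
closed-formula ground truth: `m·p + C(m,2)·q + c` metabolite nodes and
`m·p + 2·C(m,2)·q + m·c` edges. The seed only chooses planted
producers/consumers and flux magnitudes.

Planted FBA states balance mass exactly: for each shared metabolite one
producer secretes precisely what the planted consumers take up, so its
boundary exchange carries zero flux, while private metabolites drain to or
from the environment. Planted FVA states make a configurable fraction of
member transfers straddle zero (default 0.5, rounded to a whole count),
split the rest between production-only, consumption-only and inactive
ranges, and give boundary exchanges a symmetric range.

What passing tests on these fixtures shows — and does not. The fixtures
cover the conventions, the reduction/layout/classification logic and the
statistics on networks whose ground truth is enumerable. They do not
emulate genome-scale models (hundreds of exchanged metabolites, messy ID
schemes, solver noise near bounds), so conclusions about performance or
about ε-robustness on real FVA output need real models; the pipeline
consumes any convention-conforming SBML + TSV pair unchanged.

## Problem sizes and numerical choices

The test suite runs a matrix of roughly a hundred seeded fixture
communities (2–6 members, up to 3 private and 2 pairwise metabolites per
member/pair plus community-wide core metabolites) — small enough to
enumerate exhaustively, large enough to exercise every circle, class and
partition. The acceptance script uses a four-member community (6 private,
2 pairwise, 3 core), the scale of the communities typically visualized.
Tolerances: layout radius and export round-trips are checked at 1e−9;
mass balance of planted states at 1e−9; the exact-test oracle at 1e−9; ε
defaults to 1e−6 flux units. Degenerate inputs are defined behaviour:
a single-member community layouts on its own (full-circle sector), an
empty interaction network summarizes to zeros, an FVA table may be empty,
and an all-zero magnitude set maps every width to `w_min`.

## Known limitations

* The SBML reader targets Level 3 (+FBC) community models following the
  prefix conventions; it is not a general SBML validator, and Level 2
  dialects that encode members as compartments are unsupported.
* Member inference is heuristic for pathological naming schemes; use
  `member_override` when IDs are ambiguous.
* FBA/FVA solutions are inputs, not products, of this package.
* Very large communities (tens of members, hundreds of exchanged
  metabolites) will produce readable files but cluttered figures; the
  label declutter rule helps, coarse-graining is out of scope.
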