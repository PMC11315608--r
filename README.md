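# communet

Community genome-scale metabolic models merge several organisms'
reconstructions into one stoichiometric model, each member in its own
compartments, all of them exchanging metabolites through a shared external
compartment (conventionally `medium`). Such models easily reach thousands
of metabolites and reactions, which makes the one thing they exist for —
the *interactions* between members — invisible in a whole-network drawing.

`communet` reduces a compartmentalized community model (SBML Level 3 with
FBC, PyCoMo-style `memberId_` prefixes on metabolite and compartment IDs)
to its interaction essence and prepares it for publication:

* **Reduction** — a bipartite graph with one node per community member,
  one node per external metabolite some member transports, and one edge
  per single-metabolite transport reaction; community boundary exchanges
  are kept as metabolite-node attributes.
* **Layout** — four concentric circles: private metabolites (member-degree
  1) outermost, members evenly spaced on circle 2, two-member metabolites
  on circle 3 at the mid-angle of their member pair (the circular member
  order is chosen to make such pairs adjacent), hub metabolites
  (member-degree ≥ 3) innermost.
* **Contextualization** — an FBA flux vector or FVA flux ranges classify
  every edge: with signed production `p = coefficient × flux`,
  `|p| ≤ ε` is INACTIVE (dropped from the drawing), `p > ε` PRODUCTION,
  `p < −ε` CONSUMPTION; a production range straddling zero beyond ε is
  BIDIRECTIONAL. Edge widths scale log-compressed with flux magnitude.
* **Cross-feeding** — a metabolite is cross-fed when some member produces
  it and a *different* member takes it up (more than two members may take
  part; presence in the medium is irrelevant). A toggle hides everything
  not involved in cross-feeding and restores it on the second call.
  `bidirectionalityStats()` compares the fraction of bidirectional
  transports on cross-fed vs other metabolites with a two-sided Fisher
  exact test.
* **Export** — deterministic GraphML and Cytoscape JSON (`.cyjs`) with
  positions and styles, plus SVG/PNG figures; a `communet` command-line
  script (`inst/scripts/communet`) wraps the pipeline.
* **Fixtures** — a seeded generator of toy community models (SBML + flux
  TSVs + ground-truth records), so the whole pipeline is testable offline.

Computing FBA/FVA solutions is out of scope: fluxes are consumed as TSV
(`reaction_id`/`flux`, or `reaction_id`/`min_flux`/`max_flux`). A typical
recipe for producing them: maximize community growth, fix ≥ 90 % of the
optimum, then minimize/maximize each exchange reaction (FVA) with any
constraint-based modelling toolbox.

## Worked example

```r
library(communet)

dir <- tempfile()
spec <- fixtureSpec(n_members = 4, n_private = 6, n_pair = 2, n_core = 3,
                    seed = 1)
fx    <- generateToyCommunity(spec, dir)
model <- readCommunitySBML(fx$sbml_path)
model
#> CommunityModel 'toy_community_4m'
#>   members (4): alpha, beta, delta, gamma
#>   shared compartment: medium
#>   99 species, 159 reactions, 5 compartments

transports <- collectTransportReactions(model)
network    <- buildReducedNetwork(model, transports)
network
#> ReducedNetwork: 4 members, 39 metabolites, 60 edges
#>   boundary exchange reactions: 39
#>   hidden elements: 0

fva    <- generateFluxState(spec, fx$ground_truth, "FVA", dir)
ranges <- readFVATSV(fva$path)
ctx    <- classifyEdgesFVA(network, transports, ranges)
table(ctx$direction_class)
#> BIDIRECTIONAL   CONSUMPTION      INACTIVE    PRODUCTION
#>            30            13             3            14

network <- applyEdgeContexts(network, ctx)   # drop inactive edges
report  <- detectCrossFeeding(network, ctx)  # feasible cross-feeding
sum(report$cross_fed)
#> [1] 14

stats <- bidirectionalityStats(transports, ranges, report)
stats$fraction_bidirectional_crossfed
#> [1] 0.4705882
stats$p_value
#> [1] 0.7947745

network <- toggleCrossFeeding(network, report)
doc <- styleNetwork(network, computePositions(network), ctx)
writeGraphML(doc, file.path(dir, "network.graphml"))
writeCyjs(doc, file.path(dir, "network.cyjs"))
renderFigure(doc, file.path(dir, "network.svg"), format = "svg")
```

The 4 members, 39 metabolites and 60 edges match the generator's closed
formulas (4·6 private + 6·2 pairwise + 3 core metabolites; one edge per
member/metabolite incidence). The direction-class table reflects the
planted FVA state (half the member transports straddle zero), and the
Fisher test compares bidirectionality between transports of cross-fed and
other metabolites.

The same pipeline from a shell:

```sh
communet simulate --n-members 4 --private 6 --pair 2 --core 3 --seed 1 \
    --fva --out-dir fx
communet run --model fx/toy_community_m4_s1.xml --fva fx/fva_m4_s1.tsv \
    --crossfeed --out net.graphml --figure net.svg
```

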