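test_that("signed production follows the coefficient-times-flux convention", {
  expect_equal(signedProduction(+1, 2.5), 2.5)
  expect_equal(signedProduction(-1, 2.5), -2.5)
  expect_equal(signedProduction(+2, -3), -6)
})

test_that("FBA classification matches planted labels and hides zero flux", {
  b <- makeFixtureBundle(4, 2, 1, 1, seed = 41)
  st <- generateFluxState(b$spec, b$fx$ground_truth, "FBA", b$dir)
  fluxes <- readFluxTSV(st$path)
  ctx <- classifyEdgesFBA(b$network, b$transports, fluxes)
  planted <- st$ground_truth$planted_classes
  expect_identical(ctx$direction_class, unname(planted[ctx$edge_id]))
  expect_true(all(c("PRODUCTION", "CONSUMPTION") %in% ctx$direction_class))
  # inactive edges (|p| <= eps) end up hidden, their metabolites too when
  # fully inactive; member nodes never hide
  net <- applyEdgeContexts(b$network, ctx)
  inactive <- ctx$edge_id[ctx$direction_class == "INACTIVE"]
  expect_true(all(inactive %in% hiddenIds(net)))
  expect_false(any(memberNodes(net)$node_id %in% hiddenIds(net)))
  ed <- networkEdges(net)
  for (nid in metaboliteNodes(net)$node_id) {
    if (all(ed$edge_id[ed$metabolite_node == nid] %in% hiddenIds(net))) {
      expect_true(nid %in% hiddenIds(net))
    }
  }
})

test_that("edges absent from the flux vector are inactive with a warning,
           stray flux IDs are ignored with a warning", {
  b <- makeFixtureBundle(2, 1, 1, 0, seed = 42)
  fl <- setNames(rep(1, nrow(b$transports)), b$transports$reaction_id)
  missing_one <- fl[-1]
  expect_warning(
    ctx <- classifyEdgesFBA(b$network, b$transports, missing_one),
    "absent")
  dropped <- names(fl)[1]
  if (dropped %in% ctx$edge_id) {
    expect_identical(
      ctx$direction_class[ctx$edge_id == dropped], "INACTIVE")
  }
  expect_warning(
    classifyEdgesFBA(b$network, b$transports, c(fl, GHOST_RXN = 5)),
    "ignored")
})

test_that("FVA classification handles the four sign cases and matches
           planted labels", {
  b <- makeFixtureBundle(3, 1, 1, 1, seed = 43)
  # order correction: range (2, 5) with coefficient -1 is consumption
  tr4 <- b$transports[b$transports$member != SHARED_MEMBER, ][1:4, ]
  tr4$external_coefficient <- c(1, 1, -1, -1)
  net4 <- b$network
  net4@edges <- net4@edges[match(tr4$reaction_id, net4@edges$edge_id), ]
  net4@edges$external_coefficient <- tr4$external_coefficient
  keep_met <- unique(net4@edges$metabolite_node)
  net4@metaboliteNodes <-
    net4@metaboliteNodes[net4@metaboliteNodes$node_id %in% keep_met, ]
  rg <- data.frame(reaction_id = tr4$reaction_id,
                   min_flux = c(-3, 0, 2, -5),
                   max_flux = c(5, 0, 5, -2))
  attr(tr4, "all_reaction_ids") <- tr4$reaction_id
  ctx <- classifyEdgesFVA(net4, tr4, rg, epsilon = 1e-6)
  expect_identical(ctx$direction_class,
                   c("BIDIRECTIONAL", "INACTIVE", "CONSUMPTION",
                     "PRODUCTION"))
  expect_equal(ctx$min_production[3], -5)
  expect_equal(ctx$max_production[3], -2)

  st <- generateFluxState(b$spec, b$fx$ground_truth, "FVA", b$dir)
  ranges <- readFVATSV(st$path)
  full <- classifyEdgesFVA(b$network, b$transports, ranges)
  expect_identical(full$direction_class,
                   unname(st$ground_truth$planted_classes[full$edge_id]))
})

test_that("FBA classification equals FVA of the degenerate range", {
  b <- makeFixtureBundle(4, 1, 2, 1, seed = 44)
  st <- generateFluxState(b$spec, b$fx$ground_truth, "FBA", b$dir)
  fluxes <- readFluxTSV(st$path)
  fba <- classifyEdgesFBA(b$network, b$transports, fluxes)
  degen <- data.frame(reaction_id = names(fluxes),
                      min_flux = unname(fluxes),
                      max_flux = unname(fluxes))
  fva <- classifyEdgesFVA(b$network, b$transports, degen)
  expect_identical(fba$direction_class, fva$direction_class)
  expect_equal(fba$display_width, fva$display_width)
})

test_that("edge widths are monotone with the documented boundary values", {
  mags <- c(0, 1, 10, 100)
  w <- edgeWidth(mags, width_range = c(1, 8))
  expect_equal(w[1], 1)
  expect_equal(w[4], 8)
  expect_true(all(diff(w) > 0))
  expect_equal(edgeWidth(c(0, 0, 0)), c(1, 1, 1))
  lin <- edgeWidth(c(0, 50, 100), mode = "linear")
  expect_equal(lin, c(1, 4.5, 8))
})

test_that("cross-feeding detection equals the brute-force oracle and is
           invariant under member relabelling", {
  for (seed in c(51, 52)) {
    b <- makeFixtureBundle(4, 1, 1, 2, seed = seed)
    st <- generateFluxState(b$spec, b$fx$ground_truth, "FBA", b$dir)
    fluxes <- readFluxTSV(st$path)
    ctx <- classifyEdgesFBA(b$network, b$transports, fluxes)
    rep_ <- detectCrossFeeding(b$network, ctx)
    oracle <- oracleCrossFeeding(b$transports, flux = fluxes)
    oi <- match(rep_$species_id, oracle$species_id)
    expect_identical(rep_$cross_fed, oracle$cross_fed[oi])
    expect_identical(lapply(rep_$producers, identity),
                     oracle$producers[oi])
    expect_identical(lapply(rep_$consumers, identity),
                     oracle$consumers[oi])
    # planted ground truth agrees
    gt <- st$ground_truth$planted_crossfeeding
    gi <- match(rep_$species_id, gt$species_id)
    expect_identical(rep_$cross_fed, gt$cross_fed[gi])

    # FVA (feasibility) mode against the oracle
    sv <- generateFluxState(b$spec, b$fx$ground_truth, "FVA", b$dir)
    ranges <- readFVATSV(sv$path)
    cvx <- classifyEdgesFVA(b$network, b$transports, ranges)
    repv <- detectCrossFeeding(b$network, cvx)
    ov <- oracleCrossFeeding(b$transports, ranges = ranges)
    expect_identical(repv$cross_fed,
                     ov$cross_fed[match(repv$species_id, ov$species_id)])

    # relabelling members permutes the report without changing flags
    net2 <- b$network
    perm <- setNames(rev(sort(net2@memberNodes$member)),
                     sort(net2@memberNodes$member))
    net2@memberNodes$member <- unname(perm[net2@memberNodes$member])
    rep2 <- detectCrossFeeding(net2, ctx)
    expect_identical(rep2$cross_fed, rep_$cross_fed)
    expect_identical(
      lapply(rep_$producers, function(p) sort(unname(perm[p]))),
      lapply(rep2$producers, identity))
  }
})

test_that("a metabolite produced and consumed by the same member only is
           not cross-fed", {
  tr <- data.frame(
    reaction_id = c("T1", "T2"), member = c("a", "a"),
    external_species = c("x_medium", "x_medium"),
    external_coefficient = c(1, -1),
    lower_bound = -1000, upper_bound = 1000, stringsAsFactors = FALSE)
  oracle <- oracleCrossFeeding(tr, flux = c(T1 = 2, T2 = 2))
  expect_false(oracle$cross_fed)
})

test_that("the cross-feeding toggle hides non-cross-fed parts and is an
           involution", {
  b <- makeFixtureBundle(3, 2, 1, 1, seed = 61)
  st <- generateFluxState(b$spec, b$fx$ground_truth, "FBA", b$dir)
  ctx <- classifyEdgesFBA(b$network, b$transports, readFluxTSV(st$path))
  net <- applyEdgeContexts(b$network, ctx)
  rep_ <- detectCrossFeeding(net, ctx)
  before <- hiddenIds(net)

  toggled <- toggleCrossFeeding(net, rep_)
  vis <- visibleIds(toggled)
  met_vis <- intersect(metaboliteNodes(toggled)$node_id, vis)
  expect_setequal(met_vis, rep_$node_id[rep_$cross_fed])
  # INACTIVE edges stay hidden regardless
  inactive <- ctx$edge_id[ctx$direction_class == "INACTIVE"]
  expect_true(all(inactive %in% hiddenIds(toggled)))
  # members always visible
  expect_true(all(memberNodes(toggled)$node_id %in% vis))

  restored <- toggleCrossFeeding(toggled, rep_)
  expect_identical(hiddenIds(restored), before)
})

test_that("bidirectionality statistics reproduce hand-computed tables and
           an independent exact test", {
  st <- makeTableStats(31, 9, 8, 91)
  expect_equal(st$fraction_bidirectional_crossfed, 31 / 40)
  expect_equal(st$fraction_bidirectional_other, 8 / 99)
  expect_equal(st$p_value, oracleExactP(st$table), tolerance = 1e-9)

  allbi <- makeTableStats(5, 0, 7, 0)
  expect_equal(allbi$fraction_bidirectional_crossfed, 1)
  expect_equal(allbi$fraction_bidirectional_other, 1)
  expect_equal(allbi$p_value, 1)

  # empty partition: no cross-fed group -> undefined fraction, no test
  none <- makeTableStats(0, 0, 3, 4)
  expect_true(is.na(none$fraction_bidirectional_crossfed))
  expect_true(is.na(none$p_value))
})

test_that("bidirectionality stats on fixtures include boundary-inclusive
           denominators and write a readable TSV", {
  b <- makeFixtureBundle(4, 2, 1, 1, seed = 71)
  st <- generateFluxState(b$spec, b$fx$ground_truth, "FVA", b$dir)
  ranges <- readFVATSV(st$path)
  ctx <- classifyEdgesFVA(b$network, b$transports, ranges)
  rep_ <- detectCrossFeeding(b$network, ctx)
  bs <- bidirectionalityStats(b$transports, ranges, rep_)
  expect_identical(bs$n_crossfed + bs$n_other,
                   sum(b$transports$member != SHARED_MEMBER))
  expect_identical(bs$n_other_with_boundary - bs$n_other,
                   sum(b$transports$member == SHARED_MEMBER))
  expect_equal(bs$fraction_bidirectional_crossfed,
               bs$n_bidirectional_crossfed / bs$n_crossfed)
  f <- file.path(b$dir, "stats.tsv")
  writeStatsTSV(bs, f)
  lines <- readLines(f)
  expect_match(lines[1], "^# p_value\t")
  expect_identical(lines[2], "group\tn\tn_bidirectional\tfraction")
  expect_length(lines, 5L)
})
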