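# Build a ReducedNetwork directly from a member/metabolite incidence list;
# keeps layout tests independent of the SBML pipeline.
incidenceNetwork <- function(incidence) {
  members <- sort(unique(unlist(incidence)))
  mem_nodes <- data.frame(node_id = paste0("M::", members),
                          member = members, stringsAsFactors = FALSE)
  mets <- names(incidence)
  met_nodes <- data.frame(
    node_id = paste0("X::", mets), species_id = mets, label = mets,
    has_boundary_exchange = FALSE, stringsAsFactors = FALSE)
  met_nodes$boundary_reaction_ids <- rep(list(character()), length(mets))
  edges <- do.call(rbind, lapply(mets, function(x) {
    data.frame(
      edge_id = paste0("TR_", incidence[[x]], "_", x),
      reaction_id = paste0("TR_", incidence[[x]], "_", x),
      member_node = paste0("M::", incidence[[x]]),
      metabolite_node = paste0("X::", x),
      external_coefficient = 1,
      stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  new("ReducedNetwork", memberNodes = mem_nodes, metaboliteNodes = met_nodes,
      edges = edges, hidden = character(), toggleMemory = list())
}

test_that("member ordering maximizes adjacency of heavy pairs", {
  # 3 members: every circular order is a triangle; lexicographic tie-break
  net3 <- incidenceNetwork(c(
    setNames(rep(list(c("a", "b")), 5), paste0("ab", 1:5)),
    setNames(rep(list(c("b", "c")), 4), paste0("bc", 1:4))
  ))
  expect_identical(orderMembers(net3), c("M::a", "M::b", "M::c"))

  # 4 members, w(a,b) = 3, w(c,d) = 3: optimum keeps both pairs adjacent
  net4 <- incidenceNetwork(c(
    setNames(rep(list(c("a", "b")), 3), paste0("ab", 1:3)),
    setNames(rep(list(c("c", "d")), 3), paste0("cd", 1:3))
  ))
  ord <- orderMembers(net4)
  expect_equal(oracleOrderObjective(net4, ord), 6)
  # brute force over the 3 distinct circular orders of 4 nodes
  best <- max(vapply(
    list(c("M::a", "M::b", "M::c", "M::d"),
         c("M::a", "M::b", "M::d", "M::c"),
         c("M::a", "M::c", "M::b", "M::d")),
    function(o) oracleOrderObjective(net4, o), numeric(1)))
  expect_equal(oracleOrderObjective(net4, ord), best)

  # degenerate single member
  net1 <- incidenceNetwork(list(x1 = "a"))
  expect_identical(orderMembers(net1), "M::a")
})

test_that("the greedy ordering used above 8 members is deterministic and
           respects heavy pairs", {
  inc <- c(
    setNames(rep(list(c("m01", "m02")), 4), paste0("p", 1:4)),
    setNames(rep(list(c("m03", "m04")), 4), paste0("q", 1:4)),
    lapply(setNames(sprintf("m%02d", 1:9), paste0("s", 1:9)), identity)
  )
  net <- incidenceNetwork(inc)
  ord <- orderMembers(net)
  expect_identical(sort(ord), sort(paste0("M::", sprintf("m%02d", 1:9))))
  expect_identical(ord, orderMembers(net))
  pos_of <- setNames(seq_along(ord), ord)
  circdist <- function(a, b) {
    d <- abs(pos_of[[a]] - pos_of[[b]])
    min(d, length(ord) - d)
  }
  expect_identical(circdist("M::m01", "M::m02"), 1L)
  expect_identical(circdist("M::m03", "M::m04"), 1L)
})

test_that("circle assignment follows member-degree", {
  net <- incidenceNetwork(list(
    only_a = "a", pair_ab = c("a", "b"), hub = c("a", "b", "c")))
  circ <- assignCircles(net)
  expect_identical(unname(circ["X::only_a"]), 1L)
  expect_identical(unname(circ["X::pair_ab"]), 3L)
  expect_identical(unname(circ["X::hub"]), 4L)
  expect_true(all(circ[paste0("M::", c("a", "b", "c"))] == 2L))
})

test_that("members are evenly spaced and adjacent-pair metabolites sit at
           the shorter-arc midpoint", {
  net <- incidenceNetwork(list(
    p1 = "a", p2 = "b", p3 = "c", p4 = "d",
    ab = c("a", "b"), bc = c("b", "c")))
  lay <- computePositions(net, order = paste0("M::", letters[1:4]))
  pos <- nodePositions(lay)
  ang <- setNames(pos$angle, pos$node_id)
  expect_equal(unname(ang[paste0("M::", letters[1:4])]),
               c(0, pi / 2, pi, 3 * pi / 2), tolerance = 1e-12)
  expect_equal(unname(ang[["X::ab"]]), pi / 4, tolerance = 1e-12)
  expect_equal(unname(ang[["X::bc"]]), 3 * pi / 4, tolerance = 1e-12)
  # private metabolites sit in their member's sector on circle 1
  expect_equal(unname(ang[["X::p1"]]), 0, tolerance = 1e-12)
  r <- circleRadii(lay)
  expect_equal(sqrt(pos$x^2 + pos$y^2), r[pos$circle], tolerance = 1e-9)
})

test_that("non-decreasing radii are rejected", {
  net <- incidenceNetwork(list(x = "a", y = "b"))
  expect_error(computePositions(net, radii = c(100, 200, 50, 10)),
               class = "communet_parameter_error")
  expect_error(computePositions(net, radii = c(100, 50, 10)),
               class = "communet_parameter_error")
})

test_that("layout invariants hold on randomized fixtures and the layout is
           rotation-equivariant and deterministic", {
  for (seed in c(31, 32)) {
    b <- makeFixtureBundle(5, 2, 1, 1, seed = seed)
    net <- b$network
    ord <- orderMembers(net)
    lay <- computePositions(net, ord)
    pos <- nodePositions(lay)
    r <- circleRadii(lay)

    expect_equal(sqrt(pos$x^2 + pos$y^2), r[pos$circle], tolerance = 1e-9)

    mang <- sort(pos$angle[pos$circle == 2])
    gaps <- diff(c(mang, mang[1] + 2 * pi))
    expect_equal(gaps, rep(2 * pi / length(mang), length(mang)),
                 tolerance = 1e-9)

    deg <- memberDegree(net)
    met <- pos[startsWith(pos$node_id, "X::"), ]
    expect_identical(
      met$circle,
      unname(ifelse(deg[met$node_id] == 1L, 1L,
                    ifelse(deg[met$node_id] == 2L, 3L, 4L))))

    # minimum angular separation of 2 degrees within each circle
    for (ci in c(1, 3, 4)) {
      a <- sort(pos$angle[pos$circle == ci])
      if (length(a) > 1) {
        gaps <- diff(c(a, a[1] + 2 * pi))
        expect_gte(min(gaps), 2 * pi / 180 - 1e-9)
      }
    }

    # determinism and rotation equivariance
    expect_identical(nodePositions(computePositions(net, ord)), pos)
    m <- length(ord)
    for (k in c(1L, 2L)) {
      ord2 <- c(ord[-seq_len(k)], ord[seq_len(k)])
      pos2 <- nodePositions(computePositions(net, ord2))
      pos2 <- pos2[match(pos$node_id, pos2$node_id), ]
      phi <- -2 * pi * k / m
      expect_equal(pos2$x, cos(phi) * pos$x - sin(phi) * pos$y,
                   tolerance = 1e-9)
      expect_equal(pos2$y, sin(phi) * pos$x + cos(phi) * pos$y,
                   tolerance = 1e-9)
    }
  }
})
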