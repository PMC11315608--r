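# Independent oracles used across the suite. These deliberately re-derive
# quantities from the raw files / raw tables through a different code path
# than the package implementation.

# Re-count a community SBML document by walking the XML directly.
oracleCountsFromSBML <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  comp <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//listOfCompartments/compartment"), "id")
  par <- xml2::xml_find_first(
    doc, ".//listOfParameters/parameter[@id='shared_compartment_id']")
  shared <- if (!inherits(par, "xml_missing")) {
    nm <- xml2::xml_attr(par, "name")
    if (!is.na(nm) && nm %in% comp) nm else xml2::xml_attr(par, "value")
  } else "medium"
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_comp <- setNames(xml2::xml_attr(sp_nodes, "compartment"),
                      xml2::xml_attr(sp_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  ext_of_member_transport <- character()
  n_member_edges <- 0L
  n_boundary <- 0L
  for (node in rx_nodes) {
    refs <- xml2::xml_attr(
      xml2::xml_find_all(node, ".//speciesReference"), "species")
    in_shared <- sp_comp[refs] == shared
    if (sum(in_shared) != 1L) next
    if (all(in_shared)) {
      n_boundary <- n_boundary + 1L
    } else {
      n_member_edges <- n_member_edges + 1L
      ext_of_member_transport <- c(ext_of_member_transport,
                                   refs[in_shared])
    }
  }
  list(
    n_species = length(sp_nodes),
    n_reactions = length(rx_nodes),
    n_metabolite_nodes = length(unique(ext_of_member_transport)),
    n_edges = n_member_edges,
    n_boundary_reactions = n_boundary,
    shared = shared
  )
}

# Two-sided exact test of independence on a 2x2 table by hypergeometric
# enumeration (conditional on margins).
oracleExactP <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  sum(dens[dens <= dens[support == x] * (1 + 1e-7)])
}

# Brute-force cross-feeding from the member x metabolite signed-production
# table: a member produces a metabolite when any of its transports has
# signed production > eps (max over a range in FVA mode), consumes when
# any has signed production < -eps.
oracleCrossFeeding <- function(transports, flux = NULL, ranges = NULL,
                               eps = 1e-6) {
  mt <- transports[transports$member != SHARED_MEMBER, , drop = FALSE]
  species <- sort(unique(mt$external_species))
  members <- sort(unique(mt$member))
  out <- data.frame(species_id = species, cross_fed = FALSE,
                    stringsAsFactors = FALSE)
  producers <- consumers <- vector("list", length(species))
  for (si in seq_along(species)) {
    p_set <- c_set <- character()
    for (mb in members) {
      rows <- which(mt$external_species == species[si] & mt$member == mb)
      can_p <- can_c <- FALSE
      for (r in rows) {
        co <- mt$external_coefficient[r]
        rid <- mt$reaction_id[r]
        if (!is.null(flux)) {
          v <- if (rid %in% names(flux)) flux[[rid]] else 0
          p <- co * v
          if (p > eps) can_p <- TRUE
          if (p < -eps) can_c <- TRUE
        } else {
          i <- match(rid, ranges$reaction_id)
          lo <- if (is.na(i)) 0 else ranges$min_flux[i]
          hi <- if (is.na(i)) 0 else ranges$max_flux[i]
          pv <- sort(c(co * lo, co * hi))
          if (pv[2] > eps) can_p <- TRUE
          if (pv[1] < -eps) can_c <- TRUE
        }
      }
      if (can_p) p_set <- c(p_set, mb)
      if (can_c) c_set <- c(c_set, mb)
    }
    producers[[si]] <- p_set
    consumers[[si]] <- c_set
    out$cross_fed[si] <- length(p_set) > 0 && length(c_set) > 0 &&
      length(union(p_set, c_set)) >= 2
  }
  out$producers <- producers
  out$consumers <- consumers
  out
}

# Objective value of a circular member order: adjacent-pair weights where
# w(a, b) = number of metabolites connected to exactly {a, b}.
oracleOrderObjective <- function(network, ord) {
  ed <- networkEdges(network)
  mm <- lapply(split(ed$member_node, ed$metabolite_node), unique)
  deg2 <- Filter(function(x) length(x) == 2L, mm)
  nxt <- c(ord[-1], ord[1])
  sum(vapply(seq_along(ord), function(i) {
    sum(vapply(deg2, function(p) setequal(p, c(ord[i], nxt[i])), logical(1)))
  }, numeric(1)))
}

# One small fixture bundle: model + network + planted states.
makeFixtureBundle <- function(n_members, n_private, n_pair, n_core, seed,
                              dir = withr::local_tempdir(
                                .local_envir = parent.frame())) {
  spec <- fixtureSpec(n_members, n_private, n_pair, n_core, seed = seed)
  fx <- generateToyCommunity(spec, dir)
  model <- readCommunitySBML(fx$sbml_path)
  transports <- collectTransportReactions(model)
  network <- buildReducedNetwork(model, transports)
  list(spec = spec, fx = fx, model = model, transports = transports,
       network = network, dir = dir)
}

# Synthetic transports/ranges/report realizing a given 2x2 bidirectionality
# table (crossfed bi / crossfed not / other bi / other not).
makeTableStats <- function(n_cf_bi, n_cf_no, n_ot_bi, n_ot_no) {
  n_cf <- n_cf_bi + n_cf_no
  n_ot <- n_ot_bi + n_ot_no
  tr <- data.frame(
    reaction_id = sprintf("T%03d", seq_len(n_cf + n_ot)),
    member = "a",
    external_species = c(rep("cf_medium", n_cf), rep("ot_medium", n_ot)),
    external_coefficient = 1,
    lower_bound = -1000, upper_bound = 1000, stringsAsFactors = FALSE)
  bi <- c(rep(TRUE, n_cf_bi), rep(FALSE, n_cf_no),
          rep(TRUE, n_ot_bi), rep(FALSE, n_ot_no))
  rg <- data.frame(reaction_id = tr$reaction_id,
                   min_flux = ifelse(bi, -1, 1),
                   max_flux = ifelse(bi, 1, 2))
  rep_ <- data.frame(node_id = c("X::cf_medium", "X::ot_medium"),
                     species_id = c("cf_medium", "ot_medium"),
                     cross_fed = c(TRUE, FALSE),
                     stringsAsFactors = FALSE)
  attr(rep_, "mode") <- "FVA"
  bidirectionalityStats(tr, rg, rep_)
}

# The desk-scale fixture matrix shared by the acceptance checks.
fixtureMatrixSpecs <- function() {
  grid <- expand.grid(
    m = c(2L, 3L, 4L, 5L, 6L),
    private = c(0L, 1L, 2L, 3L),
    pair = c(0L, 1L, 2L),
    core = c(0L, 1L),
    KEEP.OUT.ATTRS = FALSE
  )
  grid <- grid[!(grid$core > 0 & grid$m < 3), , drop = FALSE]
  grid <- grid[grid$private + grid$pair + grid$core > 0, , drop = FALSE]
  grid$seed <- seq_len(nrow(grid)) + 100L
  grid
}
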