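DEFAULT_EPSILON <- 1e-6
DEFAULT_WIDTH_RANGE <- c(1, 8)

#' Signed production rate of a transport reaction
#'
#' The product of a transport's external-metabolite stoichiometric
#' coefficient and its flux. Positive values mean the member releases the
#' metabolite into the shared compartment, negative values mean uptake,
#' regardless of which direction the reaction happens to be written in.
#'
#' @param external_coefficient signed stoichiometric coefficient of the
#'   shared-compartment species (vectorized).
#' @param flux reaction flux (vectorized).
#' @return numeric, the signed production rate.
#' @examples
#' signedProduction(+1, 2.5)   # secretion
#' signedProduction(-1, 2.5)   # a reaction written as uptake
#' @export
signedProduction <- function(external_coefficient, flux) {
  external_coefficient * flux
}

edgeTransports <- function(network, transports) {
  ed <- network@edges
  idx <- match(ed$reaction_id, transports$reaction_id)
  if (anyNA(idx)) {
    parameterError("transports do not cover every network edge")
  }
  transports[idx, , drop = FALSE]
}

#' Classify edges from a single flux state (FBA)
#'
#' Each edge's signed production rate `p` (see [signedProduction()]) is
#' compared against the zero-flux tolerance `epsilon`: `|p| <= epsilon`
#' means INACTIVE (the edge is dropped from the visualization), `p >
#' epsilon` PRODUCTION, `p < -epsilon` CONSUMPTION. Edges whose reaction is
#' absent from the flux vector are INACTIVE with a warning; flux entries
#' for unknown reactions are ignored with a warning. Display widths scale
#' with flux magnitude via [edgeWidth()].
#'
#' @param network a [ReducedNetwork-class].
#' @param transports transport table from [collectTransportReactions()].
#' @param fluxes named numeric flux vector (see [readFluxTSV()]).
#' @param epsilon zero-flux tolerance in flux units (default `1e-6`).
#' @param width_range numeric(2), minimum and maximum display width.
#' @param width_mode `"log"` (default) or `"linear"` magnitude-to-width map.
#' @return data.frame with columns `edge_id`, `direction_class`,
#'   `production` and `display_width`; attributes `mode = "FBA"` and
#'   `epsilon`.
#' @export
classifyEdgesFBA <- function(network, transports, fluxes,
                             epsilon = DEFAULT_EPSILON,
                             width_range = DEFAULT_WIDTH_RANGE,
                             width_mode = c("log", "linear")) {
  stopifnot(epsilon >= 0)
  width_mode <- match.arg(width_mode)
  tr <- edgeTransports(network, transports)
  known <- attr(transports, "all_reaction_ids")
  if (is.null(known)) known <- transports$reaction_id
  stray <- setdiff(names(fluxes), known)
  if (length(stray)) {
    warning("flux entries for ", length(stray),
            " reaction(s) not in the model; ignored", call. = FALSE)
  }
  f <- fluxes[tr$reaction_id]
  if (anyNA(f)) {
    warning(sum(is.na(f)), " edge reaction(s) absent from the flux vector; ",
            "treated as inactive", call. = FALSE)
    f[is.na(f)] <- 0
  }
  p <- signedProduction(tr$external_coefficient, unname(f))
  cls <- ifelse(abs(p) <= epsilon, "INACTIVE",
                ifelse(p > 0, "PRODUCTION", "CONSUMPTION"))
  w <- edgeWidth(ifelse(cls == "INACTIVE", 0, abs(p)),
                 abs(p)[cls != "INACTIVE"],
                 width_range = width_range, mode = width_mode)
  w[cls == "INACTIVE"] <- 0
  out <- data.frame(
    edge_id = network@edges$edge_id,
    direction_class = cls,
    production = p,
    display_width = w,
    stringsAsFactors = FALSE
  )
  attr(out, "mode") <- "FBA"
  attr(out, "epsilon") <- epsilon
  out
}

#' Classify edges from flux ranges (FVA)
#'
#' The signed production range of each edge is the order-corrected interval
#' `sort(coefficient * c(min_flux, max_flux))`. Ranges entirely within
#' `[-epsilon, epsilon]` are INACTIVE; ranges strictly positive beyond
#' `epsilon` are PRODUCTION; strictly negative, CONSUMPTION; ranges
#' straddling zero beyond the tolerance on both sides are BIDIRECTIONAL.
#' Width scales with the larger absolute production bound.
#'
#' @inheritParams classifyEdgesFBA
#' @param ranges data.frame from [readFVATSV()].
#' @return data.frame with columns `edge_id`, `direction_class`,
#'   `min_production`, `max_production`, `display_width`; attributes
#'   `mode = "FVA"` and `epsilon`.
#' @export
classifyEdgesFVA <- function(network, transports, ranges,
                             epsilon = DEFAULT_EPSILON,
                             width_range = DEFAULT_WIDTH_RANGE,
                             width_mode = c("log", "linear")) {
  stopifnot(epsilon >= 0)
  width_mode <- match.arg(width_mode)
  tr <- edgeTransports(network, transports)
  known <- attr(transports, "all_reaction_ids")
  if (is.null(known)) known <- transports$reaction_id
  stray <- setdiff(ranges$reaction_id, known)
  if (length(stray)) {
    warning("flux ranges for ", length(stray),
            " reaction(s) not in the model; ignored", call. = FALSE)
  }
  idx <- match(tr$reaction_id, ranges$reaction_id)
  if (anyNA(idx)) {
    warning(sum(is.na(idx)),
            " edge reaction(s) absent from the FVA table; treated as inactive",
            call. = FALSE)
  }
  lo <- ifelse(is.na(idx), 0, ranges$min_flux[idx])
  hi <- ifelse(is.na(idx), 0, ranges$max_flux[idx])
  pr <- productionRange(tr$external_coefficient, lo, hi)
  cls <- classifyRange(pr$pmin, pr$pmax, epsilon)
  mag <- pmax(abs(pr$pmin), abs(pr$pmax))
  w <- edgeWidth(ifelse(cls == "INACTIVE", 0, mag),
                 mag[cls != "INACTIVE"],
                 width_range = width_range, mode = width_mode)
  w[cls == "INACTIVE"] <- 0
  out <- data.frame(
    edge_id = network@edges$edge_id,
    direction_class = cls,
    min_production = pr$pmin,
    max_production = pr$pmax,
    display_width = w,
    stringsAsFactors = FALSE
  )
  attr(out, "mode") <- "FVA"
  attr(out, "epsilon") <- epsilon
  out
}

productionRange <- function(coef, min_flux, max_flux) {
  a <- signedProduction(coef, min_flux)
  b <- signedProduction(coef, max_flux)
  list(pmin = pmin(a, b), pmax = pmax(a, b))
}

classifyRange <- function(pmin, pmax, epsilon) {
  ifelse(pmax <= epsilon & pmin >= -epsilon, "INACTIVE",
         ifelse(pmin > epsilon, "PRODUCTION",
                ifelse(pmax < -epsilon, "CONSUMPTION", "BIDIRECTIONAL")))
}

#' Map flux magnitudes to display widths
#'
#' Log-compressed by default, because genome-scale flux magnitudes span
#' orders of magnitude: `w = w_min + (w_max - w_min) * log10(1 + m/m_ref) /
#' log10(1 + m_max/m_ref)` with `m_ref` the smallest non-zero magnitude and
#' `m_max` the largest. Strictly monotone, `w(0) = w_min`, `w(m_max) =
#' w_max`. A linear mode is available.
#'
#' @param magnitude numeric vector of non-negative magnitudes to map.
#' @param all_magnitudes the population of magnitudes defining the scale
#'   (defaults to `magnitude`).
#' @param width_range numeric(2), `c(w_min, w_max)`.
#' @param mode `"log"` or `"linear"`.
#' @return numeric widths, same length as `magnitude`.
#' @export
edgeWidth <- function(magnitude, all_magnitudes = magnitude,
                      width_range = DEFAULT_WIDTH_RANGE,
                      mode = c("log", "linear")) {
  mode <- match.arg(mode)
  stopifnot(all(magnitude >= 0), length(width_range) == 2L)
  w_min <- width_range[1]
  w_max <- width_range[2]
  nz <- all_magnitudes[all_magnitudes > 0]
  if (!length(nz)) return(rep(w_min, length(magnitude)))
  m_max <- max(nz)
  if (mode == "linear") {
    return(w_min + (w_max - w_min) * magnitude / m_max)
  }
  m_ref <- min(nz)
  w_min + (w_max - w_min) *
    log10(1 + magnitude / m_ref) / log10(1 + m_max / m_ref)
}

#' Detect cross-feeding interactions
#'
#' A metabolite is cross-fed when at least one member produces it and a
#' *different* member takes it up. In FBA mode producers/consumers are the
#' members with a PRODUCTION/CONSUMPTION edge in the realized flux state; in
#' FVA mode they are the members that *could* produce (`max_production >
#' epsilon`) or consume (`min_production < -epsilon`) — feasible
#' cross-feeding. More than two members may take part, and the presence of
#' the metabolite in the medium (boundary exchange) is ignored.
#'
#' @param network a [ReducedNetwork-class].
#' @param edge_contexts classification table from [classifyEdgesFBA()] or
#'   [classifyEdgesFVA()].
#' @param mode `"FBA"` or `"FVA"`; defaults to the contexts' mode attribute.
#' @return data.frame with one row per metabolite node: `node_id`,
#'   `species_id`, list columns `producers` and `consumers` (member IDs) and
#'   `cross_fed`; attribute `mode`.
#' @export
detectCrossFeeding <- function(network, edge_contexts,
                               mode = attr(edge_contexts, "mode")) {
  mode <- match.arg(mode, c("FBA", "FVA"))
  eps <- attr(edge_contexts, "epsilon")
  if (is.null(eps)) eps <- DEFAULT_EPSILON
  ed <- network@edges
  ctx <- edge_contexts[match(ed$edge_id, edge_contexts$edge_id), , drop = FALSE]
  member_of <- setNames(network@memberNodes$member,
                        network@memberNodes$node_id)
  mem <- member_of[ed$member_node]

  if (mode == "FBA") {
    is_prod <- ctx$direction_class == "PRODUCTION"
    is_cons <- ctx$direction_class == "CONSUMPTION"
  } else {
    is_prod <- ctx$max_production > eps
    is_cons <- ctx$min_production < -eps
  }

  met <- network@metaboliteNodes
  producers <- lapply(met$node_id, function(nid) {
    sel <- ed$metabolite_node == nid & is_prod
    sort(unique(unname(mem[sel])))
  })
  consumers <- lapply(met$node_id, function(nid) {
    sel <- ed$metabolite_node == nid & is_cons
    sort(unique(unname(mem[sel])))
  })
  cross_fed <- mapply(function(p, c) {
    length(p) > 0L && length(c) > 0L && length(union(p, c)) >= 2L
  }, producers, consumers)

  out <- data.frame(
    node_id = met$node_id,
    species_id = met$species_id,
    cross_fed = unname(cross_fed),
    stringsAsFactors = FALSE
  )
  out$producers <- producers
  out$consumers <- consumers
  attr(out, "mode") <- mode
  attr(out, "epsilon") <- eps
  out
}

#' Apply edge classifications to network visibility
#'
#' Hides INACTIVE edges (reactions that carry no flux are dropped from the
#' visualization) and every metabolite node whose edges are then all
#' hidden. Member nodes are never hidden.
#'
#' @param network a [ReducedNetwork-class].
#' @param edge_contexts classification table.
#' @return the network with an updated hidden set.
#' @export
applyEdgeContexts <- function(network, edge_contexts) {
  inactive <- edge_contexts$edge_id[edge_contexts$direction_class == "INACTIVE"]
  network <- hideIds(network, inactive)
  ed <- network@edges
  all_hidden <- vapply(network@metaboliteNodes$node_id, function(nid) {
    eids <- ed$edge_id[ed$metabolite_node == nid]
    all(eids %in% network@hidden)
  }, logical(1))
  hideIds(network, network@metaboliteNodes$node_id[all_hidden])
}

#' Toggle the cross-feeding-only view
#'
#' The first call hides every metabolite that is not cross-fed together with
#' all of its edges, and on cross-fed metabolites every edge that does not
#' take part in the interaction (its member is neither producer nor
#' consumer). Edges already hidden — e.g. INACTIVE ones — stay hidden. The
#' second call restores exactly the visibility state before the first:
#' the toggle is an involution.
#'
#' @param network a [ReducedNetwork-class].
#' @param report cross-feeding report from [detectCrossFeeding()] on this
#'   network.
#' @return the network with toggled visibility.
#' @export
toggleCrossFeeding <- function(network, report) {
  if (length(network@toggleMemory)) {
    network@hidden <- network@toggleMemory[[1]]
    network@toggleMemory <- list()
    return(network)
  }
  snapshot <- network@hidden
  member_of <- setNames(network@memberNodes$member,
                        network@memberNodes$node_id)
  rep_idx <- match(network@metaboliteNodes$node_id, report$node_id)
  cf <- report$cross_fed[rep_idx]
  hide <- character()
  ed <- network@edges
  for (i in seq_len(nrow(network@metaboliteNodes))) {
    nid <- network@metaboliteNodes$node_id[i]
    eids <- ed$edge_id[ed$metabolite_node == nid]
    if (!isTRUE(cf[i])) {
      hide <- c(hide, nid, eids)
    } else {
      involved <- union(report$producers[[rep_idx[i]]],
                        report$consumers[[rep_idx[i]]])
      emem <- member_of[ed$member_node[match(eids, ed$edge_id)]]
      hide <- c(hide, eids[!(emem %in% involved)])
    }
  }
  network <- hideIds(network, hide)
  network@toggleMemory <- list(snapshot)
  network
}

#' Bidirectionality of external reactions in and outside cross-feeding
#'
#' Partitions member transport reactions by whether their metabolite is
#' cross-fed (per an FVA-mode report) and, within each group, counts the
#' reactions whose FVA production range strictly spans zero
#' (BIDIRECTIONAL). Association between the two partitions is assessed with
#' a two-sided Fisher exact test on the 2x2 table. Because it is debatable
#' whether community boundary exchanges count as "external reactions", the
#' boundary-inclusive decomposition is reported alongside (boundary
#' exchanges have no member and can never be cross-feeding).
#'
#' @param transports transport table from [collectTransportReactions()].
#' @param ranges FVA table from [readFVATSV()].
#' @param report FVA-mode report from [detectCrossFeeding()].
#' @param epsilon zero-flux tolerance (default `1e-6`).
#' @return list with the 2x2 `table` (rows crossfed/other, columns
#'   bidirectional/not), `fraction_bidirectional_crossfed`,
#'   `fraction_bidirectional_other`, `p_value`, per-group counts, and the
#'   boundary-inclusive `fraction_bidirectional_other_with_boundary`.
#'   Fractions of empty groups are `NA` and no test is run.
#' @export
bidirectionalityStats <- function(transports, ranges, report,
                                  epsilon = DEFAULT_EPSILON) {
  if (!identical(attr(report, "mode"), "FVA")) {
    parameterError("bidirectionalityStats needs an FVA-mode cross-feeding report")
  }
  idx <- match(transports$reaction_id, ranges$reaction_id)
  lo <- ifelse(is.na(idx), 0, ranges$min_flux[idx])
  hi <- ifelse(is.na(idx), 0, ranges$max_flux[idx])
  pr <- productionRange(transports$external_coefficient, lo, hi)
  bidir <- classifyRange(pr$pmin, pr$pmax, epsilon) == "BIDIRECTIONAL"

  crossfed_species <- report$species_id[report$cross_fed]
  is_member <- transports$member != SHARED_MEMBER
  on_cf <- transports$external_species %in% crossfed_species

  g_cf <- is_member & on_cf
  g_other <- is_member & !on_cf
  n_cf <- sum(g_cf); n_other <- sum(g_other)
  k_cf <- sum(bidir[g_cf]); k_other <- sum(bidir[g_other])

  tab <- matrix(c(k_cf, n_cf - k_cf, k_other, n_other - k_other),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("crossfed", "other"),
                                c("bidirectional", "not_bidirectional")))
  p <- if (n_cf > 0 && n_other > 0) {
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  } else {
    NA_real_
  }
  n_other_b <- n_other + sum(!is_member)
  k_other_b <- k_other + sum(bidir[!is_member])
  list(
    table = tab,
    n_crossfed = n_cf,
    n_bidirectional_crossfed = k_cf,
    fraction_bidirectional_crossfed = if (n_cf) k_cf / n_cf else NA_real_,
    n_other = n_other,
    n_bidirectional_other = k_other,
    fraction_bidirectional_other = if (n_other) k_other / n_other else NA_real_,
    n_other_with_boundary = n_other_b,
    n_bidirectional_other_with_boundary = k_other_b,
    fraction_bidirectional_other_with_boundary =
      if (n_other_b) k_other_b / n_other_b else NA_real_,
    p_value = p
  )
}

#' Write bidirectionality statistics to a TSV
#'
#' @param stats result of [bidirectionalityStats()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeStatsTSV <- function(stats, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# p_value\t%.10g", stats$p_value), con)
  writeLines("group\tn\tn_bidirectional\tfraction", con)
  rows <- c(
    sprintf("crossfed\t%d\t%d\t%.10g", stats$n_crossfed,
            stats$n_bidirectional_crossfed,
            stats$fraction_bidirectional_crossfed),
    sprintf("other\t%d\t%d\t%.10g", stats$n_other,
            stats$n_bidirectional_other,
            stats$fraction_bidirectional_other),
    sprintf("other_with_boundary\t%d\t%d\t%.10g",
            stats$n_other_with_boundary,
            stats$n_bidirectional_other_with_boundary,
            stats$fraction_bidirectional_other_with_boundary)
  )
  writeLines(rows, con)
  invisible(path)
}
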