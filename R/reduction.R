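memberNodeId <- function(member) {
  if (!length(member)) character(0) else paste0("M::", member)
}
metaboliteNodeId <- function(species_id) {
  if (!length(species_id)) character(0) else paste0("X::", species_id)
}

#' Build the reduced community interaction network
#'
#' Produces the simplified bipartite view of a community metabolic model:
#' one node per community member, one node per external metabolite moved by
#' some member transport, and one edge per member transport reaction
#' (parallel transporters of the same member/metabolite pair stay parallel
#' edges, since flux files key on reaction IDs). Community boundary
#' exchanges are attached to metabolite nodes as `boundary_reaction_ids`
#' rather than edges: they have no member endpoint.
#'
#' @param model a [CommunityModel-class].
#' @param transports transport table from [collectTransportReactions()];
#'   computed from `model` when omitted.
#' @return a [ReducedNetwork-class].
#' @examples
#' fx <- generateToyCommunity(fixtureSpec(2, 1, 1, seed = 1), tempdir())
#' net <- buildReducedNetwork(readCommunitySBML(fx$sbml_path))
#' networkSummary(net)
#' @export
buildReducedNetwork <- function(model,
                                transports = collectTransportReactions(model)) {
  mem_nodes <- data.frame(
    node_id = memberNodeId(model@members),
    member = model@members,
    stringsAsFactors = FALSE
  )

  is_member_tr <- transports$member != SHARED_MEMBER
  mtr <- transports[is_member_tr, , drop = FALSE]
  btr <- transports[!is_member_tr, , drop = FALSE]

  sp_ids <- sort(unique(mtr$external_species))
  sp_name <- setNames(model@species$name, model@species$species_id)
  labels <- vapply(sp_ids, function(s) {
    nm <- sp_name[[s]]
    if (!is.null(nm) && nzchar(nm)) nm else stripSharedSuffix(s, model@sharedCompartment)
  }, character(1))
  boundary <- lapply(sp_ids, function(s)
    sort(btr$reaction_id[btr$external_species == s]))
  met_nodes <- data.frame(
    node_id = metaboliteNodeId(sp_ids),
    species_id = sp_ids,
    label = unname(labels),
    has_boundary_exchange = lengths(boundary) > 0L,
    stringsAsFactors = FALSE
  )
  met_nodes$boundary_reaction_ids <- boundary

  ord <- order(mtr$reaction_id)
  mtr <- mtr[ord, , drop = FALSE]
  edges <- data.frame(
    edge_id = mtr$reaction_id,
    reaction_id = mtr$reaction_id,
    member_node = memberNodeId(mtr$member),
    metabolite_node = metaboliteNodeId(mtr$external_species),
    external_coefficient = mtr$external_coefficient,
    stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL

  new("ReducedNetwork",
      memberNodes = mem_nodes,
      metaboliteNodes = met_nodes,
      edges = edges,
      hidden = character(),
      toggleMemory = list())
}

stripSharedSuffix <- function(species_id, shared) {
  sub(paste0("_", shared, "$"), "", species_id)
}

#' Summarize a reduced network
#'
#' Counts are taken over all nodes and edges, visible or hidden: visibility
#' toggling never deletes network elements.
#'
#' @param network a [ReducedNetwork-class].
#' @return list with `n_members`, `n_metabolites`, `n_edges`,
#'   `n_boundary_reactions`, `n_reaction_records` (edges plus boundary
#'   exchanges) and `degree_histogram`, a table of metabolite edge degrees.
#' @export
networkSummary <- function(network) {
  deg <- table(factor(network@edges$metabolite_node,
                      levels = network@metaboliteNodes$node_id))
  hist <- table(as.integer(deg))
  n_boundary <- sum(lengths(network@metaboliteNodes$boundary_reaction_ids))
  list(
    n_members = nrow(network@memberNodes),
    n_metabolites = nrow(network@metaboliteNodes),
    n_edges = nrow(network@edges),
    n_boundary_reactions = n_boundary,
    n_reaction_records = nrow(network@edges) + n_boundary,
    degree_histogram = hist
  )
}

#' Member-degree of every metabolite node
#'
#' Number of distinct community members a metabolite is connected to over
#' visible and hidden edges; the quantity that decides a metabolite's layout
#' circle and drives member ordering.
#'
#' @param network a [ReducedNetwork-class].
#' @return named integer vector keyed by metabolite node ID.
#' @export
memberDegree <- function(network) {
  ed <- network@edges
  vapply(network@metaboliteNodes$node_id, function(nid) {
    length(unique(ed$member_node[ed$metabolite_node == nid]))
  }, integer(1))
}

hideIds <- function(network, ids) {
  network@hidden <- sort(unique(c(network@hidden, ids)))
  network
}

#' Set of visible element IDs of a network
#'
#' @param network a [ReducedNetwork-class].
#' @return character vector of visible node and edge IDs.
#' @export
visibleIds <- function(network) {
  all_ids <- c(network@memberNodes$node_id,
               network@metaboliteNodes$node_id,
               network@edges$edge_id)
  setdiff(all_ids, network@hidden)
}
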