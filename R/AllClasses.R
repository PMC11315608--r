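#' @import methods
NULL

#' Sentinel for community-level (member-less) entities
#'
#' Boundary exchange reactions connect a shared-compartment metabolite to the
#' model boundary and belong to no single community member. They carry this
#' sentinel in their `member` field.
#'
#' @export
SHARED_MEMBER <- ".shared"

#' CommunityModel: a parsed compartmentalized community metabolic model
#'
#' Holds the parts of an SBML Level 3 (+FBC) community model that network
#' reduction needs: community members, compartments, species and reactions.
#' Community models follow the PyCoMo conventions: each member's metabolite
#' and compartment IDs carry the member ID as a `"<member>_"` prefix, and all
#' members exchange metabolites through one shared external compartment
#' (`"medium"` unless overridden).
#'
#' @slot modelId character(1), the SBML model id.
#' @slot members character vector of member IDs, lexicographically sorted.
#' @slot sharedCompartment character(1), ID of the shared external compartment.
#' @slot compartments character vector of all compartment IDs.
#' @slot species data.frame with columns `species_id`, `compartment`,
#'   `member` (member ID or [SHARED_MEMBER]) and `name`.
#' @slot reactions data.frame with columns `reaction_id`, `lower_bound`,
#'   `upper_bound` and a list column `stoichiometry` of named numeric vectors
#'   (names are species IDs, values signed coefficients).
#'
#' @seealso [readCommunitySBML()], [collectTransportReactions()]
#' @export
setClass("CommunityModel",
  representation(
    modelId = "character",
    members = "character",
    sharedCompartment = "character",
    compartments = "character",
    species = "data.frame",
    reactions = "data.frame"
  )
)

setValidity("CommunityModel", function(object) {
  msg <- character()
  if (length(object@sharedCompartment) != 1L ||
      !(object@sharedCompartment %in% object@compartments)) {
    msg <- c(msg, "sharedCompartment must be one of the model compartments")
  }
  if (anyDuplicated(object@members) || any(!nzchar(object@members))) {
    msg <- c(msg, "members must be non-empty and unique")
  }
  nonshared <- setdiff(object@compartments, object@sharedCompartment)
  if (length(nonshared) && length(object@members)) {
    pref <- vapply(nonshared, function(cid) {
      hits <- object@members[startsWith(cid, paste0(object@members, "_"))]
      length(hits)
    }, integer(1))
    if (any(pref != 1L)) {
      msg <- c(msg, paste0(
        "non-shared compartments not prefixed by exactly one member: ",
        paste(nonshared[pref != 1L], collapse = ", ")
      ))
    }
  }
  sp <- object@species
  if (nrow(sp)) {
    in_shared <- sp$compartment == object@sharedCompartment
    if (!all((sp$member == SHARED_MEMBER) == in_shared)) {
      msg <- c(msg, "species member must be the SHARED sentinel iff the species lives in the shared compartment")
    }
  }
  rx <- object@reactions
  if (nrow(rx)) {
    if (any(vapply(rx$stoichiometry, length, integer(1)) == 0L)) {
      msg <- c(msg, "every reaction needs non-empty stoichiometry")
    }
    if (any(rx$lower_bound > rx$upper_bound)) {
      msg <- c(msg, "reaction lower_bound must not exceed upper_bound")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ReducedNetwork: the simplified community interaction network
#'
#' A strictly bipartite graph with one node per community member, one node per
#' external (shared-compartment) metabolite that some member transports, and
#' one edge per member transport reaction. Community boundary exchanges
#' (medium to environment) are recorded on the metabolite nodes, not as edges.
#' Visibility toggling (cross-feeding focus, inactive-edge dropping) operates
#' on the `hidden` set; nodes and edges are never deleted.
#'
#' @slot memberNodes data.frame with columns `node_id`, `member`.
#' @slot metaboliteNodes data.frame with columns `node_id`, `species_id`,
#'   `label`, `has_boundary_exchange` and list column `boundary_reaction_ids`.
#' @slot edges data.frame with columns `edge_id`, `reaction_id`,
#'   `member_node`, `metabolite_node`, `external_coefficient`. `edge_id` and
#'   `reaction_id` are in one-to-one correspondence.
#' @slot hidden character vector of hidden node/edge IDs.
#' @slot toggleMemory list; visibility snapshot used to make the
#'   cross-feeding toggle an involution (internal).
#'
#' @seealso [buildReducedNetwork()], [toggleCrossFeeding()]
#' @export
setClass("ReducedNetwork",
  representation(
    memberNodes = "data.frame",
    metaboliteNodes = "data.frame",
    edges = "data.frame",
    hidden = "character",
    toggleMemory = "list"
  ),
  prototype(hidden = character(), toggleMemory = list())
)

setValidity("ReducedNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  if (nrow(ed)) {
    if (!all(ed$member_node %in% object@memberNodes$node_id)) {
      msg <- c(msg, "every edge source must be a member node")
    }
    if (!all(ed$metabolite_node %in% object@metaboliteNodes$node_id)) {
      msg <- c(msg, "every edge target must be a metabolite node")
    }
    if (anyDuplicated(ed$edge_id) || anyDuplicated(ed$reaction_id)) {
      msg <- c(msg, "edge_id and reaction_id must each be unique (one-to-one)")
    }
  }
  if (nrow(object@metaboliteNodes)) {
    deg <- table(factor(ed$metabolite_node,
                        levels = object@metaboliteNodes$node_id))
    if (any(deg == 0L)) {
      msg <- c(msg, "every metabolite node needs degree >= 1 over visible + hidden edges")
    }
  }
  if (length(intersect(object@memberNodes$node_id,
                       object@metaboliteNodes$node_id))) {
    msg <- c(msg, "member and metabolite node IDs must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' NetworkLayout: node positions on four concentric circles
#'
#' Private metabolites (member-degree 1) sit on the outermost circle, members
#' on the second, two-member metabolites on the third, and hub metabolites
#' (member-degree >= 3) on the innermost circle. Coordinates follow the
#' mathematical convention (x right, y up, angles counter-clockwise from +x);
#' screen-coordinate exporters flip y.
#'
#' @slot positions data.frame with columns `node_id`, `circle` (1-4),
#'   `angle` (radians in [0, 2*pi)), `x`, `y`.
#' @slot radii numeric(4), strictly decreasing radii of circles 1-4.
#' @slot memberOrder character vector: the circular member-node order used.
#'
#' @seealso [computePositions()]
#' @export
setClass("NetworkLayout",
  representation(
    positions = "data.frame",
    radii = "numeric",
    memberOrder = "character"
  )
)

setValidity("NetworkLayout", function(object) {
  msg <- character()
  if (length(object@radii) != 4L || any(diff(object@radii) >= 0) ||
      any(object@radii <= 0)) {
    msg <- c(msg, "radii must be 4 strictly decreasing positive numbers")
  }
  p <- object@positions
  if (nrow(p)) {
    if (!all(p$circle %in% 1:4)) msg <- c(msg, "circle indices must be in 1..4")
    r <- object@radii[p$circle]
    if (any(abs(sqrt(p$x^2 + p$y^2) - r) > 1e-9 * r)) {
      msg <- c(msg, "every node must lie on its circle's radius (1e-9 relative)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' StyledNetwork: a laid-out, styled network document ready for export
#'
#' The serializable form consumed by [writeGraphML()], [writeCyjs()] and
#' [renderFigure()]: every node carries position, visibility, circle, colour
#' and size; every edge carries direction class, width, colour and arrow
#' orientation.
#'
#' @slot nodes data.frame with columns `id`, `type` ("member"/"metabolite"),
#'   `label`, `x`, `y`, `visible`, `circle`, `colour`, `size`.
#' @slot edges data.frame with columns `id`, `reaction_id`, `source`,
#'   `target`, `direction_class`, `width`, `colour`, `arrow`
#'   ("forward"/"reverse"/"both"/"none") and `visible`.
#'
#' @seealso [styleNetwork()]
#' @export
setClass("StyledNetwork",
  representation(nodes = "data.frame", edges = "data.frame")
)

setValidity("StyledNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  if (nrow(ed)) {
    ok <- (ed$direction_class == "PRODUCTION" & ed$arrow == "forward") |
      (ed$direction_class == "CONSUMPTION" & ed$arrow == "reverse") |
      (ed$direction_class == "BIDIRECTIONAL" & ed$arrow == "both") |
      (ed$direction_class %in% c("INACTIVE", "UNCONTEXTUALIZED") &
         ed$arrow == "none")
    if (!all(ok)) {
      msg <- c(msg, "arrow orientation inconsistent with direction_class")
    }
    if (!all(ed$source %in% object@nodes$id) ||
        !all(ed$target %in% object@nodes$id)) {
      msg <- c(msg, "edge endpoints must be node ids")
    }
  }
  if (length(msg)) msg else TRUE
})
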