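#' @name accessors
#' @title Accessors for communet containers
#'
#' @description Small accessor functions so user code never reaches into
#' slots directly.
#'
#' @param object a [CommunityModel-class], [ReducedNetwork-class],
#'   [NetworkLayout-class] or [StyledNetwork-class] object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("members", function(object) standardGeneric("members"))

#' @rdname accessors
#' @export
setMethod("members", "CommunityModel", function(object) object@members)

#' @rdname accessors
#' @export
setGeneric("sharedCompartment",
           function(object) standardGeneric("sharedCompartment"))

#' @rdname accessors
#' @export
setMethod("sharedCompartment", "CommunityModel",
          function(object) object@sharedCompartment)

#' @rdname accessors
#' @export
setGeneric("speciesTable", function(object) standardGeneric("speciesTable"))

#' @rdname accessors
#' @export
setMethod("speciesTable", "CommunityModel", function(object) object@species)

#' @rdname accessors
#' @export
setGeneric("reactionTable", function(object) standardGeneric("reactionTable"))

#' @rdname accessors
#' @export
setMethod("reactionTable", "CommunityModel", function(object) object@reactions)

#' @rdname accessors
#' @export
setGeneric("memberNodes", function(object) standardGeneric("memberNodes"))

#' @rdname accessors
#' @export
setMethod("memberNodes", "ReducedNetwork", function(object) object@memberNodes)

#' @rdname accessors
#' @export
setGeneric("metaboliteNodes",
           function(object) standardGeneric("metaboliteNodes"))

#' @rdname accessors
#' @export
setMethod("metaboliteNodes", "ReducedNetwork",
          function(object) object@metaboliteNodes)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setMethod("networkEdges", "ReducedNetwork", function(object) object@edges)

#' @rdname accessors
#' @export
setGeneric("hiddenIds", function(object) standardGeneric("hiddenIds"))

#' @rdname accessors
#' @export
setMethod("hiddenIds", "ReducedNetwork", function(object) object@hidden)

#' @rdname accessors
#' @export
setGeneric("nodePositions", function(object) standardGeneric("nodePositions"))

#' @rdname accessors
#' @export
setMethod("nodePositions", "NetworkLayout", function(object) object@positions)

#' @rdname accessors
#' @export
setGeneric("circleRadii", function(object) standardGeneric("circleRadii"))

#' @rdname accessors
#' @export
setMethod("circleRadii", "NetworkLayout", function(object) object@radii)

#' @rdname accessors
#' @export
setGeneric("memberOrder", function(object) standardGeneric("memberOrder"))

#' @rdname accessors
#' @export
setMethod("memberOrder", "NetworkLayout", function(object) object@memberOrder)

#' @rdname accessors
#' @export
setGeneric("styledNodes", function(object) standardGeneric("styledNodes"))

#' @rdname accessors
#' @export
setMethod("styledNodes", "StyledNetwork", function(object) object@nodes)

#' @rdname accessors
#' @export
setGeneric("styledEdges", function(object) standardGeneric("styledEdges"))

#' @rdname accessors
#' @export
setMethod("styledEdges", "StyledNetwork", function(object) object@edges)

setMethod("show", "CommunityModel", function(object) {
  cat("CommunityModel", sQuote(object@modelId), "\n")
  cat("  members (", length(object@members), "): ",
      paste(object@members, collapse = ", "), "\n", sep = "")
  cat("  shared compartment:", object@sharedCompartment, "\n")
  cat("  ", nrow(object@species), " species, ",
      nrow(object@reactions), " reactions, ",
      length(object@compartments), " compartments\n", sep = "")
})

setMethod("show", "ReducedNetwork", function(object) {
  cat("ReducedNetwork:",
      nrow(object@memberNodes), "members,",
      nrow(object@metaboliteNodes), "metabolites,",
      nrow(object@edges), "edges\n")
  nb <- sum(lengths(object@metaboliteNodes$boundary_reaction_ids))
  cat("  boundary exchange reactions:", nb, "\n")
  cat("  hidden elements:", length(object@hidden), "\n")
})

setMethod("show", "NetworkLayout", function(object) {
  cat("NetworkLayout:", nrow(object@positions), "nodes on radii (",
      paste(format(object@radii), collapse = ", "), ")\n")
  cat("  member order:", paste(object@memberOrder, collapse = " -> "), "\n")
})

setMethod("show", "StyledNetwork", function(object) {
  cat("StyledNetwork:", sum(object@nodes$visible), "of", nrow(object@nodes),
      "nodes visible;", sum(object@edges$visible), "of", nrow(object@edges),
      "edges visible\n")
})
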