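EDGE_PALETTES <- list(
  default = c(PRODUCTION = "#1B9E77", CONSUMPTION = "#D62728",
              BIDIRECTIONAL = "#7B3294", INACTIVE = "#BBBBBB",
              UNCONTEXTUALIZED = "#999999"),
  colourblind = c(PRODUCTION = "#0072B2", CONSUMPTION = "#D55E00",
                  BIDIRECTIONAL = "#CC79A7", INACTIVE = "#BBBBBB",
                  UNCONTEXTUALIZED = "#999999")
)
NODE_COLOURS <- c(member = "#4477AA", metabolite = "#DDCC77")
NODE_SIZES <- c(member = 30, metabolite = 10)  # member 3x metabolite diameter
ARROW_OF_CLASS <- c(PRODUCTION = "forward", CONSUMPTION = "reverse",
                    BIDIRECTIONAL = "both", INACTIVE = "none",
                    UNCONTEXTUALIZED = "none")

#' Assemble a styled network document
#'
#' Combines a reduced network, its layout and (optionally) edge
#' classifications into the flat, serializable [StyledNetwork-class] form
#' the exporters consume. Edge colour encodes the direction class
#' (production green, consumption red, bidirectional purple,
#' uncontextualized grey; a colour-blind-safe variant is available), arrows
#' point member-to-metabolite for production, metabolite-to-member for
#' consumption, both ways for bidirectional edges.
#'
#' @param network a [ReducedNetwork-class].
#' @param layout a [NetworkLayout-class] for the same network.
#' @param edge_contexts optional table from [classifyEdgesFBA()] /
#'   [classifyEdgesFVA()]; without it edges are uncontextualized.
#' @param palette `"default"` or `"colourblind"`.
#' @return a [StyledNetwork-class].
#' @export
styleNetwork <- function(network, layout, edge_contexts = NULL,
                         palette = c("default", "colourblind")) {
  palette <- match.arg(palette)
  pal <- EDGE_PALETTES[[palette]]
  pos <- layout@positions
  hidden <- network@hidden

  mem <- network@memberNodes
  met <- network@metaboliteNodes
  nodes <- data.frame(
    id = c(mem$node_id, met$node_id),
    type = c(rep("member", nrow(mem)), rep("metabolite", nrow(met))),
    label = c(mem$member, met$label),
    stringsAsFactors = FALSE
  )
  pi_ <- match(nodes$id, pos$node_id)
  if (anyNA(pi_)) parameterError("layout does not cover every network node")
  nodes$x <- pos$x[pi_]
  nodes$y <- pos$y[pi_]
  nodes$visible <- !(nodes$id %in% hidden)
  nodes$circle <- pos$circle[pi_]
  nodes$colour <- unname(NODE_COLOURS[nodes$type])
  nodes$size <- unname(NODE_SIZES[nodes$type])
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  ed <- network@edges
  if (is.null(edge_contexts)) {
    cls <- rep("UNCONTEXTUALIZED", nrow(ed))
    width <- rep(1, nrow(ed))
  } else {
    ci <- match(ed$edge_id, edge_contexts$edge_id)
    if (anyNA(ci)) parameterError("edge_contexts does not cover every edge")
    cls <- edge_contexts$direction_class[ci]
    width <- edge_contexts$display_width[ci]
  }
  edges <- data.frame(
    id = ed$edge_id,
    reaction_id = ed$reaction_id,
    source = ed$member_node,
    target = ed$metabolite_node,
    direction_class = cls,
    width = width,
    colour = unname(pal[cls]),
    arrow = unname(ARROW_OF_CLASS[cls]),
    visible = !(ed$edge_id %in% hidden),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$id), , drop = FALSE]
  rownames(edges) <- NULL

  new("StyledNetwork", nodes = nodes, edges = edges)
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  gsub("'", "&apos;", x, fixed = TRUE)
}

num15 <- function(x) sprintf("%.15g", x)

#' Write a styled network as GraphML
#'
#' All node and edge fields are emitted as typed GraphML attributes;
#' elements are sorted by ID, so output is byte-identical across runs.
#' Coordinates keep the mathematical convention (y up).
#'
#' @param document a [StyledNetwork-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGraphML <- function(document, path) {
  nodes <- document@nodes
  edges <- document@edges
  node_keys <- data.frame(
    name = c("type", "label", "x", "y", "visible", "circle", "colour", "size"),
    type = c("string", "string", "double", "double", "boolean", "int",
             "string", "double"),
    stringsAsFactors = FALSE
  )
  edge_keys <- data.frame(
    name = c("reaction_id", "direction_class", "width", "colour", "arrow",
             "visible"),
    type = c("string", "string", "double", "string", "string", "boolean"),
    stringsAsFactors = FALSE
  )
  fmtv <- function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else if (is.numeric(v) && !is.integer(v)) num15(v)
    else xmlEscape(as.character(v))
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\" ",
           "xmlns:xsi=\"http://www.w3.org/2001/XMLSchema-instance\" ",
           "xsi:schemaLocation=\"http://graphml.graphdrawing.org/xmlns ",
           "http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd\">"),
    sprintf("  <key id=\"n_%s\" for=\"node\" attr.name=\"%s\" attr.type=\"%s\"/>",
            node_keys$name, node_keys$name, node_keys$type),
    sprintf("  <key id=\"e_%s\" for=\"edge\" attr.name=\"%s\" attr.type=\"%s\"/>",
            edge_keys$name, edge_keys$name, edge_keys$type),
    "  <graph id=\"communet\" edgedefault=\"directed\">"
  )
  for (i in seq_len(nrow(nodes))) {
    lines <- c(lines,
      sprintf("    <node id=\"%s\">", xmlEscape(nodes$id[i])),
      vapply(node_keys$name, function(k) {
        sprintf("      <data key=\"n_%s\">%s</data>", k, fmtv(nodes[[k]][i]))
      }, character(1)),
      "    </node>")
  }
  for (i in seq_len(nrow(edges))) {
    lines <- c(lines,
      sprintf("    <edge id=\"%s\" source=\"%s\" target=\"%s\">",
              xmlEscape(edges$id[i]), xmlEscape(edges$source[i]),
              xmlEscape(edges$target[i])),
      vapply(edge_keys$name, function(k) {
        sprintf("      <data key=\"e_%s\">%s</data>", k, fmtv(edges[[k]][i]))
      }, character(1)),
      "    </edge>")
  }
  lines <- c(lines, "  </graph>", "</graphml>")
  con <- file(path, open = "wb")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  invisible(path)
}

#' Write a styled network as Cytoscape JSON (.cyjs)
#'
#' Emits a Cytoscape-compatible JSON network with position records. The y
#' axis is flipped to the screen convention (y down). Output is sorted and
#' byte-stable.
#'
#' @inheritParams writeGraphML
#' @export
writeCyjs <- function(document, path) {
  nodes <- document@nodes
  edges <- document@edges
  node_list <- lapply(seq_len(nrow(nodes)), function(i) {
    list(
      data = list(
        id = nodes$id[i],
        name = nodes$label[i],
        type = nodes$type[i],
        visible = nodes$visible[i],
        circle = nodes$circle[i],
        colour = nodes$colour[i],
        size = nodes$size[i]
      ),
      position = list(x = nodes$x[i], y = -nodes$y[i])
    )
  })
  edge_list <- lapply(seq_len(nrow(edges)), function(i) {
    list(
      data = list(
        id = edges$id[i],
        source = edges$source[i],
        target = edges$target[i],
        reaction_id = edges$reaction_id[i],
        direction_class = edges$direction_class[i],
        width = edges$width[i],
        colour = edges$colour[i],
        arrow = edges$arrow[i],
        visible = edges$visible[i]
      )
    )
  })
  doc <- list(
    format_version = "1.0",
    generated_by = "communet",
    target_cytoscapejs_version = "~2.1",
    data = list(name = "communet network"),
    elements = list(nodes = node_list, edges = edge_list)
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(path, open = "wb")
  writeLines(json, con, useBytes = TRUE)
  close(con)
  invisible(path)
}

#' Read a .cyjs file back into plain node/edge tables
#'
#' Convenience reader used for round-trip checks and downstream scripting.
#'
#' @param path a file written by [writeCyjs()].
#' @return list with `nodes` and `edges` data.frames.
#' @export
readCyjs <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  nodes <- cbind(doc$elements$nodes$data, doc$elements$nodes$position)
  edges <- doc$elements$edges$data
  list(nodes = nodes, edges = edges)
}

arrowheadPoints <- function(x0, y0, x1, y1, at, size = 8) {
  ## triangle tip at the 'at' end (1 = target, 0 = source), pointing outward
  dx <- x1 - x0; dy <- y1 - y0
  len <- sqrt(dx^2 + dy^2)
  if (len < 1e-12) return(NULL)
  ux <- dx / len; uy <- dy / len
  if (at == 0) { ux <- -ux; uy <- -uy; tipx <- x0; tipy <- y0 }
  else { tipx <- x1; tipy <- y1 }
  bx <- tipx - ux * size; by <- tipy - uy * size
  px <- -uy; py <- ux
  matrix(c(tipx, tipy,
           bx + px * size / 2, by + py * size / 2,
           bx - px * size / 2, by - py * size / 2),
         ncol = 2, byrow = TRUE)
}

svgColourLegend <- function(pal, x, y) {
  entries <- c("PRODUCTION", "CONSUMPTION", "BIDIRECTIONAL")
  out <- sprintf("  <g id=\"legend\">")
  for (i in seq_along(entries)) {
    yy <- y + (i - 1) * 22
    out <- c(out,
      sprintf(paste0("    <rect x=\"%s\" y=\"%s\" width=\"16\" height=\"16\"",
                     " fill=\"%s\"/>"),
              num15(x), num15(yy), pal[[entries[i]]]),
      sprintf("    <text x=\"%s\" y=\"%s\" font-size=\"14\">%s</text>",
              num15(x + 22), num15(yy + 13), tolower(entries[i])))
  }
  c(out, "  </g>")
}

#' Render a styled network to SVG or PNG
#'
#' Hidden elements are not drawn. Members always carry labels; metabolite
#' labels are drawn only when at most 50 metabolites are visible.
#' Bidirectional edges get an arrowhead at both ends. SVG output is plain
#' deterministic text; PNG re-draws the same primitives through the
#' grDevices png device.
#'
#' @param document a [StyledNetwork-class] with positions.
#' @param path output file path.
#' @param format `"svg"` or `"png"`.
#' @param legend draw a colour legend for the direction classes.
#' @param palette palette used for the legend swatches.
#' @param dpi raster resolution for PNG output (default 300).
#' @return invisibly, the path.
#' @export
renderFigure <- function(document, path, format = c("svg", "png"),
                         legend = TRUE,
                         palette = c("default", "colourblind"),
                         dpi = 300) {
  if (!is.character(format) || !all(format %in% c("svg", "png"))) {
    parameterError(paste0("unknown figure format: ",
                          paste(setdiff(format, c("svg", "png")),
                                collapse = ", ")))
  }
  format <- match.arg(format)
  palette <- match.arg(palette)
  nodes <- document@nodes
  edges <- document@edges
  vis_n <- nodes[nodes$visible, , drop = FALSE]
  vis_e <- edges[edges$visible, , drop = FALSE]
  extent <- max(1, abs(vis_n$x), abs(vis_n$y),
                if (nrow(nodes)) abs(nodes$x) else 0,
                if (nrow(nodes)) abs(nodes$y) else 0)
  pad <- 60
  half <- extent + pad
  label_mets <- sum(vis_n$type == "metabolite") <= 50

  if (format == "png") {
    renderPNG(document, path, legend, palette, dpi, half, label_mets)
    return(invisible(path))
  }

  ## screen coordinates: shift origin to centre, flip y
  sx <- function(x) num15(x + half)
  sy <- function(y) num15(half - y)
  np <- nodes[, c("x", "y"), drop = FALSE]
  rownames(np) <- nodes$id

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "width=\"%s\" height=\"%s\" viewBox=\"0 0 %s %s\">"),
            num15(2 * half), num15(2 * half), num15(2 * half),
            num15(2 * half)),
    "  <rect width=\"100%\" height=\"100%\" fill=\"white\"/>"
  )
  for (i in seq_len(nrow(vis_e))) {
    s <- np[vis_e$source[i], ]
    t <- np[vis_e$target[i], ]
    lines <- c(lines, sprintf(
      paste0("  <g class=\"edge\" id=\"edge-%s\">",
             "<line x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
             "stroke=\"%s\" stroke-width=\"%s\"/>"),
      xmlEscape(vis_e$id[i]), sx(s$x), sy(s$y), sx(t$x), sy(t$y),
      vis_e$colour[i], num15(max(vis_e$width[i], 0.5))))
    ends <- switch(vis_e$arrow[i],
                   forward = 1, reverse = 0, both = c(0, 1), numeric(0))
    for (at in ends) {
      tri <- arrowheadPoints(s$x + half, half - s$y,
                             t$x + half, half - t$y, at)
      if (!is.null(tri)) {
        lines <- c(lines, sprintf(
          "    <polygon points=\"%s\" fill=\"%s\"/>",
          paste(sprintf("%s,%s", num15(tri[, 1]), num15(tri[, 2])),
                collapse = " "),
          vis_e$colour[i]))
      }
    }
    lines <- c(lines, "  </g>")
  }
  for (i in seq_len(nrow(vis_n))) {
    lines <- c(lines, sprintf(
      "  <circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" stroke=\"#333333\"/>",
      sx(vis_n$x[i]), sy(vis_n$y[i]), num15(vis_n$size[i] / 2),
      vis_n$colour[i]))
    if (vis_n$type[i] == "member" ||
        (vis_n$type[i] == "metabolite" && label_mets)) {
      lines <- c(lines, sprintf(
        paste0("  <text x=\"%s\" y=\"%s\" font-size=\"13\" ",
               "text-anchor=\"middle\">%s</text>"),
        sx(vis_n$x[i]), num15(half - vis_n$y[i] - vis_n$size[i] / 2 - 4),
        xmlEscape(vis_n$label[i])))
    }
  }
  if (legend) {
    lines <- c(lines, svgColourLegend(EDGE_PALETTES[[palette]], 16, 16))
  }
  lines <- c(lines, "</svg>")
  con <- file(path, open = "wb")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  invisible(path)
}

renderPNG <- function(document, path, legend, palette, dpi, half,
                      label_mets) {
  nodes <- document@nodes
  edges <- document@edges
  vis_n <- nodes[nodes$visible, , drop = FALSE]
  vis_e <- edges[edges$visible, , drop = FALSE]
  px <- round(2 * half * dpi / 150)
  grDevices::png(path, width = px, height = px, res = dpi / 1.5)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(-half, half), ylim = c(-half, half),
                        asp = 1)
  np <- nodes
  rownames(np) <- np$id
  for (i in seq_len(nrow(vis_e))) {
    s <- np[vis_e$source[i], ]
    t <- np[vis_e$target[i], ]
    graphics::segments(s$x, s$y, t$x, t$y, col = vis_e$colour[i],
                       lwd = max(vis_e$width[i], 0.5))
    ends <- switch(vis_e$arrow[i],
                   forward = 1, reverse = 0, both = c(0, 1), numeric(0))
    for (at in ends) {
      tri <- arrowheadPoints(s$x, s$y, t$x, t$y, at)
      if (!is.null(tri)) {
        graphics::polygon(tri[, 1], tri[, 2], col = vis_e$colour[i],
                          border = NA)
      }
    }
  }
  graphics::points(vis_n$x, vis_n$y, pch = 21, bg = vis_n$colour,
                   cex = vis_n$size / 10)
  lab <- vis_n$type == "member" | (vis_n$type == "metabolite" & label_mets)
  if (any(lab)) {
    graphics::text(vis_n$x[lab], vis_n$y[lab] + vis_n$size[lab] / 2 + 8,
                   vis_n$label[lab], cex = 0.7)
  }
  if (legend) {
    pal <- EDGE_PALETTES[[palette]]
    graphics::legend("topleft",
                     legend = tolower(c("PRODUCTION", "CONSUMPTION",
                                        "BIDIRECTIONAL")),
                     col = pal[c("PRODUCTION", "CONSUMPTION",
                                 "BIDIRECTIONAL")],
                     lwd = 3, bty = "n", cex = 0.8)
  }
  invisible(path)
}
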