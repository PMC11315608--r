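DEFAULT_RADII <- c(400, 280, 180, 90)
MIN_ANGULAR_SEP <- 2 * pi / 180  # 2 degrees

#' Order community members around the layout circle
#'
#' Chooses the circular member order that maximizes the number of two-member
#' metabolites whose two partners end up adjacent: the objective is the sum,
#' over adjacent member pairs, of the number of metabolite nodes connected
#' to exactly that pair. Communities of up to 8 members are solved exactly
#' by exhaustive search over circular permutations; larger communities use a
#' greedy heaviest-pair insertion heuristic. Ties break lexicographically,
#' so the result is deterministic.
#'
#' @param network a [ReducedNetwork-class].
#' @return character vector of member node IDs in circular order, starting
#'   at the lexicographically smallest member node.
#' @export
orderMembers <- function(network) {
  mem <- sort(network@memberNodes$node_id)
  m <- length(mem)
  if (m <= 2L) return(mem)

  w <- pairWeights(network)
  obj <- function(ord) {
    nxt <- c(ord[-1], ord[1])
    sum(vapply(seq_along(ord), function(i)
      pairWeight(w, ord[i], nxt[i]), numeric(1)))
  }

  if (m <= 8L) {
    best <- NULL
    best_obj <- -Inf
    for (perm in permutationsLex(mem[-1])) {
      ord <- c(mem[1], perm)
      o <- obj(ord)
      if (o > best_obj + 1e-12) {
        best <- ord
        best_obj <- o
      }
    }
    return(best)
  }

  greedyOrder(mem, w, obj)
}

pairWeights <- function(network) {
  ed <- network@edges
  deg2 <- Filter(function(x) length(x) == 2L,
                 lapply(split(ed$member_node, ed$metabolite_node), unique))
  if (!length(deg2)) return(list())
  keys <- vapply(deg2, function(p) paste(sort(p), collapse = "\r"),
                 character(1))
  as.list(table(keys))
}

pairWeight <- function(w, a, b) {
  k <- paste(sort(c(a, b)), collapse = "\r")
  if (is.null(w[[k]])) 0 else as.numeric(w[[k]])
}

## all permutations of a sorted character vector, in lexicographic order
permutationsLex <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutationsLex(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

greedyOrder <- function(mem, w, obj) {
  pairs <- t(utils::combn(mem, 2L))
  wt <- apply(pairs, 1L, function(p) pairWeight(w, p[1], p[2]))
  o <- order(-wt, pairs[, 1], pairs[, 2])
  frag <- as.list(mem)           # path fragments
  find_frag <- function(node) {
    for (i in seq_along(frag)) {
      f <- frag[[i]]
      if (node == f[1] || node == f[length(f)]) return(i)
    }
    0L
  }
  for (k in o) {
    if (wt[k] == 0) break
    a <- pairs[k, 1]; b <- pairs[k, 2]
    ia <- find_frag(a); ib <- find_frag(b)
    if (ia == 0L || ib == 0L || ia == ib) next
    fa <- frag[[ia]]; fb <- frag[[ib]]
    if (fa[length(fa)] != a) fa <- rev(fa)
    if (fb[1] != b) fb <- rev(fb)
    frag[[ia]] <- c(fa, fb)
    frag[[ib]] <- NULL
  }
  frag <- frag[order(vapply(frag, `[`, character(1), 1L))]
  ord <- unlist(frag)
  ## canonical start + orientation
  i0 <- which(ord == min(ord))
  ord <- c(ord[i0:length(ord)], ord[seq_len(i0 - 1L)])
  if (length(ord) > 2L && ord[length(ord)] < ord[2]) {
    ord <- c(ord[1], rev(ord[-1]))
  }
  ord
}

#' Assign layout circles from member-degree
#'
#' Circle 1 (outermost): metabolites connected to a single member; circle 2:
#' the community members; circle 3: metabolites connected to exactly two
#' members; circle 4 (innermost): hub metabolites with three or more member
#' partners. Degrees count distinct members over visible and hidden edges.
#'
#' @param network a [ReducedNetwork-class].
#' @return named integer vector node ID -> circle index (1-4).
#' @export
assignCircles <- function(network) {
  deg <- memberDegree(network)
  met_circle <- ifelse(deg == 1L, 1L, ifelse(deg == 2L, 3L, 4L))
  c(setNames(rep(2L, nrow(network@memberNodes)),
             network@memberNodes$node_id),
    setNames(as.integer(met_circle), names(deg)))
}

#' Compute concentric-circle node positions
#'
#' Members are evenly spaced on circle 2, with the first member of `order`
#' at angle 0 and the order running counter-clockwise. Private metabolites
#' spread evenly in the angular sector (half-width `pi/m`) centred on their
#' sole member; two-member metabolites sit at the mid-angle of the shorter
#' arc between their two members (which is the midpoint between adjacent
#' members); hub metabolites are evenly spaced on the innermost circle.
#' Nodes sharing a circle are kept at least 2 degrees apart by deterministic
#' angular nudging. Positions are computed in a canonical frame and globally
#' rotated, so rotating `order` by k positions rotates every position by
#' exactly `2*pi*k/m`.
#'
#' @param network a [ReducedNetwork-class].
#' @param order circular member-node order, defaults to [orderMembers()].
#' @param radii numeric(4), strictly decreasing circle radii (arbitrary
#'   length units); default `c(400, 280, 180, 90)`.
#' @return a [NetworkLayout-class].
#' @export
computePositions <- function(network, order = orderMembers(network),
                             radii = DEFAULT_RADII) {
  if (length(radii) != 4L || any(diff(radii) >= 0) || any(radii <= 0)) {
    parameterError("radii must be 4 strictly decreasing positive numbers")
  }
  mem_ids <- network@memberNodes$node_id
  if (!setequal(order, mem_ids) || anyDuplicated(order)) {
    parameterError("order must be a permutation of the member node IDs")
  }
  m <- length(order)

  ## canonical frame: lexicographically smallest member at angle 0
  j <- which(order == min(order))
  canonical <- c(order[j:m], order[seq_len(j - 1L)])
  phase <- 2 * pi * (j - 1L) / m

  theta_mem <- setNames(2 * pi * (seq_len(m) - 1L) / m, canonical)

  deg <- memberDegree(network)
  circ <- assignCircles(network)
  ed <- network@edges
  met_members <- lapply(
    setNames(network@metaboliteNodes$node_id,
             network@metaboliteNodes$node_id),
    function(nid) sort(unique(ed$member_node[ed$metabolite_node == nid])))

  desired <- function(nid) {
    mm <- met_members[[nid]]
    if (length(mm) == 1L) return(NA_real_)      # handled per-member sector
    if (length(mm) == 2L) return(shorterArcMid(theta_mem[[mm[1]]],
                                               theta_mem[[mm[2]]]))
    NA_real_
  }

  ang <- c(theta_mem)

  ## circle 1: per-member sectors
  c1 <- names(circ)[circ == 1L]
  for (mn in canonical) {
    mine <- sort(c1[vapply(c1, function(nid)
      met_members[[nid]][1] == mn, logical(1))])
    n <- length(mine)
    if (!n) next
    half <- pi / m
    offs <- half * (2 * seq_len(n) - n - 1) / n
    ang[mine] <- theta_mem[[mn]] + offs
  }

  ## circle 3: shorter-arc midpoints
  c3 <- sort(names(circ)[circ == 3L])
  for (nid in c3) ang[[nid]] <- desired(nid)

  ## circle 4: even spacing in the canonical frame
  c4 <- sort(names(circ)[circ == 4L])
  if (length(c4)) {
    ang[c4] <- 2 * pi * (seq_along(c4) - 1L) / length(c4)
  }

  ## per-circle collision resolution (members already evenly spaced)
  for (ci in c(1L, 3L, 4L)) {
    ids <- names(circ)[circ == ci]
    if (length(ids) > 1L) {
      ang[ids] <- resolveCollisions(ang[ids], MIN_ANGULAR_SEP)
    }
  }

  ang <- (ang + phase) %% (2 * pi)
  node_ids <- names(ang)
  r <- radii[circ[node_ids]]
  positions <- data.frame(
    node_id = node_ids,
    circle = as.integer(circ[node_ids]),
    angle = unname(ang),
    x = unname(r * cos(ang)),
    y = unname(r * sin(ang)),
    stringsAsFactors = FALSE
  )
  rownames(positions) <- NULL
  new("NetworkLayout", positions = positions, radii = as.numeric(radii),
      memberOrder = order)
}

## mid-angle of the shorter arc between two angles; antipodal tie broken
## towards counter-clockwise from the first (smaller-angle) member
shorterArcMid <- function(a, b) {
  d <- (b - a) %% (2 * pi)
  if (d <= pi + 1e-12) (a + d / 2) %% (2 * pi) else (b + (2 * pi - d) / 2) %% (2 * pi)
}

## deterministic angular nudging: nodes at identical desired angles are
## spread symmetrically, then a sequential sweep enforces the minimum
## separation; an overcrowded circle falls back to even spacing
resolveCollisions <- function(angles, delta) {
  n <- length(angles)
  if (n * delta >= 2 * pi) {
    o <- order(angles, names(angles))
    angles[o] <- min(angles) + 2 * pi * (seq_len(n) - 1L) / n
    return(angles %% (2 * pi))
  }
  key <- round(angles / 1e-9)
  for (k in unique(key)) {
    grp <- names(angles)[key == k]
    g <- length(grp)
    if (g > 1L) {
      grp <- sort(grp)
      angles[grp] <- angles[grp] + delta * (seq_len(g) - (g + 1) / 2)
    }
  }
  o <- order(angles, names(angles))
  a <- angles[o]
  for (i in seq_len(n)[-1]) {
    if (a[i] - a[i - 1] < delta - 1e-12) a[i] <- a[i - 1] + delta
  }
  ## wrap-around: push the first node forward if the cycle closes too tight
  guard <- 0L
  while (n > 1L && (a[1] + 2 * pi) - a[n] < delta - 1e-12 && guard < n) {
    a <- c(a[-1], a[1] + 2 * pi)
    o <- c(o[-1], o[1])
    for (i in seq_len(n)[-1]) {
      if (a[i] - a[i - 1] < delta - 1e-12) a[i] <- a[i - 1] + delta
    }
    guard <- guard + 1L
  }
  angles[o] <- a %% (2 * pi)
  angles
}
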