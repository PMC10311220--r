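#' Read an arbor from an SWC file
#'
#' Standard 7-column SWC (`id type x y z radius parent`), `#` comments
#' allowed. Type codes are kept but only the root (parent -1) is
#' interpreted, as the soma.
#'
#' @param path SWC file path.
#' @return an [Arbor-class].
#' @export
readSWC <- function(path) {
  nd <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z",
                                        "radius", "parent"))
  Arbor(nd)
}

#' Write an arbor to an SWC file
#'
#' @param arbor an [Arbor-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSWC <- function(arbor, path) {
  nd <- arborNodes(arbor)
  lines <- sprintf("%d %d %.6f %.6f %.6f %.3f %d",
                   as.integer(nd$id), as.integer(nd$type),
                   nd$x, nd$y, nd$z, nd$radius, as.integer(nd$parent))
  writeLines(c("# SWC", lines), path)
  invisible(path)
}

## edge table: one row per non-root node, joining child to parent coordinates
arborEdges <- function(arbor) {
  nd <- arborNodes(arbor)
  idx <- match(nd$parent, nd$id)
  child <- which(nd$parent != -1)
  p <- idx[child]
  data.frame(
    childId = nd$id[child], parentId = nd$id[p],
    x0 = nd$x[p], y0 = nd$y[p], z0 = nd$z[p],
    x1 = nd$x[child], y1 = nd$y[child], z1 = nd$z[child],
    len = sqrt((nd$x[child] - nd$x[p])^2 + (nd$y[child] - nd$y[p])^2 +
               (nd$z[child] - nd$z[p])^2)
  )
}

#' Sholl profile of an arbor
#'
#' Counts, for concentric circles (spheres, in 3D) of increasing radius
#' about the soma, the exact number of intersection points the traced
#' processes make with each circle. Each tree edge is a straight segment;
#' intersections are found by solving the circle-segment quadratic.
#' A tangency counts once, and a node lying exactly on a circle counts once
#' across its incident edges.
#'
#' @param arbor an [Arbor-class].
#' @param params a [shollParams()] block (`step`, default 5 um; `rMax`
#'   defaults to the farthest node distance).
#' @return a data.frame of class `"ShollProfile"` with columns `radius`
#'   (um) and `crossings`.
#' @examples
#' nd <- data.frame(id = 1:2, type = c(1, 5), x = c(0, 100), y = 0, z = 0,
#'                  radius = 1, parent = c(-1, 1))
#' shollProfile(Arbor(nd), shollParams(step = 10))
#' @export
shollProfile <- function(arbor, params = shollParams()) {
  nd <- arborNodes(arbor)
  soma <- nd[nd$id == somaId(arbor), ]
  cx <- soma$x; cy <- soma$y; cz <- soma$z
  node_d <- sqrt((nd$x - cx)^2 + (nd$y - cy)^2 + (nd$z - cz)^2)
  r_max <- if (is.null(params$rMax)) max(node_d) else params$rMax
  radii <- seq(params$step, by = params$step,
               length.out = max(0L, floor(r_max / params$step + 1e-9)))
  if (!length(radii)) {
    out <- data.frame(radius = numeric(0), crossings = integer(0))
    class(out) <- c("ShollProfile", "data.frame")
    return(out)
  }
  ed <- arborEdges(arbor)
  tol <- 1e-9
  if (!nrow(ed)) {
    out <- data.frame(radius = radii, crossings = 0L)
    class(out) <- c("ShollProfile", "data.frame")
    return(out)
  }
  # quadratic |P + t D|^2 = r^2 per edge, P relative to the soma
  px <- ed$x0 - cx; py <- ed$y0 - cy; pz <- ed$z0 - cz
  dx <- ed$x1 - ed$x0; dy <- ed$y1 - ed$y0; dz <- ed$z1 - ed$z0
  a <- dx^2 + dy^2 + dz^2
  b <- 2 * (px * dx + py * dy + pz * dz)
  c0 <- px^2 + py^2 + pz^2

  crossings <- integer(length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    # nodes exactly on the circle count once each
    n_vertex <- sum(abs(node_d - r) < tol)
    cc <- c0 - r^2
    disc <- b^2 - 4 * a * cc
    n_int <- 0L
    pos <- which(a > 0 & disc > -tol)
    for (k in pos) {
      if (disc[k] <= tol * a[k]^2) {        # tangency: one root
        t1 <- -b[k] / (2 * a[k])
        ts <- t1
      } else {
        s <- sqrt(disc[k])
        ts <- c((-b[k] - s) / (2 * a[k]), (-b[k] + s) / (2 * a[k]))
      }
      # strictly interior roots; endpoint hits are the vertex cases above
      n_int <- n_int + sum(ts > tol & ts < 1 - tol)
    }
    crossings[i] <- n_int + n_vertex
  }
  out <- data.frame(radius = radii, crossings = crossings)
  class(out) <- c("ShollProfile", "data.frame")
  out
}

## per-node downstream reach: max path length from the node to any terminal
## of its subtree; computed bottom-up over a topological order
downstreamReach <- function(nd, ed) {
  reach <- stats::setNames(rep(0, nrow(nd)), nd$id)
  # process nodes in decreasing depth
  depth <- stats::setNames(rep(0L, nrow(nd)), nd$id)
  parent_of <- stats::setNames(nd$parent, nd$id)
  for (v in nd$id) {
    u <- v; dpt <- 0L
    while (parent_of[[as.character(u)]] != -1) {
      u <- parent_of[[as.character(u)]]
      dpt <- dpt + 1L
    }
    depth[[as.character(v)]] <- dpt
  }
  ord <- names(sort(depth, decreasing = TRUE))
  for (v in ord) {
    e <- ed[ed$parentId == as.numeric(v), , drop = FALSE]
    if (nrow(e)) {
      reach[[v]] <- max(e$len +
                          reach[as.character(e$childId)])
    }
  }
  list(reach = reach, depth = depth)
}

#' Branch morphometrics of a traced arbor
#'
#' Quantifies the arbor the way astrocyte tracings are scored: main
#' branches are processes originating directly at the soma, measured from
#' the soma base to the longest terminal on the branch; junction-free
#' projections shorter than `minMainBranch` are not counted as main
#' branches. A junction is an internal branching node whose side process
#' (measured to the farthest terminal of the side subtree) is at least
#' `minJunctionBranch` long — shorter projections are not counted as
#' junctions. Total process length sums every traced segment, including
#' sub-threshold stubs.
#'
#' @param arbor an [Arbor-class].
#' @param params a [morphometryParams()] block (5 um junction filter,
#'   10 um main-branch floor by default).
#' @return a list of class `"MorphometricsResult"`: `nMainBranches`,
#'   `longestMainBranch` (um), `totalProcessLength` (um), `nJunctions`.
#' @examples
#' nd <- data.frame(id = 1:3, type = c(1, 5, 5), x = c(0, 25, 50),
#'                  y = 0, z = 0, radius = 1, parent = c(-1, 1, 2))
#' branchMorphometrics(Arbor(nd))  # one 50 um unbranched main branch
#' @export
branchMorphometrics <- function(arbor, params = morphometryParams()) {
  nd <- arborNodes(arbor)
  ed <- arborEdges(arbor)
  if (!nrow(ed)) {
    return(structure(list(nMainBranches = 0L, longestMainBranch = 0,
                          totalProcessLength = 0, nJunctions = 0L),
                     class = "MorphometricsResult"))
  }
  dr <- downstreamReach(nd, ed)
  reach <- dr$reach

  # junctions: non-soma nodes with >= 2 children where at least one
  # non-principal child path is long enough
  isJunction <- function(v) {
    e <- ed[ed$parentId == v, , drop = FALSE]
    if (nrow(e) < 2) return(FALSE)
    ext <- e$len + reach[as.character(e$childId)]
    side <- sort(ext, decreasing = TRUE)[-1]   # all but the main continuation
    any(side >= params$minJunctionBranch)
  }

  internal <- setdiff(unique(ed$parentId), somaId(arbor))
  junction_nodes <- internal[vapply(internal, isJunction, FALSE)]

  # count junctions per soma-child subtree to apply the main-branch filter
  parent_of <- stats::setNames(nd$parent, nd$id)
  somaChildOf <- function(v) {
    while (parent_of[[as.character(v)]] != somaId(arbor)) {
      v <- parent_of[[as.character(v)]]
    }
    v
  }
  soma_edges <- ed[ed$parentId == somaId(arbor), , drop = FALSE]
  n_main <- 0L
  longest <- 0
  for (k in seq_len(nrow(soma_edges))) {
    child <- soma_edges$childId[k]
    extent <- soma_edges$len[k] + reach[[as.character(child)]]
    nj <- if (length(junction_nodes)) {
      sum(vapply(junction_nodes, somaChildOf, 0) == child)
    } else 0L
    if (nj == 0L && extent < params$minMainBranch) next  # small stub
    n_main <- n_main + 1L
    longest <- max(longest, extent)
  }

  structure(list(
    nMainBranches = n_main,
    longestMainBranch = longest,
    totalProcessLength = sum(ed$len),
    nJunctions = length(junction_nodes)
  ), class = "MorphometricsResult")
}

#' Astrocyte density in distance zones around an aggregate
#'
#' Assigns each cell position to a distance band measured from the
#' perimeter of a circular aggregate (`d = |point - center| - radius`,
#' band membership `inner <= d < outer`), and reports per-band counts,
#' annulus areas and densities.
#'
#' @param points numeric matrix or data.frame with two columns (x, y) in
#'   micrometres.
#' @param spec a [zoneSpec()] block (default bands: 50-200, 200-400,
#'   400-600 um from the perimeter).
#' @return a data.frame of class `"ZoneDensity"` with columns `inner`,
#'   `outer` (um from perimeter), `count`, `areaMm2`, `densityPerMm2`;
#'   the number of points falling in no band (including any inside the
#'   aggregate, which triggers a warning) is in `attr(, "unassigned")`.
#' @examples
#' zs <- zoneSpec(radius = 250)
#' zoneDensity(cbind(c(350, 550, 950), 0), zs)
#' @export
zoneDensity <- function(points, spec) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  d <- sqrt((pts[, 1] - spec$center[1])^2 +
            (pts[, 2] - spec$center[2])^2) - spec$radius
  if (any(d < 0)) {
    warning(sum(d < 0), " point(s) inside the aggregate; left unassigned")
  }
  assigned <- rep(FALSE, length(d))
  rows <- lapply(spec$bands, function(b) {
    inb <- d >= b[1] & d < b[2]
    assigned <<- assigned | inb
    area_um2 <- pi * ((spec$radius + b[2])^2 - (spec$radius + b[1])^2)
    area_mm2 <- area_um2 * 1e-6
    data.frame(inner = b[1], outer = b[2], count = sum(inb),
               areaMm2 = area_mm2, densityPerMm2 = sum(inb) / area_mm2)
  })
  out <- do.call(rbind, rows)
  attr(out, "unassigned") <- sum(!assigned)
  class(out) <- c("ZoneDensity", "data.frame")
  out
}
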