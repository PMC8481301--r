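#' Build a triangulated 2D thorax domain with 16 boundary electrodes
#'
#' Constructs a structured triangular (P1) mesh on a disk or ellipse,
#' normalized to unit bounding radius, with 16 equally spaced electrodes on
#' the boundary. Each electrode is a contiguous group of boundary edges
#' spanning 11.25 degrees (half of its 22.5-degree sector), centred on the
#' electrode's nominal angular position.
#'
#' Orientation convention (the single convention all downstream orientation
#' logic relies on): positive y is ventral, positive x is the subject's
#' left, so the subject's right lung sits at x < 0. Electrode 1 is centred
#' on the ventral midline (top of the plot) and numbering proceeds
#' clockwise as plotted.
#'
#' @param shape `"circle"` or `"ellipse"`. The ellipse is a thorax-like
#'   domain with semi-axes `1` (lateral) and `axis_ratio` (ventral-dorsal).
#' @param refinement Integer >= 1. The mesh has `32 * refinement` boundary
#'   nodes and `6 * refinement` concentric node rings; element count grows
#'   quadratically with `refinement`.
#' @param axis_ratio Ventral-dorsal semi-axis of the ellipse (ignored for
#'   `"circle"`); must lie in (0, 1].
#' @return An object of class `eit_mesh`: a list with `nodes` (n x 2),
#'   `elements` (m x 3, counter-clockwise), `boundary_edges` (ordered
#'   node-index pairs around the boundary), `electrodes` (list of 16
#'   integer vectors of boundary-edge indices), and the semi-axes `a`, `b`.
#' @examples
#' m <- build_thorax_mesh("circle", 1)
#' nrow(m$elements)
#' @export
build_thorax_mesh <- function(shape = c("circle", "ellipse"), refinement = 2,
                              axis_ratio = 0.8) {
  shape <- match.arg(shape)
  if (!is.numeric(refinement) || length(refinement) != 1L ||
      refinement < 1 || refinement != round(refinement)) {
    stop_param("`refinement` must be a positive integer (got %s)",
               deparse(refinement))
  }
  refinement <- as.integer(refinement)
  n_theta <- 32L * refinement          # boundary nodes / edges per ring
  n_rings <- 6L * refinement           # rings excluding the centre node
  d_theta <- 2 * pi / n_theta
  # offset by half the electrode width so electrode k is centred at
  # pi/2 - (k-1)*pi/8 (electrode 1 ventral, clockwise numbering)
  theta0 <- pi / 2 + pi / 32
  theta <- theta0 - (seq_len(n_theta) - 1L) * d_theta

  # bit-exact mirror symmetry about the ventral-dorsal axis: node j and
  # its mirror partner get exactly opposite x and identical y, so that
  # right/left comparisons downstream are symmetric to solver precision
  xs <- cos(theta); ys <- sin(theta)
  mirror_j <- ((refinement + 1L - seq_len(n_theta)) %% n_theta) + 1L
  for (j in seq_len(n_theta)) {
    k <- mirror_j[j]
    if (k > j) {
      xs[k] <- -xs[j]; ys[k] <- ys[j]
    } else if (k == j) {
      xs[j] <- 0
    }
  }
  nodes <- matrix(0, nrow = 1L + n_rings * n_theta, ncol = 2L)
  for (i in seq_len(n_rings)) {
    r <- i / n_rings
    idx <- 1L + (i - 1L) * n_theta + seq_len(n_theta)
    nodes[idx, 1L] <- r * xs
    nodes[idx, 2L] <- r * ys
  }
  ring_idx <- function(i) 1L + (i - 1L) * n_theta + seq_len(n_theta)
  nxt <- c(seq_len(n_theta)[-1L], 1L)

  elems <- vector("list", n_rings)
  r1 <- ring_idx(1L)
  elems[[1L]] <- cbind(1L, r1, r1[nxt])
  if (n_rings > 1L) {
    for (i in seq_len(n_rings - 1L)) {
      a <- ring_idx(i); b <- ring_idx(i + 1L)
      # choose the quad diagonal by the sign of the quad-centre x so the
      # triangulation is mirror-symmetric about the ventral-dorsal axis;
      # quads straddling the axis (centre x exactly 0 by construction)
      # cannot be split symmetrically in two and get a centre node and a
      # 4-way split instead
      cx <- nodes[a, 1L] + nodes[a[nxt], 1L] + nodes[b, 1L] +
        nodes[b[nxt], 1L]
      pos <- cx > 0; neg <- cx < 0; mid <- cx == 0
      quads <- rbind(
        cbind(a[pos], a[nxt][pos], b[nxt][pos]),
        cbind(a[pos], b[nxt][pos], b[pos]),
        cbind(a[neg], a[nxt][neg], b[neg]),
        cbind(a[nxt][neg], b[nxt][neg], b[neg])
      )
      if (any(mid)) {
        for (j in which(mid)) {
          quad <- c(a[j], a[nxt][j], b[nxt][j], b[j])
          p <- nrow(nodes) + 1L
          nodes <- rbind(nodes, c(0, mean(nodes[quad, 2L])))
          quads <- rbind(quads,
                         cbind(quad, quad[c(2L, 3L, 4L, 1L)], p,
                               deparse.level = 0))
        }
      }
      elems[[i + 1L]] <- quads
    }
  }
  elements <- do.call(rbind, elems)
  dimnames(elements) <- NULL

  a <- 1; b <- 1
  if (shape == "ellipse") {
    if (!is.numeric(axis_ratio) || axis_ratio <= 0 || axis_ratio > 1) {
      stop_param("`axis_ratio` must be in (0, 1]")
    }
    b <- axis_ratio
    nodes[, 2L] <- nodes[, 2L] * b
  }

  # enforce counter-clockwise orientation
  ar <- tri_signed_areas(nodes, elements)
  flip <- ar < 0
  if (any(flip)) {
    elements[flip, 2:3] <- elements[flip, 3:2]
  }

  outer <- ring_idx(n_rings)
  boundary_edges <- cbind(outer, outer[nxt], deparse.level = 0)

  # electrode k occupies `refinement` consecutive boundary edges starting
  # at edge (k-1)*2*refinement + 1
  electrodes <- lapply(seq_len(16L), function(k) {
    (k - 1L) * 2L * refinement + seq_len(refinement)
  })

  mesh <- structure(list(
    nodes = nodes, elements = elements, boundary_edges = boundary_edges,
    electrodes = electrodes, shape = shape, a = a, b = b,
    refinement = refinement
  ), class = "eit_mesh")
  validate_mesh(mesh)
  mesh
}

tri_signed_areas <- function(nodes, elements) {
  x1 <- nodes[elements[, 1L], 1L]; y1 <- nodes[elements[, 1L], 2L]
  x2 <- nodes[elements[, 2L], 1L]; y2 <- nodes[elements[, 2L], 2L]
  x3 <- nodes[elements[, 3L], 1L]; y3 <- nodes[elements[, 3L], 2L]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' Element areas of a mesh
#' @param mesh An `eit_mesh`.
#' @return Numeric vector of (positive) element areas.
#' @export
element_areas <- function(mesh) {
  abs(tri_signed_areas(mesh$nodes, mesh$elements))
}

#' Element centroids of a mesh
#' @param mesh An `eit_mesh`.
#' @return An m x 2 matrix of centroid coordinates.
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$elements[, 1L], , drop = FALSE] +
     mesh$nodes[mesh$elements[, 2L], , drop = FALSE] +
     mesh$nodes[mesh$elements[, 3L], , drop = FALSE]) / 3
}

validate_mesh <- function(mesh) {
  if (any(tri_signed_areas(mesh$nodes, mesh$elements) <= 0)) {
    stop_param("mesh has non-positive element areas")
  }
  if (length(mesh$electrodes) != 16L) {
    stop_param("mesh must carry 16 electrodes (found %d)",
               length(mesh$electrodes))
  }
  if (anyDuplicated(unlist(mesh$electrodes))) {
    stop_param("electrode edge groups overlap")
  }
  invisible(mesh)
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf("EIT mesh (%s, a = %g, b = %g): %d nodes, %d elements, %d electrodes\n",
              x$shape, x$a, x$b, nrow(x$nodes), nrow(x$elements),
              length(x$electrodes)))
  invisible(x)
}

#' @export
plot.eit_mesh <- function(x, sigma = NULL, ...) {
  nodes <- x$nodes; el <- x$elements
  plot(NA, xlim = c(-1.05, 1.05), ylim = c(-1.05, 1.05), asp = 1,
       xlab = "x (subject left →)", ylab = "y (ventral ↑)", ...)
  cols <- NA
  if (!is.null(sigma)) {
    pal <- grDevices::hcl.colors(64, "viridis")
    cols <- pal[cut(sigma, 64, labels = FALSE)]
  }
  for (e in seq_len(nrow(el))) {
    graphics::polygon(nodes[el[e, ], 1L], nodes[el[e, ], 2L],
                      border = "grey70",
                      col = if (is.null(sigma)) NA else cols[e])
  }
  for (k in seq_along(x$electrodes)) {
    edges <- x$boundary_edges[x$electrodes[[k]], , drop = FALSE]
    pts <- nodes[unique(as.vector(t(edges))), , drop = FALSE]
    graphics::lines(pts[, 1L], pts[, 2L], lwd = 4, col = "red3")
    ctr <- colMeans(pts) * 1.08
    graphics::text(ctr[1L], ctr[2L], k, cex = 0.7)
  }
  invisible(x)
}

#' Write / read a mesh in a plain-text node/element format
#'
#' The format is line-oriented: a header line `eit_mesh <shape> <a> <b>
#' <refinement>`, a `nodes <n>` line followed by n `x y` rows, an
#' `elements <m>` line followed by m index triples, a `boundary_edges <k>`
#' section and 16 `electrode` lines of edge indices.
#'
#' @param mesh An `eit_mesh`.
#' @param path File path.
#' @return `write_mesh` returns `path` invisibly; `read_mesh` returns an
#'   `eit_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("eit_mesh %s %.17g %.17g %d", mesh$shape, mesh$a,
                     mesh$b, mesh$refinement), con)
  writeLines(sprintf("nodes %d", nrow(mesh$nodes)), con)
  utils::write.table(format(mesh$nodes, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("elements %d", nrow(mesh$elements)), con)
  utils::write.table(mesh$elements, con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("boundary_edges %d", nrow(mesh$boundary_edges)), con)
  utils::write.table(mesh$boundary_edges, con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  for (k in seq_along(mesh$electrodes)) {
    writeLines(paste("electrode", paste(mesh$electrodes[[k]], collapse = " ")),
               con)
  }
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], " ")[[1L]]
  pos <- 2L
  read_block <- function(what, ncol) {
    stopifnot(startsWith(lines[pos], what))
    n <- as.integer(strsplit(lines[pos], " ")[[1L]][2L])
    block <- lines[pos + seq_len(n)]
    pos <<- pos + n + 1L
    matrix(as.numeric(unlist(strsplit(trimws(block), "\\s+"))),
           nrow = n, ncol = ncol, byrow = TRUE)
  }
  nodes <- read_block("nodes", 2L)
  elements <- read_block("elements", 3L)
  storage.mode(elements) <- "integer"
  boundary_edges <- read_block("boundary_edges", 2L)
  storage.mode(boundary_edges) <- "integer"
  electrodes <- lapply(lines[pos - 1L + seq_len(16L)], function(l) {
    as.integer(strsplit(l, " ")[[1L]][-1L])
  })
  mesh <- structure(list(
    nodes = nodes, elements = elements, boundary_edges = boundary_edges,
    electrodes = electrodes, shape = hdr[2L], a = as.numeric(hdr[3L]),
    b = as.numeric(hdr[4L]), refinement = as.integer(hdr[5L])
  ), class = "eit_mesh")
  validate_mesh(mesh)
  mesh
}
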