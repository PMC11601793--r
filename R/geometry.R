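#' Build the periodic rectangular unit cell of the lobular lattice
#'
#' Liver parenchyma is modelled as a perfectly periodic tiling of hexagonal
#' lobules (pointy-top orientation, vertex-to-vertex diameter
#' `lobule_diameter`) with a central vein at each lobule centre and portal
#' triads at the vertices. The smallest rectangular cell that tiles this
#' lattice is made of four half-hexagons: width \eqn{\sqrt{3}/2\,d} and
#' height \eqn{1.5\,d}, containing exactly two lobules.
#'
#' Vein centres sit at the four cell corners and the cell centre; the four
#' portal-triad centres are the hexagon vertices reduced into the half-open
#' cell \eqn{[0,w)\times[0,h)}. Vein and triad lumens are modelled as soft
#' circular inclusions (not holes); their radii are calibration knobs, not
#' histology-derived constants.
#'
#' @param lobule_diameter Vertex-to-vertex hexagon diameter in mm (default 1).
#' @param vein_radius Central-vein lumen radius in mm.
#' @param triad_radius Portal-triad lumen radius in mm.
#' @return An object of class `unit_cell`: a list with `lobule_diameter`,
#'   `width`, `height`, `vein_centers`, `triad_centers` (matrices with x, y
#'   columns, mm), `vein_radius`, `triad_radius`.
#' @examples
#' cell <- build_unit_cell(1)
#' c(cell$width, cell$height)  # 0.8660 1.5000
#' @export
build_unit_cell <- function(lobule_diameter = 1,
                            vein_radius = 0.05,
                            triad_radius = 0.04) {
  if (!is.numeric(lobule_diameter) || length(lobule_diameter) != 1L ||
      !is.finite(lobule_diameter) || lobule_diameter <= 0) {
    stop("`lobule_diameter` must be a single positive number (mm).",
         call. = FALSE)
  }
  if (vein_radius < 0 || triad_radius < 0) {
    stop("lumen radii must be non-negative.", call. = FALSE)
  }
  if (vein_radius >= lobule_diameter / 4 || triad_radius >= lobule_diameter / 4) {
    stop("lumen radii must be < lobule_diameter / 4.", call. = FALSE)
  }
  d <- lobule_diameter
  w <- sqrt(3) / 2 * d
  h <- 1.5 * d
  # two lobule centres per cell (corners are one centre periodically)
  vein <- rbind(c(0, 0), c(w, 0), c(0, h), c(w, h), c(w / 2, h / 2))
  # hexagon vertices reduced into [0, w) x [0, h)
  triad <- rbind(c(0, d / 2), c(0, d), c(w / 2, d / 4), c(w / 2, 5 * d / 4))
  colnames(vein) <- colnames(triad) <- c("x", "y")
  structure(
    list(lobule_diameter = d, width = w, height = h,
         vein_centers = vein, triad_centers = triad,
         vein_radius = vein_radius, triad_radius = triad_radius),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf(
    "<unit_cell> lobule diameter %.3g mm, cell %.4f x %.4f mm\n",
    x$lobule_diameter, x$width, x$height))
  cat(sprintf("  vein lumens: r = %.3g mm; triad lumens: r = %.3g mm\n",
              x$vein_radius, x$triad_radius))
  invisible(x)
}

# 3x3 periodic images of a point set (n x 2 matrix)
periodic_images <- function(pts, cell, reach = 1L) {
  pts <- rbind(pts)
  shifts <- as.matrix(expand.grid(ix = -reach:reach, iy = -reach:reach))
  out <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k) {
    cbind(pts[, 1] + shifts[k, 1] * cell$width,
          pts[, 2] + shifts[k, 2] * cell$height)
  }))
  out
}

#' Periodic minimum distance from points to a target set
#'
#' Minimum Euclidean distance from each query point to any target point,
#' where targets are replicated over the 3x3 tiling of periodic images of
#' the unit cell, so the field is continuous across cell boundaries.
#'
#' @param p Numeric matrix (n x 2) or length-2 vector of query points (mm).
#' @param targets Numeric matrix (m x 2) of target points (mm).
#' @param cell A [build_unit_cell()] object.
#' @return Numeric vector of distances (mm).
#' @export
periodic_distance <- function(p, targets, cell) {
  p <- rbind(p)
  if (is.null(targets) || nrow(rbind(targets)) == 0L) {
    stop("`targets` must contain at least one point.", call. = FALSE)
  }
  img <- periodic_images(targets, cell)
  dx <- outer(p[, 1], img[, 1], "-")
  dy <- outer(p[, 2], img[, 2], "-")
  sqrt(do.call(pmin, c(as.data.frame(dx^2 + dy^2), list(na.rm = FALSE)))) |>
    unname()
}

# distance from points (n x 2) to the nearest of a set of segments
# (m x 4 matrix: x1 y1 x2 y2), all already including periodic images
segment_distance <- function(p, seg) {
  p <- rbind(p)
  n <- nrow(p)
  best <- rep(Inf, n)
  for (k in seq_len(nrow(seg))) {
    ax <- seg[k, 1]; ay <- seg[k, 2]
    vx <- seg[k, 3] - ax; vy <- seg[k, 4] - ay
    L2 <- vx * vx + vy * vy
    t <- ((p[, 1] - ax) * vx + (p[, 2] - ay) * vy) / L2
    t <- pmin(pmax(t, 0), 1)
    dd <- (p[, 1] - (ax + t * vx))^2 + (p[, 2] - (ay + t * vy))^2
    best <- pmin(best, dd)
  }
  sqrt(best)
}

# pointy-top hexagon vertices around a centre, circumradius R
hex_vertices <- function(center, R) {
  ang <- pi / 2 + (0:5) * pi / 3
  cbind(center[1] + R * cos(ang), center[2] + R * sin(ang))
}

# all hexagon edge segments / centre-to-vertex radii over the 3x3 tiling
cell_segments <- function(cell, what = c("edge", "radius")) {
  what <- match.arg(what)
  R <- cell$lobule_diameter / 2
  centers <- rbind(c(0, 0), c(cell$width / 2, cell$height / 2))
  centers <- periodic_images(centers, cell)
  segs <- lapply(seq_len(nrow(centers)), function(k) {
    v <- hex_vertices(centers[k, ], R)
    if (what == "edge") {
      cbind(v, v[c(2:6, 1), ])
    } else {
      cbind(matrix(centers[k, ], nrow = 6, ncol = 2, byrow = TRUE), v)
    }
  })
  do.call(rbind, segs)
}

#' Distance fields on a point set
#'
#' Computes, for each query point, the periodic distances used by the
#' deposition generators: to the nearest central vein (`d_vein`), nearest
#' portal triad (`d_triad`), nearest hexagon edge segment (`d_edge`, the
#' perpendicular distance to the lobule boundary) and nearest lobular radius
#' (`d_radius`, segments joining each central vein to its six vertices).
#' All fields respect the cell periodicity (3x3 image tiling).
#'
#' @param p Numeric matrix (n x 2) of points (mm).
#' @param cell A [build_unit_cell()] object.
#' @return A tibble with columns `d_vein`, `d_triad`, `d_edge`, `d_radius`.
#' @export
distance_fields <- function(p, cell) {
  p <- rbind(p)
  tibble::tibble(
    d_vein = periodic_distance(p, cell$vein_centers, cell),
    d_triad = periodic_distance(p, cell$triad_centers, cell),
    d_edge = segment_distance(p, cell_segments(cell, "edge")),
    d_radius = segment_distance(p, cell_segments(cell, "radius"))
  )
}

#' Classify points as parenchyma or lumen
#'
#' A point is `VEIN_LUMEN` if its periodic distance to a vein centre is at
#' most `vein_radius`, else `TRIAD_LUMEN` if within `triad_radius` of a
#' triad centre, else `PARENCHYMA` (vein takes precedence on overlap).
#'
#' @inheritParams distance_fields
#' @return Factor with levels `PARENCHYMA`, `VEIN_LUMEN`, `TRIAD_LUMEN`.
#' @export
classify_region <- function(p, cell) {
  dv <- periodic_distance(p, cell$vein_centers, cell)
  dt <- periodic_distance(p, cell$triad_centers, cell)
  out <- rep("PARENCHYMA", length(dv))
  out[dt <= cell$triad_radius] <- "TRIAD_LUMEN"
  out[dv <= cell$vein_radius] <- "VEIN_LUMEN"
  factor(out, levels = c("PARENCHYMA", "VEIN_LUMEN", "TRIAD_LUMEN"))
}

#' Rasterize the unit cell onto the material grid
#'
#' Builds the regular raster that carries all synthetic histology: pixel
#' centres of an `nx` x `ny` lattice covering the cell, with region labels
#' and the four distance fields pre-computed. The default 80 x 160 matches
#' the resolution at which deposition patterns are generated.
#'
#' @param cell A [build_unit_cell()] object.
#' @param nx,ny Raster size (pixels across width and height).
#' @return A tibble of class `lobule_grid` with columns `i`, `j`, `x`, `y`,
#'   `region`, `d_vein`, `d_triad`, `d_edge`, `d_radius`; attributes `cell`,
#'   `nx`, `ny`.
#' @export
lobule_grid <- function(cell, nx = 80, ny = 160) {
  stopifnot(nx >= 2, ny >= 2)
  dx <- cell$width / nx
  dy <- cell$height / ny
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  p <- cbind((ij$i - 0.5) * dx, (ij$j - 0.5) * dy)
  df <- distance_fields(p, cell)
  g <- tibble::tibble(
    i = ij$i, j = ij$j, x = p[, 1], y = p[, 2],
    region = classify_region(p, cell),
    d_vein = df$d_vein, d_triad = df$d_triad,
    d_edge = df$d_edge, d_radius = df$d_radius
  )
  attr(g, "cell") <- cell
  attr(g, "nx") <- nx
  attr(g, "ny") <- ny
  class(g) <- c("lobule_grid", class(g))
  g
}

#' Write unit-cell geometry to JSON
#'
#' @param cell A [build_unit_cell()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cell_json <- function(cell, path) {
  jsonlite::write_json(
    list(lobule_diameter = cell$lobule_diameter,
         width = cell$width, height = cell$height,
         vein_radius = cell$vein_radius, triad_radius = cell$triad_radius,
         vein_centers = unname(cell$vein_centers),
         triad_centers = unname(cell$triad_centers)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
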