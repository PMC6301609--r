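#' Minimum convex polygon (convex hull) in isotope space
#'
#' Builds the smallest convex polygon enclosing a set of
#' (\eqn{\delta^{13}}C, \eqn{\delta^{15}}N) points. Vertices are returned
#' in counter-clockwise order, first vertex not repeated; interior points
#' and collinear boundary points are excluded, so the retained polygon is
#' strictly convex. Vertex finding uses [grDevices::chull()]; collinear
#' boundary vertices are pruned afterwards.
#'
#' @param points Two-column matrix or data frame of (d13C, d15N); at least
#'   3 non-collinear points.
#' @return Object of class `"convex_polygon"`: tibble of `d13C`, `d15N`
#'   vertices (CCW) with the signed area in the `"area"` attribute.
#' @examples
#' convex_hull(tibble::tibble(d13C = c(0, 1, 1, 0, 0.5),
#'                            d15N = c(0, 0, 1, 1, 0.5)))
#' @export
convex_hull <- function(points) {
  pts <- as.matrix(points[, 1:2])
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3) abort("convex_hull needs >= 3 points")
  idx <- grDevices::chull(pts)      # clockwise order
  idx <- rev(idx)                   # counter-clockwise
  v <- pts[idx, , drop = FALSE]
  v <- drop_collinear(v)
  if (nrow(v) < 3 || signed_area(v) <= 0) {
    abort("degenerate polygon: all points collinear")
  }
  structure(
    tibble::tibble(d13C = v[, 1], d15N = v[, 2]),
    area = signed_area(v),
    class = c("convex_polygon", class(tibble::tibble()))
  )
}

# Shoelace signed area; positive for counter-clockwise vertex order.
signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Remove vertices where the hull turns by ~0 (three collinear retained
# vertices would violate strict convexity).
drop_collinear <- function(v, tol = 1e-12) {
  repeat {
    n <- nrow(v)
    if (n < 3) return(v)
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      a <- v[if (i == 1) n else i - 1, ]
      b <- v[i, ]
      c <- v[if (i == n) 1 else i + 1, ]
      cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      if (abs(cross) <= tol * (1 + sum(abs(c(a, b, c))))) keep[i] <- FALSE
    }
    if (all(keep)) return(v)
    v <- v[keep, , drop = FALSE]
  }
}

#' Polygon area
#'
#' @param polygon A `convex_polygon`.
#' @return Area (permil squared).
#' @export
polygon_area <- function(polygon) attr(polygon, "area")

#' Point-in-polygon test (boundary inclusive)
#'
#' Tests whether points fall inside or on the boundary of a convex polygon
#' via half-plane sign checks against each counter-clockwise edge. The
#' boundary counts as inside, with an absolute tolerance of 1e-9 permil so
#' points on an edge do not flip with rounding.
#'
#' @param polygon A `convex_polygon`.
#' @param points Two-column matrix or data frame of (d13C, d15N).
#' @param tol Boundary tolerance (permil), default 1e-9.
#' @return Logical vector, one entry per point.
#' @export
polygon_contains <- function(polygon, points, tol = 1e-9) {
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  storage.mode(pts) <- "double"
  v <- as.matrix(polygon[, c("d13C", "d15N")])
  n <- nrow(v)
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[if (i == n) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & (cross >= -tol)
  }
  inside
}

#' Mixing-polygon plausibility of a TEF scenario
#'
#' Shifts each consumer back by the scenario's mean trophic enrichment
#' (\eqn{\delta^{13}C - \varepsilon^{13}C_{mean}},
#' \eqn{\delta^{15}N - \varepsilon^{15}N_{mean}}; TEF SD plays no role in
#' this point-geometry check) and counts how many fall (a) inside the
#' minimum convex polygon around all raw source values and (b) inside the
#' polygon around the four group means. A consumer outside a source
#' polygon cannot be written as a mixture of those sources under that TEF,
#' so these counts rule enrichment scenarios in or out.
#'
#' Shifting consumers down by the mean TEF is equivalent to shifting every
#' source up by it; the counts are identical either way.
#'
#' @param consumers Consumers tibble (`consumer_id`, `d13C`, `d15N`).
#' @param sources Sources tibble (corrected values).
#' @param scenario A [tef_scenario()].
#' @return List: `n_inside_raw`, `n_inside_mean`, `n_consumers`, `flags`
#'   (tibble of `consumer_id`, `inside_raw`, `inside_mean`), `hull_raw`,
#'   `hull_mean`.
#' @export
tef_plausibility <- function(consumers, sources, scenario) {
  gs <- group_summary(sources)
  if (nrow(gs) < 3) abort("need >= 3 group means to build a mixing polygon")
  hull_raw <- convex_hull(sources[, c("d13C", "d15N")])
  hull_mean <- convex_hull(tibble::tibble(d13C = gs$mean_d13C,
                                          d15N = gs$mean_d15N))
  shifted <- tibble::tibble(
    d13C = consumers$d13C - scenario$eps13C_mean,
    d15N = consumers$d15N - scenario$eps15N_mean
  )
  in_raw <- polygon_contains(hull_raw, shifted)
  in_mean <- polygon_contains(hull_mean, shifted)
  list(
    n_inside_raw = sum(in_raw),
    n_inside_mean = sum(in_mean),
    n_consumers = nrow(consumers),
    flags = tibble::tibble(consumer_id = consumers$consumer_id,
                           inside_raw = in_raw, inside_mean = in_mean),
    hull_raw = hull_raw, hull_mean = hull_mean
  )
}

#' Plot a TEF mixing-polygon check
#'
#' Draws the raw-source and group-mean minimum convex polygons with the
#' TEF-shifted consumers overlaid, one panel per scenario.
#'
#' @param consumers,sources As in [tef_plausibility()].
#' @param scenarios List of [tef_scenario()] objects (default all four
#'   named scenarios).
#' @return A ggplot object.
#' @export
plot_mixing_polygons <- function(consumers, sources,
                                 scenarios = tef_scenarios()) {
  panels <- purrr::map_dfr(scenarios, function(sc) {
    dplyr::bind_rows(
      tibble::tibble(kind = "consumer",
                     d13C = consumers$d13C - sc$eps13C_mean,
                     d15N = consumers$d15N - sc$eps15N_mean,
                     scenario = sc$name),
      tibble::tibble(kind = "source", d13C = sources$d13C,
                     d15N = sources$d15N, scenario = sc$name)
    )
  })
  hulls <- purrr::map_dfr(scenarios, function(sc) {
    tp <- tef_plausibility(consumers, sources, sc)
    dplyr::bind_rows(
      dplyr::mutate(tp$hull_raw, hull = "raw", scenario = sc$name),
      dplyr::mutate(tp$hull_mean, hull = "group means", scenario = sc$name)
    )
  })
  ggplot2::ggplot(panels, ggplot2::aes(x = .data$d13C, y = .data$d15N)) +
    ggplot2::geom_polygon(data = hulls,
                          ggplot2::aes(linetype = .data$hull),
                          fill = NA, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$kind), size = 1) +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = expression(delta^13 * C ~ ("\u2030")),
                  y = expression(delta^15 * N ~ ("\u2030"))) +
    ggplot2::theme_minimal()
}
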