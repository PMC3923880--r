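#' Plot a landscape's elevation, water and subcatchment structure
#'
#' @param object A `vuln_landscape`.
#' @param ... Unused.
#' @return A ggplot: elevation raster with water in blue and subcatchment
#'   centroids marked.
#' @method autoplot vuln_landscape
#' @export
autoplot.vuln_landscape <- function(object, ...) {
  cells <- object$cells
  ggplot(cells, aes(.data$x, .data$y)) +
    geom_raster(aes(fill = ifelse(.data$is_water, NA, .data$elevation))) +
    geom_raster(
      data = cells |> filter(.data$is_water), fill = "steelblue3"
    ) +
    geom_point(
      data = object$subcatchments, aes(.data$x, .data$y),
      size = 0.3, colour = "black"
    ) +
    scale_fill_viridis_c(name = "elevation (m)", na.value = "steelblue3") +
    coord_equal() +
    labs(x = "x (km)", y = "y (km)")
}

## suitability (or any per-subcatchment value) painted onto the cell grid
map_subcatchment_values <- function(landscape, values, name) {
  cells <- landscape$cells |>
    left_join(values, by = "subcatchment")
  ggplot(cells, aes(.data$x, .data$y)) +
    geom_raster(aes(fill = .data$value)) +
    scale_fill_viridis_c(name = name, na.value = "steelblue3") +
    coord_equal() +
    labs(x = "x (km)", y = "y (km)")
}

#' Map a suitability surface over the landscape
#'
#' @param object A `suitability_surface`.
#' @param landscape The `vuln_landscape` it was computed on.
#' @param ... Unused.
#' @return A ggplot raster of per-subcatchment suitability (water in
#'   blue).
#' @method autoplot suitability_surface
#' @export
autoplot.suitability_surface <- function(object, landscape, ...) {
  at <- surface_attrs(object)
  map_subcatchment_values(
    landscape,
    tibble(subcatchment = object$subcatchment, value = object$suitability),
    "suitability"
  ) +
    labs(title = sprintf("%s — %s", at$species, at$scenario))
}

#' Map least-cost distances over the landscape
#'
#' @param object A `distance_field`.
#' @param landscape The `vuln_landscape`.
#' @param ... Unused.
#' @return A ggplot raster of per-subcatchment distance (km).
#' @method autoplot distance_field
#' @export
autoplot.distance_field <- function(object, landscape, ...) {
  map_subcatchment_values(
    landscape,
    tibble(subcatchment = object$subcatchment, value = object$distance_km),
    "distance (km)"
  )
}

#' Map a conservation priority surface
#'
#' @param object A `priority_map`.
#' @param landscape The `vuln_landscape`.
#' @param ... Unused.
#' @return A ggplot raster of per-subcatchment priority.
#' @method autoplot priority_map
#' @export
autoplot.priority_map <- function(object, landscape, ...) {
  map_subcatchment_values(
    landscape,
    tibble(subcatchment = object$subcatchment, value = object$priority),
    "priority"
  ) +
    labs(title = sprintf(
      "Priority (categories %s) — %s",
      paste(attr(object, "categories"), collapse = ","), attr(object, "scenario")
    ))
}

#' Plot dispersal kernels for a set of threshold distances
#'
#' @param d0 Named or unnamed vector of inflection distances (km), e.g.
#'   `c(current = 300, "2055" = 630, "2085" = 1080)`.
#' @param b,a,c Kernel shape parameters (see [kernel_params()]).
#' @param max_d Largest distance plotted (default `2.5 * max(d0)`).
#' @return A ggplot of dispersal probability against distance.
#' @export
plot_kernels <- function(d0, b = 4, a = 1, c = 0, max_d = NULL) {
  nm <- names(d0) %||% as.character(d0)
  max_d <- max_d %||% (2.5 * max(d0))
  grid <- map(seq_along(d0), function(i) {
    tibble(
      threshold = nm[i], d = seq(0, max_d, length.out = 400),
      k = kernel_value(seq(0, max_d, length.out = 400), kernel_params(d0[i], b = b, a = a, c = c))
    )
  }) |> bind_rows()
  ggplot(grid, aes(.data$d, .data$k, colour = .data$threshold)) +
    geom_line() +
    labs(
      x = "cost-weighted distance (km)", y = "dispersal probability",
      colour = "threshold"
    )
}
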