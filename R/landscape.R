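#' Generate a synthetic subcatchment landscape
#'
#' Builds a gridded land/sea landscape partitioned into contiguous
#' subcatchments, standing in for a national catchment database at desk
#' scale. Elevation is a smoothed Gaussian random field rescaled to
#' `[0, max_elev]`; the lowest-lying fraction of cells becomes open water, and
#' land cells bordering water are forced to low elevation so that sea-level
#' exposure rules have something to act on. Subcatchments are grown by seeded
#' region growing from random land cells, which yields irregular contiguous
#' units resembling catchments without any hydrological modelling.
#'
#' @param n_rows,n_cols Grid dimensions (cells).
#' @param n_subcatchments Number of subcatchments to partition land into.
#' @param cell_size Cell edge length in km.
#' @param sea_fraction Proportion of cells that are open water, in `[0, 1)`.
#' @param max_elev Maximum elevation in m.
#' @param seed Integer seed; identical seeds give bit-identical landscapes.
#'
#' @return An object of class `vuln_landscape`: a list with
#'   * `cells`: tibble (cell, row, col, x, y, elevation, is_water,
#'     subcatchment),
#'   * `subcatchments`: tibble (subcatchment, x, y, mean_elev, n_cells,
#'     region, code),
#'   * `n_rows`, `n_cols`, `cell_size`.
#'   Coordinates are planar km with the origin at the grid's lower-left
#'   corner and cell centers at `(index - 0.5) * cell_size`.
#' @export
#' @examples
#' ls <- generate_landscape(12, 12, n_subcatchments = 8, seed = 1)
#' ls$subcatchments
generate_landscape <- function(n_rows, n_cols, n_subcatchments,
                               cell_size = 25, sea_fraction = 0.15,
                               max_elev = 1500, seed = 1) {
  stopifnot(n_rows >= 2, n_cols >= 2, cell_size > 0)
  if (sea_fraction < 0 || sea_fraction >= 1) {
    abort("`sea_fraction` must be in [0, 1).")
  }
  n_cells <- n_rows * n_cols
  withr::with_seed(seed, {
    z <- smooth_field(n_rows, n_cols, passes = 8L)
    is_water <- rep(FALSE, n_cells)
    if (sea_fraction > 0) {
      cut <- quantile(z, sea_fraction, names = FALSE)
      is_water <- as.vector(z <= cut)
    }
    n_land <- sum(!is_water)
    if (n_subcatchments > n_land) {
      abort(sprintf(
        "Cannot place %d subcatchments on %d land cells.",
        n_subcatchments, n_land
      ))
    }

    zl <- as.vector(z)
    rng <- range(zl[!is_water])
    elevation <- rep(0, n_cells)
    if (diff(rng) > 0) {
      elevation[!is_water] <- (zl[!is_water] - rng[1]) / diff(rng) * max_elev
    }
    nbr <- neighbour_matrix(n_rows, n_cols)
    if (any(is_water)) {
      # coastal land cells forced low so the <= 1 m sea-level rule can fire
      coastal <- !is_water &
        apply(nbr, 1L, function(i) any(is_water[i[!is.na(i)]]))
      elevation[coastal] <- runif(sum(coastal), 0, 1.2)
    }

    sub_idx <- grow_subcatchments(!is_water, nbr, n_subcatchments)

    row <- rep(seq_len(n_rows), times = n_cols)
    col <- rep(seq_len(n_cols), each = n_rows)
    cells <- tibble(
      cell = seq_len(n_cells), row = row, col = col,
      x = (col - 0.5) * cell_size, y = (row - 0.5) * cell_size,
      elevation = elevation, is_water = is_water,
      subcatchment = ifelse(is.na(sub_idx), NA_character_,
        sprintf("SC%04d", sub_idx)
      )
    )

    comp <- land_components(!is_water, nbr)
    region_of_cell <- comp$label

    subcatchments <- cells |>
      filter(!is.na(.data$subcatchment)) |>
      mutate(region_cell = region_of_cell[.data$cell]) |>
      group_by(subcatchment = .data$subcatchment) |>
      summarise(
        x = mean(.data$x), y = mean(.data$y),
        mean_elev = mean(.data$elevation),
        n_cells = n(),
        region = names(sort(table(.data$region_cell), decreasing = TRUE))[1],
        .groups = "drop"
      ) |>
      arrange(.data$subcatchment) |>
      group_by(.data$region) |>
      mutate(code = sprintf(
        "%s.%02d", sub("^mainland$", "R1", sub("^island", "I", .data$region)),
        row_number()
      )) |>
      ungroup()

    structure(
      list(
        cells = cells, subcatchments = subcatchments,
        n_rows = n_rows, n_cols = n_cols, cell_size = cell_size
      ),
      class = "vuln_landscape"
    )
  })
}

#' @export
print.vuln_landscape <- function(x, ...) {
  cat(sprintf(
    "<vuln_landscape> %d x %d grid (%.0f km cells), %d land cells, %d subcatchments, regions: %s\n",
    x$n_rows, x$n_cols, x$cell_size, sum(!x$cells$is_water),
    nrow(x$subcatchments), paste(unique(x$subcatchments$region), collapse = ", ")
  ))
  invisible(x)
}

## Smoothed standard-normal field: white noise + repeated 3x3 box blur.
smooth_field <- function(n_rows, n_cols, passes = 8L) {
  m <- matrix(rnorm(n_rows * n_cols), n_rows, n_cols)
  for (i in seq_len(passes)) m <- box_blur(m)
  (m - mean(m)) / sd(m)
}

box_blur <- function(m) {
  n <- nrow(m)
  p <- ncol(m)
  up <- m[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
  horiz <- function(a) {
    (a[, c(1L, seq_len(p - 1L)), drop = FALSE] + a +
      a[, c(seq_len(p - 1L) + 1L, p), drop = FALSE]) / 3
  }
  (horiz(up) + horiz(m) + horiz(dn)) / 3
}

## N x 8 matrix of neighbour cell ids (NA off-grid), cells in column-major
## order (cell = row + (col-1) * n_rows).
neighbour_matrix <- function(n_rows, n_cols) {
  n <- n_rows * n_cols
  row <- rep(seq_len(n_rows), times = n_cols)
  col <- rep(seq_len(n_cols), each = n_rows)
  offs <- cbind(
    c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
    c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  )
  out <- matrix(NA_integer_, n, 8L)
  for (k in seq_len(8L)) {
    r2 <- row + offs[k, 1L]
    c2 <- col + offs[k, 2L]
    ok <- r2 >= 1L & r2 <= n_rows & c2 >= 1L & c2 <= n_cols
    out[ok, k] <- r2[ok] + (c2[ok] - 1L) * n_rows
  }
  attr(out, "n_rows") <- n_rows
  out
}

## Seeded region growing over land cells; returns integer subcatchment index
## per cell (NA for water). Orphan land components without a seed are
## attached to the nearest assigned land cell.
grow_subcatchments <- function(is_land, nbr, n_sub) {
  n <- length(is_land)
  lab <- rep(NA_integer_, n)
  land_ids <- which(is_land)
  seeds <- land_ids[sample.int(length(land_ids), n_sub)]
  lab[seeds] <- seq_len(n_sub)
  repeat {
    open <- which(is_land & is.na(lab))
    if (length(open) == 0L) break
    has_lab <- open[vapply(open, function(i) {
      nb <- nbr[i, ]
      any(!is.na(lab[nb[!is.na(nb)]]))
    }, logical(1))]
    if (length(has_lab) == 0L) break
    for (i in has_lab[sample.int(length(has_lab))]) {
      nb <- nbr[i, ]
      labs <- lab[nb[!is.na(nb)]]
      labs <- labs[!is.na(labs)]
      if (length(labs)) lab[i] <- labs[sample.int(length(labs), 1L)]
    }
  }
  open <- which(is_land & is.na(lab))
  if (length(open)) {
    n_rows <- attr(nbr, "n_rows")
    assigned <- which(!is.na(lab))
    ar <- (assigned - 1L) %% n_rows
    ac <- (assigned - 1L) %/% n_rows
    for (i in open) {
      d2 <- (ar - (i - 1L) %% n_rows)^2 + (ac - (i - 1L) %/% n_rows)^2
      lab[i] <- lab[assigned[which.min(d2)]]
    }
  }
  lab
}

## Connected components of land under 8-connectivity; largest is "mainland",
## the rest "island1", "island2", ... by decreasing size.
land_components <- function(is_land, nbr) {
  n <- length(is_land)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in which(is_land)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      nb <- nbr[i, ]
      nb <- nb[!is.na(nb)]
      nb <- nb[is_land[nb] & is.na(comp[nb])]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes <- sort(table(comp), decreasing = TRUE)
  ord <- as.integer(names(sizes))
  name <- rep(NA_character_, max(c(cur, 1L)))
  name[ord] <- c("mainland", paste0("island", seq_len(max(cur - 1L, 0L))))[seq_len(cur)]
  list(label = ifelse(is.na(comp), NA_character_, name[comp]), n = cur)
}
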