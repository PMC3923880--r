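#' Write a matrix as an ESRI ASCII grid
#'
#' Rows of `m` run south to north (row 1 = bottom), matching the package's
#' planar-km convention; the file is written north-first as the format
#' requires.
#'
#' @param m Numeric matrix (`NA` written as the NODATA value).
#' @param path Output path.
#' @param cell_size Cell size (km).
#' @param xll,yll Lower-left corner coordinates.
#' @param nodata NODATA sentinel (default -9999).
#' @export
write_esri_ascii <- function(m, path, cell_size = 1, xll = 0, yll = 0,
                             nodata = -9999) {
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", xll),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  mm <- m
  mm[is.na(mm)] <- nodata
  rows <- apply(mm[rev(seq_len(nrow(mm))), , drop = FALSE], 1L, function(r) {
    paste(formatC(r, digits = 12, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return List: `values` (matrix, row 1 = south, NODATA as `NA`),
#'   `cell_size`, `xll`, `yll`, `nodata`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr))) abort("Malformed ESRI ASCII header.")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  nr <- hdr$nrows
  nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    abort(sprintf("Grid body has %d values; header promises %d.", length(vals), nr * nc))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA
  m <- m[rev(seq_len(nr)), , drop = FALSE]
  list(
    values = m, cell_size = hdr$cellsize %||% 1,
    xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0, nodata = nodata
  )
}

## cells-vector -> matrix in grid orientation (row 1 = south)
cells_to_matrix <- function(landscape, values) {
  matrix(values, nrow = landscape$n_rows, ncol = landscape$n_cols)
}

#' Write a landscape to a directory
#'
#' Writes `elevation.asc`, `water.asc` and `subcatchment.asc` (ESRI ASCII;
#' water cells are NODATA in the elevation and subcatchment grids) plus
#' `subcatchments.geojson`, a FeatureCollection with one MultiPolygon of
#' member-cell squares per subcatchment carrying its attribute table.
#'
#' @param landscape A `vuln_landscape`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- landscape$cells
  cs <- landscape$cell_size
  elev <- ifelse(cells$is_water, NA, cells$elevation)
  water <- as.numeric(cells$is_water)
  sub_idx <- match(cells$subcatchment, landscape$subcatchments$subcatchment)
  write_esri_ascii(cells_to_matrix(landscape, elev),
    file.path(dir, "elevation.asc"),
    cell_size = cs
  )
  write_esri_ascii(cells_to_matrix(landscape, water),
    file.path(dir, "water.asc"),
    cell_size = cs
  )
  write_esri_ascii(cells_to_matrix(landscape, sub_idx),
    file.path(dir, "subcatchment.asc"),
    cell_size = cs
  )

  subs <- landscape$subcatchments
  features <- map(seq_len(nrow(subs)), function(i) {
    mem <- cells[which(cells$subcatchment == subs$subcatchment[i]), ]
    polys <- map(seq_len(nrow(mem)), function(j) {
      x0 <- mem$x[j] - cs / 2
      y0 <- mem$y[j] - cs / 2
      list(list(
        c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs),
        c(x0, y0 + cs), c(x0, y0)
      ))
    })
    list(
      type = "Feature",
      geometry = list(type = "MultiPolygon", coordinates = polys),
      properties = list(
        subcatchment = subs$subcatchment[i], index = i,
        centroid_x = subs$x[i], centroid_y = subs$y[i],
        mean_elev = subs$mean_elev[i], n_cells = subs$n_cells[i],
        region = subs$region[i], code = subs$code[i]
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    file.path(dir, "subcatchments.geojson"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a landscape written by [write_landscape()]
#'
#' NODATA cells in the subcatchment grid are water / no-subcatchment per
#' the grid header.
#'
#' @param dir Directory containing the grids and GeoJSON.
#' @return A `vuln_landscape`.
#' @export
read_landscape <- function(dir) {
  elev <- read_esri_ascii(file.path(dir, "elevation.asc"))
  water <- read_esri_ascii(file.path(dir, "water.asc"))
  subg <- read_esri_ascii(file.path(dir, "subcatchment.asc"))
  gj <- jsonlite::read_json(file.path(dir, "subcatchments.geojson"))
  props <- map(gj$features, "properties")
  subs <- tibble(
    subcatchment = map_chr(props, "subcatchment"),
    x = map_dbl(props, "centroid_x"), y = map_dbl(props, "centroid_y"),
    mean_elev = map_dbl(props, "mean_elev"),
    n_cells = as.integer(map_dbl(props, "n_cells")),
    region = map_chr(props, "region"), code = map_chr(props, "code")
  )
  idx <- map_dbl(props, "index")
  id_of_index <- character(max(idx))
  id_of_index[idx] <- subs$subcatchment
  n_rows <- nrow(elev$values)
  n_cols <- ncol(elev$values)
  cs <- elev$cell_size
  is_water <- as.vector(water$values) == 1
  sub_vec <- as.vector(subg$values)
  cells <- tibble(
    cell = seq_len(n_rows * n_cols),
    row = rep(seq_len(n_rows), times = n_cols),
    col = rep(seq_len(n_cols), each = n_rows)
  )
  cells$x <- (cells$col - 0.5) * cs
  cells$y <- (cells$row - 0.5) * cs
  ev <- as.vector(elev$values)
  cells$elevation <- ifelse(is.na(ev), 0, ev)
  cells$is_water <- is_water
  cells$subcatchment <- ifelse(is.na(sub_vec), NA_character_, id_of_index[sub_vec])
  structure(
    list(
      cells = cells, subcatchments = subs,
      n_rows = n_rows, n_cols = n_cols, cell_size = cs
    ),
    class = "vuln_landscape"
  )
}

#' Write scenario stacks as long-format CSV
#'
#' @param stacks Named list of `scenario_stack`s.
#' @param path Output CSV path.
#' @param comment Optional comment lines (written with a leading `#`).
#' @export
write_scenario_stacks <- function(stacks, path, comment = character()) {
  long <- imap(stacks, function(st, nm) {
    as_tibble(st) |>
      tidyr::pivot_longer(-"subcatchment", names_to = "factor", values_to = "value") |>
      mutate(scenario = nm, .before = 1)
  }) |> bind_rows()
  write_report(long, path, comment)
}

#' Read scenario stacks from long-format CSV
#'
#' @param path CSV path written by [write_scenario_stacks()].
#' @return Named list of `scenario_stack`s.
#' @export
read_scenario_stacks <- function(path) {
  long <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("scenario", "subcatchment", "factor", "value")
  if (!all(need %in% names(long))) {
    abort(paste0("Scenario CSV must have columns: ", paste(need, collapse = ", ")))
  }
  split(long, long$scenario) |>
    map(function(d) {
      new_scenario_stack(
        tidyr::pivot_wider(d |> select(-"scenario"),
          names_from = "factor", values_from = "value"
        ),
        unique(d$scenario)
      )
    })
}

#' Write occurrence records as CSV
#'
#' @param occ An `occurrence_set` (or bound rows of several).
#' @param path Output CSV path.
#' @param comment Optional comment lines.
#' @export
write_occurrences <- function(occ, path, comment = character()) {
  write_report(as_tibble(occ), path, comment)
}

#' Read and validate occurrence records
#'
#' When a landscape is supplied, every record must fall on a land cell and
#' carry the subcatchment of its coordinates; violations are reported by
#' row.
#'
#' @param path CSV path.
#' @param landscape Optional `vuln_landscape` for validation.
#' @return An `occurrence_set` tibble.
#' @export
read_occurrences <- function(path, landscape = NULL) {
  occ <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("species", "x", "y", "subcatchment")
  missing <- setdiff(need, names(occ))
  if (length(missing)) {
    abort(paste0(
      "Occurrence CSV missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (!is.null(landscape)) {
    cs <- landscape$cell_size
    col <- pmin(pmax(ceiling(occ$x / cs), 1L), landscape$n_cols)
    row <- pmin(pmax(ceiling(occ$y / cs), 1L), landscape$n_rows)
    cell <- row + (col - 1L) * landscape$n_rows
    bad_water <- which(landscape$cells$is_water[cell])
    if (length(bad_water)) {
      abort(sprintf(
        "Occurrence record(s) on water cells at row(s): %s",
        paste(bad_water, collapse = ", ")
      ))
    }
    bad_sub <- which(landscape$cells$subcatchment[cell] != occ$subcatchment)
    if (length(bad_sub)) {
      abort(sprintf(
        "Occurrence record(s) with inconsistent subcatchment at row(s): %s",
        paste(bad_sub, collapse = ", ")
      ))
    }
    occ$cell <- cell
  }
  structure(occ, class = c("occurrence_set", class(occ)))
}

#' Write suitability surfaces as long CSV
#'
#' @param surfaces List of `suitability_surface`s.
#' @param path Output CSV path.
#' @param comment Optional comment lines.
#' @export
write_surfaces <- function(surfaces, path, comment = character()) {
  long <- map(surfaces, function(s) {
    at <- surface_attrs(s)
    as_tibble(s) |>
      mutate(
        species = at$species, scenario = at$scenario,
        tss_threshold = at$tss_threshold, .before = 1
      )
  }) |> bind_rows()
  write_report(long, path, comment)
}

#' Read suitability surfaces written by [write_surfaces()]
#'
#' @param path CSV path.
#' @return List of `suitability_surface`s (one per species x scenario).
#' @export
read_surfaces <- function(path) {
  long <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  split(long, paste(long$species, long$scenario)) |>
    map(function(d) {
      new_suitability_surface(
        d |> select("subcatchment", "suitability"),
        species = unique(d$species), scenario = unique(d$scenario),
        tss_threshold = unique(d$tss_threshold)
      )
    }) |> unname()
}

## CSV writer with "#" comment header (config hash, seed) above the header
## row; deterministic output for byte-identical reruns.
write_report <- function(df, path, comment = character()) {
  if (length(comment)) {
    writeLines(paste0("# ", comment), path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}
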