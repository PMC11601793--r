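# Plain-text exports: CSV rasters, legacy-ASCII VTK image data, JSON
# results. Plots and files are pure views of tibbles already computed.

#' Write a raster column of a grid tibble as CSV
#'
#' Columns `i, j, x_mm, y_mm, value`.
#'
#' @param grid A grid-backed tibble (`lobule_grid`, `fat_field`, ...).
#' @param column Name of the value column (e.g. `"fat"`, `"collagen"`,
#'   `"region"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(grid, column, path) {
  df <- data.frame(i = grid$i, j = grid$j, x_mm = grid$x, y_mm = grid$y,
                   value = grid[[column]])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write raster fields as legacy-ASCII VTK structured points
#'
#' Minimal VTK writer for visual inspection in ParaView; one scalar field
#' per listed column (complex columns are split into real and imaginary
#' parts).
#'
#' @param grid A grid-backed tibble.
#' @param columns Character vector of column names to export.
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_image <- function(grid, columns, path) {
  nx <- attr(grid, "nx") %||% max(grid$i)
  ny <- attr(grid, "ny") %||% max(grid$j)
  cell <- attr(grid, "cell")
  dx <- if (is.null(cell)) 1 else cell$width / nx
  dy <- if (is.null(cell)) 1 else cell$height / ny
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "lobulemech raster export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %g %g 0", dx / 2, dy / 2),
               sprintf("SPACING %g %g 1", dx, dy),
               sprintf("POINT_DATA %d", nx * ny)), con)
  ord <- order(grid$j, grid$i)  # x fastest, VTK convention
  emit <- function(name, v) {
    writeLines(c(sprintf("SCALARS %s float 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(v[ord], digits = 7, trim = TRUE, scientific = TRUE),
               con)
  }
  for (col in columns) {
    v <- grid[[col]]
    if (is.complex(v)) {
      emit(paste0(col, "_re"), Re(v))
      emit(paste0(col, "_im"), Im(v))
    } else {
      emit(col, as.numeric(v))
    }
  }
  invisible(path)
}

#' Write a homogenization result as JSON
#'
#' @param result A `homog_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  meta <- result$meta
  meta$matrix_model <- list(kind = meta$matrix_model$kind,
                            params = meta$matrix_model$params)
  jsonlite::write_json(
    list(storage_Pa = result$storage, loss_Pa = result$loss,
         tau_s = result$tau, freq_Hz = result$frequency, meta = meta),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
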