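#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

as_homog_ensemble <- function(x) {
  class(x) <- c("homog_ensemble", "tbl_df", "tbl", "data.frame")
  x
}

#' Tidy a homogenization result
#'
#' @param x A `homog_result`.
#' @param ... Unused.
#' @return One-row tibble with `storage`, `loss`, `tau`, `freq_Hz`,
#'   realized fractions and mesh size.
#' @method tidy homog_result
#' @export
tidy.homog_result <- function(x, ...) {
  tibble::tibble(
    storage = x$storage, loss = x$loss, tau = x$tau,
    freq_Hz = x$frequency,
    fat_realized = x$meta$realized_fat,
    cpa_realized = x$meta$realized_cpa,
    collagen_G_Pa = x$meta$collagen_modulus,
    mesh_nx = x$meta$mesh_nx, mesh_ny = x$meta$mesh_ny)
}

#' @rdname tidy.homog_result
#' @method glance homog_result
#' @export
glance.homog_result <- function(x, ...) tidy(x, ...)

#' Summarise a homogenization ensemble
#'
#' Means and standard deviations of storage modulus, loss modulus and
#' relaxation time, grouped by the sweep settings.
#'
#' @param x A `homog_ensemble` tibble.
#' @param ... Unused.
#' @return A tibble with one row per distinct setting.
#' @method glance homog_ensemble
#' @export
glance.homog_ensemble <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$fat_target,
                    .data$cpa_target, .data$fat_pattern, .data$fib_pattern,
                    .data$collagen_G_Pa, .data$freq_Hz, .data$mesh_nx,
                    .data$mesh_ny),
    n = dplyr::n(),
    storage_mean = mean(.data$storage), storage_sd = stats::sd(.data$storage),
    loss_mean = mean(.data$loss), loss_sd = stats::sd(.data$loss),
    tau_mean = mean(.data$tau), tau_sd = stats::sd(.data$tau),
    fat_realized_mean = mean(.data$fat_realized),
    cpa_realized_mean = mean(.data$cpa_realized),
    .groups = "drop")
}

#' Heatmap of a fat field
#'
#' @param object A `fat_field` (or `microstructure`) tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fat_field
#' @export
autoplot.fat_field <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$x, .data$y, fill = .data$fat)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 0.5), name = "fat fraction") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' Collagen mask overlay
#'
#' Collagen pixels as dots over the parenchyma/lumen background.
#'
#' @param object A `collagen_mask` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot collagen_mask
#' @export
autoplot.collagen_mask <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$region == "PARENCHYMA")) +
    ggplot2::scale_fill_manual(values = c("FALSE" = "navy", "TRUE" = "grey55"),
                               guide = "none") +
    ggplot2::geom_point(data = df[df$collagen, ], colour = "yellow",
                        size = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' Microstructure overview plot
#'
#' Fat-fraction raster with collagen pixels overlaid.
#'
#' @param object A `microstructure` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot microstructure
#' @export
autoplot.microstructure <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fat)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 0.5), name = "fat fraction") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
  if (!is.null(df$collagen) && any(df$collagen)) {
    p <- p + ggplot2::geom_point(data = df[df$collagen, ],
                                 colour = "red", size = 0.3)
  }
  p
}

#' Sweep plot: moduli versus a driving variable
#'
#' Pure view of an ensemble table: storage moduli as open circles and loss
#' moduli (or relaxation time) as dots against the chosen x variable,
#' coloured by pattern. No computation happens here; the data are exactly
#' the sweep rows.
#'
#' @param data A `homog_ensemble` tibble.
#' @param x Name of the x column (e.g. `"fat_realized"`,
#'   `"cpa_realized"`).
#' @param y2 Second series: `"loss"` (default) or `"tau"`.
#' @param colour Grouping column name (default whichever pattern varies).
#' @return A ggplot.
#' @export
plot_sweep <- function(data, x = "fat_realized", y2 = c("loss", "tau"),
                       colour = NULL) {
  y2 <- match.arg(y2)
  if (is.null(colour)) {
    colour <- if (length(unique(data$fib_pattern)) > 1) "fib_pattern"
    else "fat_pattern"
  }
  df <- tibble::as_tibble(data)
  df$.grp <- factor(df[[colour]])
  ggplot2::ggplot(df, ggplot2::aes(.data[[x]], colour = .data$.grp)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$storage), shape = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data[[y2]]), shape = 20) +
    ggplot2::labs(x = x, y = "modulus (Pa)",
                  colour = "pattern",
                  subtitle = sprintf("circles: storage; dots: %s", y2))
}
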