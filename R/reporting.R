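# Figure regeneration: every figure is written alongside a CSV "twin" holding
# exactly the numbers drawn, so plotted content is testable without reading
# pixels. PNG always; SVG too when the R build has cairo support.

save_plot_files <- function(p, path_base, width = 6, height = 4.5) {
  files <- paste0(path_base, ".png")
  ggplot2::ggsave(files, p, width = width, height = height, dpi = 100)
  if (isTRUE(unname(capabilities("cairo")))) {
    svg_path <- paste0(path_base, ".svg")
    grDevices::svg(svg_path, width = width, height = height)
    tryCatch(print(p), finally = grDevices::dev.off())
    files <- c(files, svg_path)
  }
  files
}

write_twin <- function(df, path_base) {
  csv <- paste0(path_base, ".csv")
  utils::write.csv(df, csv, row.names = FALSE)
  csv
}

plot_bundle <- function(figures, csvs, data) {
  structure(list(figures = figures, csvs = csvs, data = data),
            class = "plot_bundle")
}

# Scott-style rule-of-thumb KDE; degenerate (zero-spread) columns get a
# single-point "density" spike instead of a curve
kde_frame <- function(v) {
  if (stats::sd(v) == 0) {
    return(data.frame(x = v[1], density = NA_real_, degenerate = TRUE))
  }
  d <- stats::density(v, bw = "nrd")
  data.frame(x = d$x, density = d$y, degenerate = FALSE)
}

#' Distribution plots (KDE and violin-with-box) for T, P and solubility
#'
#' Kernel density estimates and violin/boxplot combinations for the three
#' dataset columns, mirroring the exploratory views of the study: a
#' right-skewed solubility distribution against roughly uniform temperature
#' and pressure designs.
#'
#' @param ds A `solubility_dataset`.
#' @param out_dir Output directory (created if missing).
#' @return A `plot_bundle`: figure paths, CSV twin paths, and the plotted
#'   values (`$data$kde_<col>`, `$data$values`).
#' @export
distribution_plots <- function(ds, out_dir = "results/figures") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(ds)
  figures <- csvs <- character(0)
  data <- list()
  for (col in names(df)) {
    kf <- kde_frame(df[[col]])
    base <- file.path(out_dir, paste0("kde_", col))
    csvs <- c(csvs, write_twin(kf, base))
    data[[paste0("kde_", col)]] <- kf
    p <- if (kf$degenerate[1]) {
      ggplot2::ggplot(df, ggplot2::aes(x = .data[[col]])) +
        ggplot2::geom_dotplot(binwidth = 1) +
        ggplot2::labs(title = paste("Degenerate distribution of", col))
    } else {
      ggplot2::ggplot(kf, ggplot2::aes(x = x, y = density)) +
        ggplot2::geom_line() +
        ggplot2::labs(title = paste("Kernel density of", col), x = col)
    }
    figures <- c(figures, save_plot_files(p, base))
  }
  long <- do.call(rbind, lapply(names(df), function(col) {
    data.frame(variable = col, value = df[[col]])
  }))
  data$values <- long
  base <- file.path(out_dir, "violin_all")
  csvs <- c(csvs, write_twin(long, base))
  pv <- ggplot2::ggplot(long, ggplot2::aes(x = variable, y = value)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.8) +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(title = "Distributions of T, P and solubility")
  figures <- c(figures, save_plot_files(pv, base))
  plot_bundle(figures, csvs, data)
}

#' Parity plot: predicted versus observed solubility
#'
#' Scatter of predicted against observed values with the identity line;
#' train and test points are distinguished when a `subset` label is given.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param family Family label embedded in the output file names.
#' @param subset Optional character vector (e.g. "train"/"test") per point.
#' @param out_dir Output directory.
#' @return A `plot_bundle` whose CSV twin holds exactly the plotted pairs.
#' @export
parity_plot <- function(observed, predicted, family,
                        subset = NULL, out_dir = "results/figures") {
  stopifnot(length(observed) == length(predicted))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(observed = observed, predicted = predicted,
                   subset = subset %||% rep("all", length(observed)))
  base <- file.path(out_dir, paste0("parity_", family))
  csv <- write_twin(df, base)
  p <- ggplot2::ggplot(df, ggplot2::aes(observed, predicted, colour = subset)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(title = paste("Actual vs predicted solubility,", family))
  plot_bundle(save_plot_files(p, base), csv, list(pairs = df))
}

#' Prediction surface, contour and trend-slice plots for a tuned model
#'
#' Evaluates the model on a temperature-by-pressure grid inside the data box
#' and draws (a) a 3-D perspective surface, (b) a filled contour map, and
#' (c) solubility-vs-T curves at each pressure and solubility-vs-P curves at
#' each temperature.
#'
#' @param bundle A `tuning_result` or `model_bundle` (model + scaler).
#' @param temperatures,pressures Grid vectors (default 50 levels over the
#'   ketoprofen data box).
#' @param label Label embedded in file names.
#' @param out_dir Output directory.
#' @return A `plot_bundle`; `$data$grid` has one row per grid node
#'   (`n_T * n_P` rows).
#' @export
surface_plots <- function(bundle,
                          temperatures = seq(308.15, 338.15, length.out = 50),
                          pressures = seq(160, 400, length.out = 50),
                          label = bundle$family %||% "model",
                          out_dir = "results/figures") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- expand.grid(temperature_K = temperatures, pressure_bar = pressures,
                      KEEP.OUT.ATTRS = FALSE)
  grid$predicted <- predict_solubility(bundle, grid)
  figures <- csvs <- character(0)
  base <- file.path(out_dir, paste0("surface_", label))
  csvs <- c(csvs, write_twin(grid, base))
  z <- matrix(grid$predicted, nrow = length(temperatures))
  zlim <- range(z)
  if (diff(zlim) == 0) zlim <- zlim + c(-1, 1) * max(1e-12, abs(zlim[1]) * 0.1)
  png_path <- paste0(base, "_3d.png")
  grDevices::png(png_path, width = 600, height = 500)
  tryCatch(
    graphics::persp(temperatures, pressures, z, theta = 35, phi = 25,
                    zlim = zlim,
                    xlab = "T (K)", ylab = "P (bar)", zlab = "solubility",
                    ticktype = "detailed",
                    main = paste("Predicted solubility surface,", label)),
    finally = grDevices::dev.off())
  figures <- c(figures, png_path)
  csvs <- c(csvs, write_twin(grid, paste0(base, "_3d")))
  pc <- ggplot2::ggplot(grid, ggplot2::aes(temperature_K, pressure_bar,
                                           z = predicted)) +
    ggplot2::geom_contour_filled() +
    ggplot2::labs(title = paste("Predicted solubility contours,", label))
  figures <- c(figures, save_plot_files(pc, base))
  # trend slices on the coarse design grid
  slice <- expand.grid(temperature_K = sort(unique(round(seq(min(temperatures),
                                                             max(temperatures),
                                                             length.out = 4), 2))),
                       pressure_bar = sort(unique(round(seq(min(pressures),
                                                            max(pressures),
                                                            length.out = 7)))))
  slice$predicted <- predict_solubility(bundle, slice)
  tbase <- file.path(out_dir, paste0("trend_T_", label))
  csvs <- c(csvs, write_twin(slice, tbase))
  pt <- ggplot2::ggplot(slice, ggplot2::aes(temperature_K, predicted,
                                            colour = factor(pressure_bar))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(colour = "P (bar)",
                  title = paste("Solubility vs T at each pressure,", label))
  figures <- c(figures, save_plot_files(pt, tbase))
  pbase <- file.path(out_dir, paste0("trend_P_", label))
  csvs <- c(csvs, write_twin(slice, pbase))
  pp <- ggplot2::ggplot(slice, ggplot2::aes(pressure_bar, predicted,
                                            colour = factor(temperature_K))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(colour = "T (K)",
                  title = paste("Solubility vs P at each temperature,", label))
  figures <- c(figures, save_plot_files(pp, pbase))
  plot_bundle(figures, csvs, list(grid = grid, slices = slice))
}
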