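#' Load a solubility dataset
#'
#' Reads a `(temperature_K, pressure_bar, solubility)` table and validates it
#' as a solubility dataset: strictly positive solubility (a mole fraction),
#' positive temperature and pressure, no duplicated `(T, P)` design points.
#'
#' The bundled dataset is the full 28-point isothermal solubility table for
#' ketoprofen in supercritical CO2: four temperatures (308.15--338.15 K) by
#' seven pressures (160--400 bar).
#'
#' @param source Path to a CSV file with header columns `temperature_K`,
#'   `pressure_bar`, `solubility`, or the string `"bundled"` for the
#'   ketoprofen dataset shipped with the package.
#' @param name Label attached to the dataset.
#' @return A data frame of class `solubility_dataset` with columns
#'   `temperature_K`, `pressure_bar`, `solubility` and attributes `name` and
#'   `provenance`.
#' @export
#' @examples
#' ds <- load_dataset("bundled")
#' nrow(ds)   # 28
load_dataset <- function(source = "bundled", name = NULL) {
  if (identical(source, "bundled")) {
    path <- system.file("extdata", "ketoprofen_scco2.csv", package = "scfsol",
                        mustWork = TRUE)
    name <- name %||% "ketoprofen_scCO2"
    provenance <- "bundled ketoprofen / supercritical CO2 isothermal solubility table"
  } else {
    path <- source
    if (!file.exists(path)) stop("dataset file not found: ", path)
    name <- name %||% basename(path)
    provenance <- paste("read from", path)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("temperature_K", "pressure_bar", "solubility")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  raw <- raw[required]
  for (col in required) {
    v <- raw[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (!is.numeric(v) || anyNA(v)) {
      stop("non-numeric or missing values in column '", col, "'")
    }
    raw[[col]] <- as.numeric(v)
  }
  as_solubility_dataset(raw, name = name, provenance = provenance)
}

#' Construct and validate a solubility dataset
#'
#' @param df Data frame with columns `temperature_K`, `pressure_bar`,
#'   `solubility`.
#' @param name,provenance Labels carried as attributes.
#' @return A validated `solubility_dataset`.
#' @export
as_solubility_dataset <- function(df, name = "dataset", provenance = "") {
  df <- as.data.frame(df)[c("temperature_K", "pressure_bar", "solubility")]
  if (nrow(df) == 0) stop("dataset is empty")
  if (any(df$solubility <= 0)) {
    stop("solubility must be strictly positive (mole fraction); found ",
         sum(df$solubility <= 0), " non-positive value(s)")
  }
  if (any(df$temperature_K <= 0) || any(df$pressure_bar <= 0)) {
    stop("temperature (K) and pressure (bar) must be strictly positive")
  }
  if (anyDuplicated(df[c("temperature_K", "pressure_bar")])) {
    stop("duplicate (temperature, pressure) design points are not allowed")
  }
  rownames(df) <- NULL
  structure(df, name = name, provenance = provenance,
            class = c("solubility_dataset", "data.frame"))
}

#' Write a solubility dataset as CSV
#'
#' @param ds A `solubility_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "solubility_dataset"))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Random train/test split
#'
#' Partitions the dataset into disjoint train and test index sets. The test
#' size is `round_half_up(fraction_test * n)`; the draw is reproducible for a
#' fixed seed.
#'
#' @param ds A `solubility_dataset` (or anything with rows), `n >= 5`.
#' @param fraction_test Test fraction in (0, 1); default 0.2 (an 80/20 split).
#' @param seed Integer seed for the random draw.
#' @return List of class `data_split` with `train`, `test` (integer index
#'   vectors), `seed`, `fraction_test`.
#' @export
split_dataset <- function(ds, fraction_test = 0.2, seed = 1L) {
  n <- nrow(ds)
  if (is.null(n) || n < 5) stop("need at least 5 records to split")
  if (!(fraction_test > 0 && fraction_test < 1)) {
    stop("fraction_test must be in (0, 1)")
  }
  n_test <- round_half_up(fraction_test * n)
  if (n_test < 1 || n_test >= n) {
    stop("fraction_test = ", fraction_test, " leaves an empty train or test set")
  }
  test <- sort(with_seed(seed, sample.int(n, n_test)))
  structure(
    list(train = setdiff(seq_len(n), test), test = test,
         seed = as.integer(seed), fraction_test = fraction_test),
    class = "data_split"
  )
}

#' Fit a feature scaler (center/scale standardization)
#'
#' Centers each feature at its mean and scales by its standard deviation, so
#' scaled features have zero mean and unit spread on the fitting data. Only
#' temperature and pressure are ever scaled; the solubility target is left on
#' its raw mole-fraction scale.
#'
#' @param ds Dataset (or data frame) holding the feature columns.
#' @param features Character vector of feature column names.
#' @return A `feature_scaler` with `center` and `scale` vectors.
#' @export
fit_scaler <- function(ds, features = c("temperature_K", "pressure_bar")) {
  if (nrow(ds) == 0) stop("cannot fit a scaler on an empty dataset")
  x <- as.matrix(as.data.frame(ds)[features])
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  if (nrow(x) == 1) scale[] <- NA_real_
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    stop("constant (zero-spread) feature; cannot scale: ",
         paste(features[!is.finite(scale) | scale <= 0], collapse = ", "))
  }
  structure(list(center = center, scale = scale, features = features),
            class = "feature_scaler")
}

#' Apply / invert a feature scaler
#'
#' @param scaler A `feature_scaler`.
#' @param x Data frame or matrix holding the scaler's feature columns (for
#'   `apply_scaler`) or a scaled matrix (for `invert_scaler`).
#' @return Numeric matrix of scaled (resp. original-unit) features.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  m <- as.matrix(as.data.frame(x)[scaler$features])
  sweep(sweep(m, 2, scaler$center), 2, scaler$scale, `/`)
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "feature_scaler"))
  m <- as.matrix(x)
  sweep(sweep(m, 2, scaler$scale, `*`), 2, scaler$center, `+`)
}
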