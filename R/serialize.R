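# JSON serialization of fitted models (with their feature scaler), so a
# tuned model can be stored as text and reloaded for prediction.

model_payload <- function(model) {
  if (inherits(model, "scfsol_ppr")) {
    list(class = "scfsol_ppr", degree = model$degree,
         penalty_weight = model$penalty_weight,
         n_parameters = model$n_parameters,
         box = list(lo = unname(model$box$lo), hi = unname(model$box$hi)),
         leaves = lapply(model$leaves, function(l) {
           list(lo = unname(l$box$lo), hi = unname(l$box$hi),
                coef = unname(l$coef), n = l$n)
         }))
  } else if (inherits(model, "scfsol_krr")) {
    list(class = "scfsol_krr", x = unname(model$x), alpha = model$alpha,
         lambda = model$lambda, gamma = model$gamma, kernel = model$kernel,
         effective_dof = model$effective_dof)
  } else if (inherits(model, "scfsol_tdr")) {
    list(class = "scfsol_tdr", coefficients = unname(model$coefficients),
         power = model$power, ridge = model$ridge,
         dispersion = model$dispersion, k = model$k)
  } else stop("cannot serialize model of class ", paste(class(model), collapse = "/"))
}

rebuild_model <- function(payload) {
  cls <- payload$class
  if (cls == "scfsol_ppr") {
    structure(list(
      leaves = lapply(payload$leaves, function(l) {
        list(box = list(lo = as.numeric(l$lo), hi = as.numeric(l$hi)),
             coef = as.numeric(l$coef), n = l$n)
      }),
      degree = payload$degree,
      box = list(lo = as.numeric(payload$box$lo), hi = as.numeric(payload$box$hi)),
      penalty_weight = payload$penalty_weight,
      n_parameters = payload$n_parameters), class = "scfsol_ppr")
  } else if (cls == "scfsol_krr") {
    x <- payload$x
    if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
    structure(list(x = as.matrix(x), alpha = as.numeric(payload$alpha),
                   lambda = payload$lambda, gamma = payload$gamma,
                   kernel = payload$kernel,
                   effective_dof = payload$effective_dof),
              class = "scfsol_krr")
  } else if (cls == "scfsol_tdr") {
    structure(list(coefficients = as.numeric(payload$coefficients),
                   power = payload$power, ridge = payload$ridge,
                   dispersion = payload$dispersion, k = payload$k),
              class = "scfsol_tdr")
  } else stop("unknown serialized model class: ", cls)
}

#' Save / load a tuned model as JSON
#'
#' The bundle stores the model family, selected hyperparameters, the feature
#' scaler fitted on the training subset, and the model's own coefficients, so
#' predictions on raw `(temperature_K, pressure_bar)` queries are fully
#' reproducible from the text file alone.
#'
#' @param result A `tuning_result` from [tune_model()], or a list with
#'   elements `family`, `model`, `scaler`, `best_hyperparameters`.
#' @param path JSON file path.
#' @return `path` invisibly (`save_model_json`); a `model_bundle`
#'   (`load_model_json`).
#' @export
save_model_json <- function(result, path) {
  bundle <- list(
    family = result$family,
    hyperparameters = result$best_hyperparameters,
    scaler = list(center = as.list(result$scaler$center),
                  scale = as.list(result$scaler$scale),
                  features = result$scaler$features),
    model = model_payload(result$model))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  scaler <- structure(list(center = unlist(b$scaler$center),
                           scale = unlist(b$scaler$scale),
                           features = unlist(b$scaler$features)),
                      class = "feature_scaler")
  structure(list(family = b$family, hyperparameters = b$hyperparameters,
                 scaler = scaler, model = rebuild_model(b$model)),
            class = "model_bundle")
}

#' Predict solubility from a model bundle on raw (T, P) queries
#'
#' @param bundle A `model_bundle` (or `tuning_result`).
#' @param newdata Data frame with columns `temperature_K`, `pressure_bar`.
#' @return Predicted mole-fraction solubility.
#' @export
predict_solubility <- function(bundle, newdata) {
  predict(bundle$model, apply_scaler(bundle$scaler, newdata))
}
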