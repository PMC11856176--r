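#' Validate a paired logger/station temperature series
#'
#' Checks the structural preconditions for fitting a station-to-scene
#' correction model: strictly hourly timestamps, equal-length columns, and at
#' least `min_rows` paired rows (default 48 — two days of hourly records, the
#' minimum recommended for reliable retrodiction).
#'
#' @param paired Tibble with columns `timestamp`, `station_temp_C`,
#'   `scene_temp_C` and optional covariates `humidity_pct`, `wind_speed_ms`,
#'   `rainfall_mm`.
#' @param min_rows Minimum number of paired rows required.
#' @param require_scene Whether `scene_temp_C` must be present (FALSE when
#'   validating a station-only retrodiction series).
#' @return `paired`, invisibly, with `timestamp` parsed to POSIXct.
#' @export
validate_paired_series <- function(paired, min_rows = 48, require_scene = TRUE) {
  paired <- tibble::as_tibble(paired)
  need <- c("timestamp", "station_temp_C", if (require_scene) "scene_temp_C")
  missing <- setdiff(need, names(paired))
  if (length(missing) > 0) {
    rlang::abort(paste0("Paired series missing column(s): ", paste(missing, collapse = ", ")))
  }
  paired$timestamp <- parse_local_dt(paired$timestamp)
  if (nrow(paired) < min_rows) {
    rlang::abort(paste0(
      "Insufficient temperature data: ", nrow(paired), " hourly rows; at least ",
      min_rows, " (2 days recorded at one-hour intervals) are required."
    ))
  }
  gaps <- diff(as.numeric(paired$timestamp)) / 3600
  if (any(abs(gaps - 1) > 1e-6)) {
    rlang::abort("Timestamps must be strictly increasing at a fixed 1 h spacing (no gaps).")
  }
  invisible(paired)
}

#' Read a paired temperature CSV
#'
#' @param path CSV with header `timestamp, station_temp_C, scene_temp_C,
#'   humidity_pct, wind_speed_ms, rainfall_mm`; ISO-8601 timestamps; empty
#'   cells are missing values.
#' @return Tibble with `timestamp` parsed.
#' @export
read_paired_series <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$timestamp <- parse_local_dt(raw$timestamp)
  tibble::as_tibble(raw)
}

new_correction_model <- function(kind, fit, features, scaler, mad_C, rmse_C, diagnostics) {
  structure(
    list(
      kind = kind, fit = fit, features = features, scaler = scaler,
      mad_C = mad_C, rmse_C = rmse_C, diagnostics = diagnostics
    ),
    class = c(paste0("correction_", kind), "correction_model")
  )
}

# 5-fold blocked cross-validation over contiguous hour blocks: refit on the
# complement of each block, predict the block, pool errors. Time-series aware
# in the minimal sense that folds are contiguous, never interleaved hours.
blocked_cv_errors <- function(paired, fitter, folds = 5) {
  n <- nrow(paired)
  fold_id <- cut(seq_len(n), breaks = folds, labels = FALSE)
  purrr::map(seq_len(folds), function(k) {
    train <- paired[fold_id != k, , drop = FALSE]
    test <- paired[fold_id == k, , drop = FALSE]
    m <- fitter(train)
    predict(m, test) - test$scene_temp_C
  }) |> unlist()
}

mad_rmse <- function(errors) {
  c(mad_C = mean(abs(errors)), rmse_C = sqrt(mean(errors^2)))
}

#' Fit a quadratic station-to-scene correction model
#'
#' Least-squares fit of `scene = a + b * station + c * station^2` on paired
#' hourly observations. Diagnostics (MAD, RMSE) default to 5-fold blocked
#' cross-validation over contiguous hour blocks; set `cv = FALSE` for
#' in-sample residual diagnostics.
#'
#' @inheritParams validate_paired_series
#' @param cv Use blocked cross-validation for the reported MAD/RMSE.
#' @return A `correction_model` with `kind = "quadratic"`.
#' @export
fit_quadratic <- function(paired, cv = TRUE) {
  paired <- validate_paired_series(paired)
  if (stats::sd(paired$station_temp_C) < 1e-12) {
    rlang::abort("Degenerate design: station temperatures are all identical; quadratic fit is unidentifiable.")
  }
  fit_core <- function(df) {
    fit <- stats::lm(scene_temp_C ~ station_temp_C + I(station_temp_C^2), data = df)
    new_correction_model("quadratic", fit,
      features = "station_temp_C",
      scaler = NULL, mad_C = NA_real_, rmse_C = NA_real_, diagnostics = NULL
    )
  }
  model <- fit_core(paired)
  errors <- if (cv) {
    blocked_cv_errors(paired, fit_core)
  } else {
    predict(model, paired) - paired$scene_temp_C
  }
  d <- mad_rmse(errors)
  model$mad_C <- d[["mad_C"]]
  model$rmse_C <- d[["rmse_C"]]
  model$diagnostics <- list(scheme = if (cv) "blocked_cv_5" else "in_sample", n = nrow(paired))
  model
}

#' Fit a support-vector-regression correction model
#'
#' Radial-basis-kernel epsilon-SVR of scene temperature on the station
#' temperature plus selected environmental covariates (humidity, wind speed,
#' rainfall). Features are z-standardized with training-window statistics.
#' Covariates requested but absent from the data are dropped with a warning
#' (falling back toward a station-temperature-only feature set), since field
#' cases often record temperature alone.
#'
#' @inheritParams fit_quadratic
#' @param features Character vector of covariate columns to use alongside
#'   `station_temp_C`; any of `"humidity_pct"`, `"wind_speed_ms"`,
#'   `"rainfall_mm"`.
#' @param cost,epsilon SVR hyperparameters (regularization and tube width).
#' @param gamma RBF kernel width; `NULL` uses `1/n_features` on the
#'   standardized features (unit-variance scale heuristic).
#' @return A `correction_model` with `kind = "svr"`.
#' @export
fit_svr <- function(paired, features = character(), cv = TRUE,
                    cost = 10, epsilon = 0.1, gamma = NULL) {
  paired <- validate_paired_series(paired)
  features <- unique(as.character(features))
  absent <- setdiff(features, names(paired))
  if (length(absent) > 0) {
    rlang::warn(paste0(
      "Requested covariate(s) absent and dropped: ", paste(absent, collapse = ", "),
      "; falling back to the remaining feature set."
    ))
    features <- setdiff(features, absent)
  }
  feats <- c("station_temp_C", features)
  na_feats <- feats[purrr::map_lgl(feats, ~ anyNA(paired[[.x]]))]
  if (length(na_feats) > 0) {
    rlang::abort(paste0("Missing values in feature column(s): ", paste(na_feats, collapse = ", ")))
  }
  if (is.null(gamma)) gamma <- 1 / length(feats)
  fit_core <- function(df) {
    x <- as.matrix(df[feats])
    mu <- colMeans(x)
    sd_ <- apply(x, 2, stats::sd)
    sd_[sd_ < 1e-12] <- 1 # constant feature: leave centred at zero
    z <- sweep(sweep(x, 2, mu), 2, sd_, "/")
    fit <- e1071::svm(
      x = z, y = df$scene_temp_C, type = "eps-regression",
      kernel = "radial", cost = cost, epsilon = epsilon, gamma = gamma,
      scale = FALSE, fitted = FALSE
    )
    new_correction_model("svr", fit,
      features = feats,
      scaler = list(mean = mu, sd = sd_),
      mad_C = NA_real_, rmse_C = NA_real_, diagnostics = NULL
    )
  }
  model <- fit_core(paired)
  errors <- if (cv) {
    blocked_cv_errors(paired, fit_core)
  } else {
    predict(model, paired) - paired$scene_temp_C
  }
  d <- mad_rmse(errors)
  model$mad_C <- d[["mad_C"]]
  model$rmse_C <- d[["rmse_C"]]
  model$diagnostics <- list(
    scheme = if (cv) "blocked_cv_5" else "in_sample", n = nrow(paired),
    cost = cost, epsilon = epsilon, gamma = gamma
  )
  model
}

#' @export
predict.correction_model <- function(object, newdata, ...) {
  newdata <- tibble::as_tibble(newdata)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    rlang::abort(paste0("Prediction data missing feature(s): ", paste(missing, collapse = ", ")))
  }
  if (object$kind == "quadratic") {
    unname(stats::predict(object$fit, newdata = newdata))
  } else {
    x <- as.matrix(newdata[object$features])
    z <- sweep(sweep(x, 2, object$scaler$mean), 2, object$scaler$sd, "/")
    if (object$fit$tot.nSV == 0) {
      # every training point sat inside the epsilon tube: the SVR is the
      # constant -rho
      rep(-object$fit$rho, nrow(z))
    } else {
      unname(stats::predict(object$fit, z))
    }
  }
}

#' Evaluate a correction model on paired data
#'
#' @param model A fitted `correction_model`.
#' @param paired Paired series with observed `scene_temp_C`.
#' @return Tibble with one row: `mad_C` (mean absolute difference) and
#'   `rmse_C` (root mean square error) of the model's predictions.
#' @export
evaluate_model <- function(model, paired) {
  paired <- validate_paired_series(paired, min_rows = 1)
  errors <- predict(model, paired) - paired$scene_temp_C
  d <- mad_rmse(errors)
  tibble::tibble(kind = model$kind, mad_C = d[["mad_C"]], rmse_C = d[["rmse_C"]])
}

#' Select the best correction model
#'
#' Picks the candidate with the lowest RMSE; ties broken by lower MAD, then
#' by preferring the simpler quadratic form over SVR.
#'
#' @param candidates List of fitted `correction_model` objects with
#'   diagnostics populated.
#' @return The winning `correction_model`.
#' @export
select_model <- function(candidates) {
  if (inherits(candidates, "correction_model")) candidates <- list(candidates)
  if (length(candidates) == 0) rlang::abort("No candidate models supplied.")
  simplicity <- c(quadratic = 0, svr = 1)
  key <- purrr::map(candidates, ~ c(.x$rmse_C, .x$mad_C, simplicity[[.x$kind]]))
  ord <- order(
    purrr::map_dbl(key, 1),
    purrr::map_dbl(key, 2),
    purrr::map_dbl(key, 3)
  )
  candidates[[ord[1]]]
}

#' Retrodict hourly scene temperatures from station records
#'
#' Applies a fitted correction model to an hourly station series (with any
#' covariates the model uses) over the pre-discovery window, returning the
#' predicted scene series and its arithmetic mean. Gaps in the station
#' series are an error: no silent interpolation.
#'
#' @param model A fitted `correction_model`.
#' @param station Tibble with `timestamp`, `station_temp_C` and the model's
#'   covariates, hourly, covering the requested window.
#' @return Tibble `timestamp, temp_C` of predicted scene temperatures with a
#'   `mean_C` attribute.
#' @export
retrodict <- function(model, station) {
  station <- validate_paired_series(station, min_rows = 1, require_scene = FALSE)
  pred <- predict(model, station)
  out <- tibble::tibble(timestamp = station$timestamp, temp_C = pred)
  attr(out, "mean_C") <- mean(pred)
  out
}

#' @export
print.correction_model <- function(x, ...) {
  cat("<correction_model> kind=", x$kind,
    "  MAD=", signif(x$mad_C, 4), " °C  RMSE=", signif(x$rmse_C, 4), " °C  (",
    x$diagnostics$scheme, ", n=", x$diagnostics$n, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a correction model
#'
#' For the quadratic model, the intercept/linear/quadratic coefficients with
#' standard errors; for the SVR model, one row per feature describing the
#' standardization applied.
#'
#' @param x A `correction_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy correction_model
#' @export
tidy.correction_model <- function(x, ...) {
  if (x$kind == "quadratic") {
    # noise-free calibration data trip summary.lm's perfect-fit caution;
    # the coefficients and (degenerate) SEs are still what we want
    s <- suppressWarnings(summary(x$fit))$coefficients
    tibble::tibble(
      term = c("intercept", "station", "station^2"),
      estimate = unname(s[, 1]),
      std.error = unname(s[, 2])
    )
  } else {
    tibble::tibble(
      term = x$features,
      center = unname(x$scaler$mean),
      scale = unname(x$scaler$sd)
    )
  }
}

#' One-row model summary
#'
#' @param x A `correction_model`.
#' @param ... Unused.
#' @return Tibble with `kind`, `mad_C`, `rmse_C`, `scheme`, `n`.
#' @method glance correction_model
#' @export
glance.correction_model <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, mad_C = x$mad_C, rmse_C = x$rmse_C,
    scheme = x$diagnostics$scheme, n = x$diagnostics$n
  )
}

#' Plot observed vs predicted scene temperature
#'
#' @param object A `correction_model`.
#' @param paired Paired series to plot against.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correction_model
#' @export
autoplot.correction_model <- function(object, paired, ...) {
  paired <- validate_paired_series(paired, min_rows = 1)
  df <- dplyr::mutate(paired, predicted = predict(object, paired))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$scene_temp_C, colour = "scene (logger)")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted, colour = "predicted")) +
    ggplot2::labs(
      x = NULL, y = "Temperature (°C)", colour = NULL,
      title = paste0("Scene-temperature retrodiction (", object$kind, ")")
    ) +
    ggplot2::theme_minimal()
}
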