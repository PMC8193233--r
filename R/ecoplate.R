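# Community-level physiological profiling from Biolog EcoMicroplate series.
#
# A plate series is a long tibble with columns sample_id, time_h, wavelength
# (590/750), well (0-based index) and od. All downstream CLPP metrics work on
# the blank-corrected colour response at one snapshot time: per substrate,
# Ci = mean over replicate wells of (A590 - A750), R = the same for the water
# control, and the working value is max(Ci - R, 0). Negative corrected values
# are clamped to zero before every metric.

#' Read an EcoMicroplate absorbance series
#'
#' Reads a long-format plate CSV with header
#' `sample_id,time_h,wavelength,well,od`. Wells may be labels `A1..H12`
#' (row-major) or integers `0..95`. The series is validated: both
#' wavelengths (590 and 750 nm) must be present for every sample at every
#' timepoint and all absorbances must be finite and non-negative.
#'
#' @param path path to the plate CSV file.
#' @param layout substrate layout tibble; defaults to the standard EcoPlate
#'   layout [eco_layout()].
#' @return a `plate_series` tibble with columns `sample_id`, `time_h`,
#'   `wavelength`, `well`, `od`, carrying the layout as an attribute.
#' @export
read_plate_series <- function(path, layout = eco_layout()) {
  if (!file.exists(path)) abort(paste("Plate file not found:", path))
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("sample_id", "time_h", "wavelength", "well", "od")
  if (!all(need %in% names(raw))) {
    abort(paste("Plate CSV must have columns:", paste(need, collapse = ", ")))
  }
  plate_series(
    tibble(
      sample_id = as.character(raw$sample_id),
      time_h = as.numeric(raw$time_h),
      wavelength = as.integer(raw$wavelength),
      well = well_index(raw$well),
      od = as.numeric(raw$od)
    ),
    layout = layout
  )
}

#' Construct and validate a plate series
#'
#' @param readings long tibble with columns `sample_id`, `time_h`,
#'   `wavelength`, `well` (0-based), `od`.
#' @param layout substrate layout tibble.
#' @return the validated `plate_series` tibble.
#' @export
plate_series <- function(readings, layout = eco_layout()) {
  validate_layout(layout)
  x <- as_tibble(readings)
  if (!all(x$wavelength %in% c(590L, 750L))) {
    abort("Wavelength must be 590 or 750 nm.")
  }
  if (any(!is.finite(x$od))) abort("Absorbance values must be finite.")
  if (any(x$od < 0)) {
    bad <- x[x$od < 0, ][1, ]
    abort(sprintf(
      "Negative absorbance for sample %s, t=%g h, %d nm, well %d.",
      bad$sample_id, bad$time_h, bad$wavelength, bad$well))
  }
  # both wavelengths at every (sample, time)
  cov <- x |>
    distinct(.data$sample_id, .data$time_h, .data$wavelength) |>
    dplyr::count(.data$sample_id, .data$time_h)
  if (any(cov$n != 2)) {
    bad <- cov[cov$n != 2, ][1, ]
    abort(sprintf("Missing wavelength for sample %s at t=%g h.",
                  bad$sample_id, bad$time_h))
  }
  x <- arrange(x, .data$sample_id, .data$time_h, .data$wavelength, .data$well)
  attr(x, "layout") <- layout
  class(x) <- c("plate_series", class(x))
  x
}

plate_layout <- function(series, layout = NULL) {
  layout %||% attr(series, "layout") %||% eco_layout()
}

# choose the snapshot time: exact match, else nearest within `tolerance`
snap_time <- function(times, time_h, tolerance = 6) {
  d <- abs(times - time_h)
  i <- which.min(d)
  if (d[i] > tolerance + 1e-9) {
    abort(sprintf(
      "No timepoint within %g h of t=%g h (available: %s).",
      tolerance, time_h, paste(sort(unique(times)), collapse = ", ")))
  }
  times[i]
}

#' Blank-corrected colour response at a snapshot time
#'
#' For each substrate, computes the mean over its replicate wells of the
#' differential absorbance (A590 - A750), subtracts the water-control mean
#' `R`, and clamps negative values to zero. The default snapshot is the
#' 72-h incubation reading; if the exact time is absent, the nearest
#' timepoint within `tolerance` hours is used, or (with
#' `interpolate = TRUE`) linear interpolation between bracketing times.
#'
#' @param series a `plate_series` tibble (one or more samples).
#' @param time_h snapshot incubation time in hours (default 72).
#' @param layout substrate layout; defaults to the layout attached to the
#'   series.
#' @param tolerance maximal snap distance in hours when the exact time is
#'   missing (default 6).
#' @param interpolate linearly interpolate between the bracketing timepoints
#'   instead of snapping (default `FALSE`).
#' @return a `color_response` tibble with one row per sample x substrate:
#'   `sample_id`, `time_h`, `substrate_id`, `guild`, `raw_ci` (pre-clamp
#'   Ci - R plus control), `control_value`, `value` (clamped Ci - R).
#' @export
blank_corrected_response <- function(series, time_h = 72, layout = NULL,
                                     tolerance = 6, interpolate = FALSE) {
  layout <- validate_layout(plate_layout(series, layout))
  x <- as_tibble(series)
  well_map <- tibble(
    substrate_id = rep(layout$substrate_id, lengths(layout$wells)),
    well = unlist(layout$wells)
  )
  if (!all(well_map$well %in% x$well)) {
    abort("Plate readings do not cover every well of the layout.")
  }

  resp_at <- function(xt, t) {
    wide <- xt |>
      tidyr::pivot_wider(names_from = "wavelength", values_from = "od",
                         names_prefix = "a") |>
      mutate(diff = .data$a590 - .data$a750) |>
      dplyr::inner_join(well_map, by = "well") |>
      group_by(.data$sample_id, .data$substrate_id) |>
      summarise(ci = mean(.data$diff), .groups = "drop")
    ctl <- layout$substrate_id[layout$is_control]
    wide |>
      group_by(.data$sample_id) |>
      mutate(control_value = .data$ci[.data$substrate_id == ctl]) |>
      ungroup() |>
      filter(.data$substrate_id != ctl) |>
      mutate(time_h = t)
  }

  out <- x |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map(function(xs) {
      times <- sort(unique(xs$time_h))
      if (interpolate && !any(abs(times - time_h) < 1e-9)) {
        lo <- max(times[times <= time_h]); hi <- min(times[times >= time_h])
        if (!is.finite(lo) || !is.finite(hi)) {
          abort("Snapshot time outside the sampled range; cannot interpolate.")
        }
        w <- if (hi > lo) (time_h - lo) / (hi - lo) else 0
        r_lo <- resp_at(filter(xs, .data$time_h == lo), time_h)
        r_hi <- resp_at(filter(xs, .data$time_h == hi), time_h)
        r_lo |>
          mutate(ci = (1 - w) * .data$ci + w * r_hi$ci,
                 control_value = (1 - w) * .data$control_value +
                   w * r_hi$control_value)
      } else {
        t_use <- snap_time(times, time_h, tolerance)
        resp_at(filter(xs, .data$time_h == t_use), t_use)
      }
    }) |>
    bind_rows()

  out <- out |>
    mutate(raw_ci = .data$ci,
           value = pmax(.data$ci - .data$control_value, 0)) |>
    left_join(select(layout, "substrate_id", "guild"), by = "substrate_id") |>
    select("sample_id", "time_h", "substrate_id", "guild",
           "raw_ci", "control_value", "value") |>
    arrange(.data$sample_id, .data$substrate_id)
  class(out) <- c("color_response", class(out))
  out
}

# Extract the clamped response vector from a color_response (single sample)
# or pass a numeric vector through.
response_values <- function(resp) {
  if (is.numeric(resp)) {
    if (any(!is.finite(resp)) || any(resp < 0)) {
      abort("Response values must be finite and non-negative.")
    }
    return(resp)
  }
  stopifnot(is.data.frame(resp))
  if (length(unique(resp$sample_id)) != 1) {
    abort("Expected a single-sample colour response; use clpp_metrics() for many.")
  }
  setNames(resp$value, resp$substrate_id)
}

#' Average well-colour development (AWCD)
#'
#' Arithmetic mean of the clamped blank-corrected responses over the `n`
#' substrate wells: `AWCD = sum(Ci - R) / n`, with negative `Ci - R` set
#' to zero.
#'
#' @param resp a single-sample `color_response` tibble or a numeric vector of
#'   clamped responses.
#' @return a single non-negative number.
#' @export
#' @examples
#' awcd(c(0.2, 0.4, 0.6))
awcd <- function(resp) {
  v <- response_values(resp)
  if (length(v) == 0) abort("Empty response: no substrates.")
  mean(v)
}

#' McIntosh index (U)
#'
#' Euclidean norm of the clamped response vector:
#' `U = sqrt(sum(ni^2))` with `ni = max(Ci - R, 0)`.
#'
#' @inheritParams awcd
#' @return a single non-negative number.
#' @export
#' @examples
#' mcintosh_u(c(3, 4)) # 5
mcintosh_u <- function(resp) {
  v <- response_values(resp)
  sqrt(sum(v^2))
}

#' Shannon diversity (H') of the colour response
#'
#' `Pi` is the share of well `i` in the total clamped response and
#' `H' = -sum(Pi log Pi)`, with zero wells contributing nothing
#' (`0 log 0 := 0`).
#'
#' @inheritParams awcd
#' @return a single number in `[0, log(n)]`.
#' @export
#' @examples
#' shannon_h(c(1, 1)) # log(2)
shannon_h <- function(resp) {
  v <- response_values(resp)
  tot <- sum(v)
  if (tot <= 0) abort("Degenerate plate: all responses are zero; H' undefined.")
  p <- v[v > 0] / tot
  -sum(p * log(p))
}

#' AWCD-normalised response intensities (Rsi)
#'
#' `Rsi = (Ci - R) / AWCD` on the clamped responses, so that the values sum
#' to the number of substrates.
#'
#' @inheritParams awcd
#' @return named numeric vector of Rsi values.
#' @export
normalize_rsi <- function(resp) {
  v <- response_values(resp)
  a <- awcd(v)
  if (a <= 0) abort("Degenerate plate: AWCD is zero; Rsi undefined.")
  v / a
}

#' Per-sample CLPP summary metrics
#'
#' Computes AWCD, McIntosh U and Shannon H' for every sample of a colour
#' response (or directly from a plate series at a snapshot time).
#'
#' @param resp a `color_response` tibble (any number of samples), or a
#'   `plate_series` (then `time_h` etc. are honoured).
#' @param ... passed to [blank_corrected_response()] when `resp` is a plate
#'   series.
#' @return tibble with columns `sample_id`, `time_h`, `n_substrates`,
#'   `awcd`, `mcintosh_u`, `shannon_h`.
#' @export
clpp_metrics <- function(resp, ...) {
  if (inherits(resp, "plate_series")) {
    resp <- blank_corrected_response(resp, ...)
  }
  resp |>
    group_by(.data$sample_id, .data$time_h) |>
    summarise(
      n_substrates = dplyr::n(),
      awcd = mean(.data$value),
      mcintosh_u = sqrt(sum(.data$value^2)),
      shannon_h = {
        tot <- sum(.data$value)
        if (tot > 0) {
          p <- .data$value[.data$value > 0] / tot
          -sum(p * log(p))
        } else NA_real_
      },
      .groups = "drop"
    )
}

#' AWCD kinetics over incubation time
#'
#' AWCD computed at every available timepoint of the series, per sample, in
#' time order.
#'
#' @param series a `plate_series` tibble.
#' @param layout substrate layout (defaults to the attached layout).
#' @return tibble `sample_id`, `time_h`, `awcd`.
#' @export
awcd_curve <- function(series, layout = NULL) {
  layout <- validate_layout(plate_layout(series, layout))
  times <- sort(unique(series$time_h))
  purrr::map(times, function(t) {
    blank_corrected_response(series, time_h = t, layout = layout,
                             tolerance = 0) |>
      group_by(.data$sample_id) |>
      summarise(awcd = mean(.data$value), .groups = "drop") |>
      mutate(time_h = t)
  }) |>
    bind_rows() |>
    select("sample_id", "time_h", "awcd") |>
    arrange(.data$sample_id, .data$time_h)
}

#' Mean colour response by substrate guild
#'
#' Per-guild arithmetic mean of the clamped substrate responses, so guilds
#' with unequal substrate counts remain comparable.
#'
#' @param resp a `color_response` tibble (any number of samples).
#' @param layout optional layout used to re-annotate guilds.
#' @return tibble `sample_id`, `time_h`, `guild`, `mean_response`.
#' @export
guild_profile <- function(resp, layout = NULL) {
  if (!is.null(layout)) {
    resp <- resp |>
      select(-"guild") |>
      left_join(select(validate_layout(layout), "substrate_id", "guild"),
                by = "substrate_id")
  }
  if (any(is.na(resp$guild))) {
    warn("Substrates without a guild are excluded from the guild profile.")
    resp <- filter(resp, !is.na(.data$guild))
  }
  resp |>
    group_by(.data$sample_id, .data$time_h, .data$guild) |>
    summarise(mean_response = mean(.data$value), .groups = "drop")
}

#' Samples-by-substrates Rsi matrix
#'
#' AWCD-normalised responses in wide form, one row per sample, ready for
#' [clpp_pca()].
#'
#' @param resp a `color_response` tibble.
#' @return tibble with `sample_id` and one column per substrate.
#' @export
rsi_matrix <- function(resp) {
  resp |>
    group_by(.data$sample_id) |>
    mutate(rsi = {
      a <- mean(.data$value)
      if (a <= 0) abort(sprintf("Degenerate plate for sample %s: AWCD = 0.",
                                .data$sample_id[1]))
      .data$value / a
    }) |>
    ungroup() |>
    select("sample_id", "substrate_id", "rsi") |>
    tidyr::pivot_wider(names_from = "substrate_id", values_from = "rsi")
}

#' PCA of normalised colour responses
#'
#' Column-centred (unscaled) principal component analysis of the Rsi matrix
#' via singular value decomposition of the covariance structure.
#'
#' @param rsi a tibble as from [rsi_matrix()] (first column `sample_id`) or
#'   a numeric matrix with sample rownames.
#' @return object of class `clpp_pca`: list with `scores` (tibble),
#'   `loadings` (tibble), `explained` (fraction of variance per axis) and
#'   `sdev`.
#' @export
clpp_pca <- function(rsi) {
  m <- otu_matrix(rsi)
  if (nrow(m) < 2 || ncol(m) < 2) abort("PCA needs >= 2 samples and >= 2 substrates.")
  if (any(!is.finite(m))) abort("PCA input must be complete and finite.")
  if (all(abs(sweep(m, 2, colMeans(m))) < 1e-12)) {
    abort("PCA input has zero variance (constant matrix).")
  }
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(
      scores = as_tibble(fit$x, rownames = "sample_id"),
      loadings = as_tibble(fit$rotation, rownames = "substrate_id"),
      explained = expl,
      sdev = fit$sdev
    ),
    class = "clpp_pca"
  )
}

#' @export
print.clpp_pca <- function(x, ...) {
  cat("CLPP PCA:", nrow(x$scores), "samples,",
      nrow(x$loadings), "substrates\n")
  k <- min(3, length(x$explained))
  cat("Explained variance:",
      paste0(sprintf("PC%d %.1f%%", seq_len(k), 100 * x$explained[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}
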