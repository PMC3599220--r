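# SCORE-style absolute-risk charts: a grid of integer-percent risks over
# sex x smoking x age x SBP x blood marker (glucose or cholesterol).

.default_axes <- function(marker) {
  list(sex = c("male", "female"),
       smoking = c(FALSE, TRUE),
       age = c(40, 50, 55, 60, 65),
       sbp = c(120, 140, 160, 180),
       marker = if (marker == "glucose") c(4, 5, 6, 7, 8) else c(4, 5, 6, 7, 8))
}

#' Build a SCORE-style risk chart
#'
#' Evaluates [predict_absolute_risk()] on every combination of the chart axes
#' and rounds (half-up) to integer percent, the convention of the printed
#' ESC charts.  Model covariates that are neither the marker, smoking nor
#' SBP (e.g. diabetes in an extended model) must be pinned via `fixed`.
#'
#' @param model a `weibull_ph_model` or `weibull_ph` fit containing the
#'   marker covariate.
#' @param marker `"glucose"` or `"cholesterol"`.
#' @param axes named list of axis values (`sex`, `smoking`, `age`, `sbp`,
#'   `marker`); defaults: ages 40/50/55/60/65, SBP 120-180 by 20, marker
#'   4-8 mmol/L (a chart convention, not a data fact).
#' @param horizon prediction horizon in years (10, 20 or 30 typically).
#' @param fixed named list of values for remaining model covariates.
#' @return An object of class `risk_chart`: long-format `$cells`
#'   (axis values + `risk` + integer `percent`), `$axes`, `$marker`,
#'   `$horizon`, `$model_id`.
#' @export
build_chart <- function(model, marker = c("glucose", "cholesterol"),
                        axes = NULL, horizon = 10, fixed = list()) {
  marker <- match.arg(marker)
  m <- as_weibull_ph_model(model)
  if (!marker %in% names(m$beta))
    stopf("model has no '%s' coefficient; cannot chart that marker", marker)
  ax <- .default_axes(marker)
  if (!is.null(axes)) ax[names(axes)] <- axes
  ax <- ax[c("sex", "smoking", "age", "sbp", "marker")]

  grid <- expand.grid(sex = ax$sex, smoking = ax$smoking, age = ax$age,
                      sbp = ax$sbp, marker = ax$marker,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  profiles <- grid
  names(profiles)[names(profiles) == "marker"] <- marker
  other <- setdiff(names(m$beta), names(profiles))
  for (k in other) {
    if (!k %in% names(fixed))
      stopf("model covariate '%s' is neither on an axis nor in `fixed`", k)
    profiles[[k]] <- fixed[[k]]
  }
  risk <- predict_absolute_risk(m, profiles, horizon)
  grid$risk <- risk
  grid$percent <- as.integer(round_half_up(100 * risk))
  structure(list(cells = grid, axes = ax, marker = marker, horizon = horizon,
                 fixed = fixed, model_id = m$label),
            class = "risk_chart")
}

#' Paired risk charts stratified by a second marker
#'
#' Builds one chart per level of a dichotomized covariate (e.g. glucose
#' charts for "low" and "high" cholesterol), pinning the stratifier at a
#' representative value per level.
#'
#' @param model joint model containing both `marker` and `stratifier`.
#' @param marker charted marker (axis).
#' @param stratifier covariate to dichotomize.
#' @param levels named numeric of representative values, default
#'   `c(low = 5.2, high = 7.0)` (mmol/L, a configurable convention).
#' @param ... passed to [build_chart()].
#' @return Named list of `risk_chart` objects, one per level.
#' @export
build_stratified_chart <- function(model, marker, stratifier,
                                   levels = c(low = 5.2, high = 7.0), ...) {
  m <- as_weibull_ph_model(model)
  if (!stratifier %in% names(m$beta))
    stopf("model has no '%s' coefficient to stratify on", stratifier)
  out <- lapply(levels, function(v) {
    fx <- list(...)$fixed %||% list()
    fx[[stratifier]] <- v
    args <- list(...)
    args$fixed <- fx
    do.call(build_chart, c(list(model = model, marker = marker), args))
  })
  names(out) <- names(levels)
  out
}

#' @export
print.risk_chart <- function(x, ...) {
  cat(sprintf("SCORE-style %d-year risk chart (%s), percent risk of fatal CVD\n",
              x$horizon, x$marker))
  cat(sprintf("model: %s\n", x$model_id))
  sbp_desc <- sort(unique(x$cells$sbp), decreasing = TRUE)
  mk_asc <- sort(unique(x$cells$marker))
  for (s in unique(x$cells$sex)) for (sm in unique(x$cells$smoking))
    for (a in unique(x$cells$age)) {
      cat(sprintf("\n%s, %s, age %g  (SBP rows desc / %s columns asc)\n",
                  s, if (sm) "smoker" else "non-smoker", a, x$marker))
      panel <- matrix(NA_integer_, length(sbp_desc), length(mk_asc),
                      dimnames = list(paste0("SBP ", sbp_desc), mk_asc))
      sub <- x$cells[x$cells$sex == s & x$cells$smoking == sm &
                       x$cells$age == a, ]
      panel[cbind(match(sub$sbp, sbp_desc), match(sub$marker, mk_asc))] <-
        sub$percent
      print(panel)
    }
  invisible(x)
}

#' @export
as.data.frame.risk_chart <- function(x, ...) {
  out <- x$cells
  out$marker_name <- x$marker
  out$horizon <- x$horizon
  out
}

#' Render a risk chart to a file
#'
#' `csv`: long-format table (one data row per cell) that [read_chart()]
#' re-parses losslessly.  `text`: per-panel matrices with the highest SBP on
#' the top row and the marker ascending along columns.  `figure`: PNG or SVG
#' of colour-banded panels with a band legend.
#'
#' @param grid a `risk_chart`.
#' @param format `"csv"`, `"text"` or `"figure"`.
#' @param path output file.
#' @param bands risk-percent cut points for the figure's colour bands.
#' @return `path`, invisibly.
#' @export
render_chart <- function(grid, format = c("csv", "text", "figure"), path,
                         bands = c(1, 2, 5, 10, 15)) {
  stopifnot(inherits(grid, "risk_chart"))
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(as.data.frame(grid), path, row.names = FALSE)
  } else if (format == "text") {
    writeLines(utils::capture.output(print(grid)), path)
  } else {
    dev <- if (grepl("\\.svg$", path)) grDevices::svg else grDevices::png
    if (identical(dev, grDevices::png)) dev(path, width = 1200, height = 900)
    else dev(path, width = 12, height = 9)
    on.exit(grDevices::dev.off())
    .plot_chart(grid, bands)
  }
  invisible(path)
}

#' Re-read a chart CSV written by [render_chart()]
#'
#' @param path CSV file.
#' @return A `risk_chart` equivalent to the rendered one.
#' @export
read_chart <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  marker <- unique(df$marker_name)
  horizon <- unique(df$horizon)
  stopifnot(length(marker) == 1, length(horizon) == 1)
  cells <- df[, c("sex", "smoking", "age", "sbp", "marker", "risk", "percent")]
  cells$smoking <- as.logical(cells$smoking)
  cells$percent <- as.integer(cells$percent)
  structure(list(cells = cells,
                 axes = list(sex = unique(cells$sex),
                             smoking = unique(cells$smoking),
                             age = sort(unique(cells$age)),
                             sbp = sort(unique(cells$sbp)),
                             marker = sort(unique(cells$marker))),
                 marker = marker, horizon = horizon, fixed = list(),
                 model_id = "read_chart"),
            class = "risk_chart")
}

.plot_chart <- function(x, bands) {
  cols <- grDevices::hcl.colors(length(bands) + 1, "YlOrRd", rev = TRUE)
  band_of <- function(p) findInterval(p, bands) + 1L
  sexes <- unique(x$cells$sex); smks <- unique(x$cells$smoking)
  ages <- sort(unique(x$cells$age))
  sbps <- sort(unique(x$cells$sbp))
  mks <- sort(unique(x$cells$marker))
  old <- graphics::par(mfrow = c(length(ages), length(sexes) * length(smks)),
                       mar = c(2, 3, 2, 1), oma = c(4, 2, 3, 1))
  on.exit(graphics::par(old))
  for (a in rev(ages)) for (s in sexes) for (sm in smks) {
    sub <- x$cells[x$cells$sex == s & x$cells$smoking == sm & x$cells$age == a, ]
    z <- matrix(NA_integer_, length(mks), length(sbps))
    z[cbind(match(sub$marker, mks), match(sub$sbp, sbps))] <- sub$percent
    graphics::image(seq_along(mks), seq_along(sbps), matrix(band_of(z),
                    nrow(z)), col = cols, zlim = c(1, length(cols)),
                    axes = FALSE, xlab = "", ylab = "")
    for (i in seq_along(mks)) for (j in seq_along(sbps))
      graphics::text(i, j, z[i, j], cex = 0.8)
    graphics::axis(1, seq_along(mks), mks, cex.axis = 0.7)
    graphics::axis(2, seq_along(sbps), sbps, cex.axis = 0.7, las = 1)
    graphics::mtext(sprintf("%s %s age %g", s,
                            if (sm) "smoker" else "non-smoker", a),
                    cex = 0.6, line = 0.2)
  }
  graphics::mtext(sprintf("%d-year risk of fatal CVD (%%), %s model",
                          x$horizon, x$marker), outer = TRUE, line = 1)
  leg <- c(paste0("<", bands[1]),
           paste0(utils::head(bands, -1), "-", utils::tail(bands, -1) - 1),
           paste0(">=", utils::tail(bands, 1)))
  graphics::par(fig = c(0, 1, 0, 1), oma = c(0, 0, 0, 0), new = TRUE)
  graphics::plot.new()
  graphics::legend("bottom", legend = leg, fill = cols, horiz = TRUE,
                   bty = "n", cex = 0.8)
}
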