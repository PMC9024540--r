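#' Binarize a 0-1000 suitability grid
#'
#' `cell >= threshold -> 1 else 0`; nodata propagates. The conventional
#' choice of threshold is the ensemble's TSS-maximizing cutoff learned on
#' current data (x 1000), applied unchanged to future projections.
#'
#' @param suit single-layer `raster_stack` on the 0-1000 scale (or a bare
#'   matrix).
#' @param threshold cutoff in [0, 1000].
#' @return object of class `binary_map`: single-layer `raster_stack` of
#'   {0, 1, NA} with attributes `threshold_used`.
#' @export
binarize <- function(suit, threshold) {
  if (threshold < 0 || threshold > 1000) stopf("threshold must be in [0, 1000]")
  if (is.matrix(suit))
    suit <- raster_stack(list(suitability = suit))
  m <- (suit$layers[[1L]] >= threshold) * 1
  out <- raster_stack(stats::setNames(list(m), names(suit$layers)[1L]),
                      xll = suit$xll, yll = suit$yll,
                      cellsize = suit$cellsize, crs = suit$crs)
  attr(out, "threshold_used") <- threshold
  class(out) <- c("binary_map", class(out))
  out
}

#' Species range-change statistics between two binary maps
#'
#' Per-pixel cross-tabulation of current vs future presence:
#' \itemize{
#'   \item loss: present now, absent in the future
#'   \item stable: present in both
#'   \item gain: absent now, present in the future
#'   \item absent: absent in both
#' }
#' with `percent_loss = 100 * loss / (loss + stable)`,
#' `percent_gain = 100 * gain / (loss + stable)` and
#' `range_change = percent_gain - percent_loss`. Also returns a categorical
#' change map coded -2 (loss), -1 (absent), 1 (stable), 2 (gain).
#'
#' @param current,future `binary_map`s (or 0/1 matrices) on the same grid
#'   and mask. Alternatively pass `counts` to compute the percentages from
#'   known pixel counts directly.
#' @param counts optional named list/vector with `loss`, `absent`, `stable`,
#'   `gain`; when given, `current`/`future` are ignored and no map is
#'   produced.
#' @return object of class `range_change_stats`: list with the four counts,
#'   the three percentages (unrounded), and `change_map` (a `raster_stack`
#'   or NULL).
#' @export
range_change_stats <- function(current = NULL, future = NULL, counts = NULL) {
  change_map <- NULL
  if (is.null(counts)) {
    cm <- if (is.matrix(current)) current else current$layers[[1L]]
    fm <- if (is.matrix(future)) future else future$layers[[1L]]
    if (!identical(dim(cm), dim(fm))) stopf("current/future grids differ in shape")
    if (!identical(is.na(cm), is.na(fm))) stopf("current/future masks differ")
    loss <- sum(cm == 1 & fm == 0, na.rm = TRUE)
    stable <- sum(cm == 1 & fm == 1, na.rm = TRUE)
    gain <- sum(cm == 0 & fm == 1, na.rm = TRUE)
    absent <- sum(cm == 0 & fm == 0, na.rm = TRUE)
    code <- matrix(NA_real_, nrow(cm), ncol(cm))
    code[cm == 1 & fm == 0] <- -2
    code[cm == 0 & fm == 0] <- -1
    code[cm == 1 & fm == 1] <- 1
    code[cm == 0 & fm == 1] <- 2
    if (!is.matrix(current)) {
      change_map <- raster_stack(list(range_change = code), xll = current$xll,
                                 yll = current$yll, cellsize = current$cellsize,
                                 crs = current$crs)
    } else change_map <- raster_stack(list(range_change = code))
  } else {
    counts <- as.list(counts)
    need <- c("loss", "absent", "stable", "gain")
    if (!all(need %in% names(counts)))
      stopf("counts must name: %s", paste(need, collapse = ", "))
    loss <- counts$loss; absent <- counts$absent
    stable <- counts$stable; gain <- counts$gain
  }
  denom <- loss + stable
  if (denom == 0) {
    warnf("no current presence pixels; percentages undefined")
    pl <- pg <- rc <- NA_real_
  } else {
    pl <- 100 * loss / denom
    pg <- 100 * gain / denom
    rc <- pg - pl
  }
  structure(list(loss = loss, absent = absent, stable = stable, gain = gain,
                 percent_loss = pl, percent_gain = pg, range_change = rc,
                 change_map = change_map),
            class = "range_change_stats")
}

#' @export
print.range_change_stats <- function(x, ...) {
  cat(sprintf("range change: loss %d | absent %d | stable %d | gain %d\n",
              x$loss, x$absent, x$stable, x$gain))
  cat(sprintf("  percent loss %.3f | percent gain %.3f | range change %.3f\n",
              x$percent_loss, x$percent_gain, x$range_change))
  invisible(x)
}

#' Tabulate range-change results (3-decimal serialization)
#'
#' @param stats_list named list of `range_change_stats` (names =
#'   "Scenario|EnsembleType" or supply `scenario`/`ensemble_type`).
#' @param scenario,ensemble_type optional character vectors parallel to
#'   `stats_list`.
#' @return data.frame with columns Scenario, EnsembleType, Loss, Absent,
#'   Stable, Gain, PercentLoss, PercentGain, RangeChange (percentages
#'   rounded to 3 decimals).
#' @export
range_change_table <- function(stats_list, scenario = NULL, ensemble_type = NULL) {
  if (is.null(scenario)) {
    parts <- strsplit(names(stats_list) %||%
                        as.character(seq_along(stats_list)), "\\|")
    scenario <- vapply(parts, `[`, "", 1L)
    ensemble_type <- vapply(parts, function(p) p[min(2L, length(p))], "")
  }
  do.call(rbind, lapply(seq_along(stats_list), function(i) {
    s <- stats_list[[i]]
    data.frame(Scenario = scenario[i], EnsembleType = ensemble_type[i],
               Loss = s$loss, Absent = s$absent, Stable = s$stable,
               Gain = s$gain,
               PercentLoss = round(s$percent_loss, 3),
               PercentGain = round(s$percent_gain, 3),
               RangeChange = round(s$range_change, 3))
  }))
}
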