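#' Build a replicate count series for interference / plating assays
#'
#' A count series is a long tibble with one row per spotted (replicate,
#' dilution): columns `condition`, `replicate`, `count` (CFU or PFU) and
#' `dilution_factor` (the factor by which the stock was diluted, e.g.
#' `1e5` for the 10^-5 spot).
#'
#' @param condition Condition label.
#' @param counts Non-negative integer counts.
#' @param dilution_factors Positive dilution factors, recycled against
#'   `counts`.
#' @param replicate Replicate ids, recycled.
#' @param units `"CFU"` or `"PFU"`.
#' @return A `count_series` tibble.
#' @export
count_series <- function(condition, counts, dilution_factors = 1,
                         replicate = NULL, units = c("CFU", "PFU")) {
  units <- match.arg(units)
  if (!length(counts)) abort("at least one replicate count is required")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("counts must be finite and non-negative")
  }
  if (any(!is.finite(dilution_factors)) || any(dilution_factors <= 0)) {
    abort("dilution factors must be positive")
  }
  out <- tibble(condition = condition,
                replicate = replicate %||% seq_along(counts),
                count = as.numeric(counts),
                dilution_factor = as.numeric(rep_len(dilution_factors, length(counts))))
  structure(out, class = c("count_series", class(out)), units = units)
}

#' Per-replicate titers from spotted serial dilutions
#'
#' Titer = count x dilution factor.  When a replicate was spotted at
#' several dilutions, the countable dilution (raw count in
#' `countable_range`) whose count is nearest `target_count` is used; when
#' no plaques or clearings appeared at any dilution, the replicate is
#' assigned a count of 1 at its most concentrated dilution, so every
#' titer (and hence every EOP) is finite and positive.
#'
#' @param series A [count_series()].
#' @param countable_range Counts considered reliable on a spot.
#' @param target_count Preferred count within the range.
#' @return A tibble with one row per replicate: `condition`, `replicate`,
#'   `count`, `dilution_factor`, `titer`, `zero_rule` (TRUE when the
#'   1-unit floor was applied).
#' @export
titer <- function(series, countable_range = c(3, 300), target_count = 30) {
  if (!"dilution_factor" %in% names(series) ||
      any(!is.finite(series$dilution_factor))) {
    abort("every replicate needs a dilution factor")
  }
  series |>
    as_tibble() |>
    group_by(.data$condition, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      if (all(d$count == 0)) {
        i <- which.min(d$dilution_factor)   # most concentrated spot
        return(tibble(count = 1, dilution_factor = d$dilution_factor[i],
                      titer = 1 * d$dilution_factor[i], zero_rule = TRUE))
      }
      pos <- d[d$count > 0, , drop = FALSE]
      inr <- pos[pos$count >= countable_range[1] &
                   pos$count <= countable_range[2], , drop = FALSE]
      pick <- if (nrow(inr)) inr else pos
      i <- which.min(abs(pick$count - target_count))
      tibble(count = pick$count[i], dilution_factor = pick$dilution_factor[i],
             titer = pick$count[i] * pick$dilution_factor[i], zero_rule = FALSE)
    }) |>
    ungroup()
}

#' Fold change of a condition over its negative control
#'
#' `fold = mean(condition titers) / mean(control titers)`; with PFU units
#' this is the efficiency of plating (EOP).  Replicate titers are computed
#' with [titer()], including the zero-plaque rule.
#'
#' @param condition,control [count_series()] objects.
#' @param ... Passed to [titer()].
#' @return A `fold_change` one-row tibble: `condition`, `control`, `fold`,
#'   `log10_fold`, `n_condition`, `n_control`, `measure` (`"fold"` or
#'   `"EOP"`).
#' @export
fold_change <- function(condition, control, ...) {
  tc <- titer(condition, ...)
  tn <- titer(control, ...)
  mc <- mean(tc$titer); mn <- mean(tn$titer)
  if (!is.finite(mn) || mn == 0) abort("control mean titer is zero: cannot normalize")
  units <- attr(condition, "units") %||% "CFU"
  out <- tibble(
    condition = tc$condition[1], control = tn$condition[1],
    fold = mc / mn, log10_fold = log10(mc / mn),
    n_condition = nrow(tc), n_control = nrow(tn),
    measure = if (identical(units, "PFU")) "EOP" else "fold")
  structure(out, class = c("fold_change", class(out)),
            condition_titers = tc$titer, control_titers = tn$titer)
}
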