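#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point geom_vline
#'   labs facet_wrap theme_minimal autoplot
#' @export
ggplot2::autoplot

#' Plot a junction histogram
#'
#' @param object A `junction_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot junction_histogram
#' @export
autoplot.junction_histogram <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$offset, y = .data$count)) +
    geom_col(fill = "grey25") +
    labs(x = "adapter-ligation offset from protospacer start (bp)",
         y = "reads") +
    theme_minimal()
}

#' Plot per-position information content of a PAM frequency matrix
#'
#' Stacked per-base contributions scaled to the position's information
#' content — the quantity a sequence logo draws.
#'
#' @param object A `pam_pfm`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pam_pfm
#' @export
autoplot.pam_pfm <- function(object, ...) {
  bits <- information_content(object)
  long <- tidyr::pivot_longer(
    mutate(as_tibble(object), bits = bits),
    cols = dplyr::all_of(BASES), names_to = "base", values_to = "freq")
  long <- mutate(long, height = .data$freq * .data$bits)
  ggplot(long, aes(x = factor(.data$position), y = .data$height,
                   fill = .data$base)) +
    geom_col() +
    labs(x = "PAM position", y = "information content (bits)",
         fill = NULL) +
    theme_minimal()
}

#' Plot a sensorgram, optionally with a dissociation fit
#'
#' @param object A `sensorgram`.
#' @param fit Optional `bli_fit` overlaid on the dissociation phase.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sensorgram
#' @export
autoplot.sensorgram <- function(object, fit = NULL, ...) {
  p <- ggplot(as_tibble(object),
              aes(x = .data$time, y = .data$response, colour = .data$phase)) +
    geom_line() +
    labs(x = "time (min)", y = "response", colour = NULL) +
    theme_minimal()
  if (!is.null(fit)) {
    d <- object[object$phase == "dissociation", , drop = FALSE]
    t0 <- d$time[1]
    curve <- tibble(time = d$time,
                    response = fit$r0 * exp(-fit$k_off * (d$time - t0)),
                    phase = "fit")
    p <- p + geom_line(data = curve, linetype = "dashed", colour = "black")
  }
  p
}

#' Plot pre/post rotation-extension curves
#'
#' @param object A `rotation_curves` tibble.
#' @param shift Optional `rotation_shift` whose apexes are marked.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rotation_curves
#' @export
autoplot.rotation_curves <- function(object, shift = NULL, ...) {
  p <- ggplot(as_tibble(object),
              aes(x = .data$turns, y = .data$extension, colour = .data$curve)) +
    geom_point(size = 0.8) +
    labs(x = "magnet turns", y = "extension (nm)", colour = NULL) +
    theme_minimal()
  if (!is.null(shift)) {
    p <- p + geom_vline(xintercept = c(shift$apex_pre, shift$apex_post),
                        linetype = "dotted")
  }
  p
}

#' Plot an A-to-G editing profile over the protospacer
#'
#' Non-A reference positions are shown in grey (no A->G frequency is
#' defined there).
#'
#' @param object An `editing_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot editing_matrix
#' @export
autoplot.editing_matrix <- function(object, ...) {
  d <- mutate(as_tibble(object),
              freq = dplyr::coalesce(.data$a_to_g, 0),
              status = dplyr::if_else(.data$is_A, "A", "non-A"))
  ggplot(d, aes(x = factor(.data$position), y = .data$freq,
                fill = .data$status)) +
    geom_col() +
    ggplot2::scale_fill_manual(values = c("A" = "#1b7837", "non-A" = "grey70")) +
    labs(x = "protospacer position (1 = PAM-proximal)",
         y = "A-to-G frequency", fill = NULL) +
    theme_minimal()
}

#' Plot enrichment folds against library counts
#'
#' @param object A `pam_enrichment`.
#' @param threshold Fold threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pam_enrichment
#' @export
autoplot.pam_enrichment <- function(object, threshold = 5, ...) {
  d <- filter(as_tibble(object), !.data$unscorable)
  ggplot(d, aes(x = .data$library_count, y = .data$enrichment_fold)) +
    geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    labs(x = "library count", y = "fold enrichment") +
    theme_minimal()
}
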