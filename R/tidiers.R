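#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a dissociation fit
#'
#' @param x A `bli_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy bli_fit
#' @export
tidy.bli_fit <- function(x, ...) {
  se <- if (is.null(x$fit)) c(NA_real_, NA_real_) else {
    summary(x$fit)$coefficients[c("R0", "k"), "Std. Error"]
  }
  tibble(term = c("R0", "k_off"),
         estimate = c(x$r0, x$k_off),
         std.error = unname(se))
}

#' @rdname tidy.bli_fit
#' @return `glance()`: one row with `k_off`, `k_analytic`, `r0`, `rms`,
#'   `n`.
#' @method glance bli_fit
#' @export
glance.bli_fit <- function(x, ...) {
  tibble(k_off = x$k_off, k_analytic = x$k_analytic, r0 = x$r0,
         rms = x$rms, n = x$n)
}

#' Tidy a rotation-curve shift
#' @param x A `rotation_shift`.
#' @param ... Unused.
#' @method tidy rotation_shift
#' @export
tidy.rotation_shift <- function(x, ...) {
  tibble(term = c("apex_pre", "apex_post", "delta_turns"),
         estimate = c(x$apex_pre, x$apex_post, x$delta_turns))
}

#' @rdname tidy.rotation_shift
#' @param pitch_bp_per_turn Helical pitch used for the R-loop size column.
#' @method glance rotation_shift
#' @export
glance.rotation_shift <- function(x, pitch_bp_per_turn = 10.5, ...) {
  tibble(delta_turns = x$delta_turns,
         rloop_bp = rloop_size(x, pitch_bp_per_turn))
}

#' Tidy a boundary call
#' @param x A `boundary_call`.
#' @param ... Unused.
#' @method tidy boundary_call
#' @export
tidy.boundary_call <- function(x, ...) {
  tibble(five_prime = x$five_prime, three_prime = x$three_prime,
         mature_length = x$mature_length,
         support_fraction = x$support_fraction)
}

#' Tidy a cleavage call
#' @param x A `cleavage_call`.
#' @param ... Unused.
#' @method tidy cleavage_call
#' @export
tidy.cleavage_call <- function(x, ...) {
  tibble(cleaved = x$cleaved, offset = x$offset,
         sample_fraction = x$sample_fraction,
         fold_over_control = x$fold_over_control)
}
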