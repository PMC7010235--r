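#' Per-rate fluxes at a given state
#'
#' Computes the instantaneous flux (mmol/day) carried by each rate:
#' `m * k` for zero-order rates, `m * k * amount(source)` for first-order
#' rates, and `m * k * amount(source) * amount(target)` for mass-action
#' exchange, where `m` is the rate's multiplier (1 = wild type, 0 = complete
#' loss of the catalysing activity).
#'
#' @param model a [kinetic_model()].
#' @param state named numeric vector of pool amounts (non-negative).
#' @param multipliers numeric vector, one value in \[0, 1\] per rate id.
#' @return Numeric vector of fluxes named by rate id.
#' @export
rate_fluxes <- function(model, state, multipliers) {
  idx <- .flux_index(model)
  .check_flux_args(state, multipliers, idx)
  .fluxes(idx, state[model$pools$name], multipliers)
}

#' Pool time derivatives
#'
#' The derivative of each pool is the sum of fluxes of rates targeting it
#' minus the sum of fluxes of rates drawing from it. With all multipliers at
#' 1 the default model's baseline state gives derivatives of (numerically)
#' zero: the model starts at steady state.
#'
#' @inheritParams rate_fluxes
#' @return Named numeric vector of d(amount)/dt, one entry per pool
#'   (mmol/day).
#' @export
cholesterol_derivatives <- function(model, state, multipliers) {
  idx <- .flux_index(model)
  .check_flux_args(state, multipliers, idx)
  x <- state[model$pools$name]
  fl <- .fluxes(idx, x, multipliers)
  .apply_fluxes(idx, fl, length(x), model$pools$name)
}

# Precomputed integer index of the flux topology; cached on the model
# environment-free list, recomputed cheaply when absent.
.flux_index <- function(model) {
  pool_names <- model$pools$name
  r <- model$rates
  ord <- order(r$id)
  r <- r[ord, , drop = FALSE]
  list(
    id = r$id,
    k = r$k,
    law = match(r$law, c("zero_order", "first_order_in_source",
                         "mass_action")),
    src = match(r$source, pool_names, nomatch = 0L),
    tgt = match(r$target, pool_names, nomatch = 0L))
}

.check_flux_args <- function(state, multipliers, idx) {
  if (length(multipliers) != length(idx$id))
    stop("need one multiplier per rate (", length(idx$id), ")")
  if (any(!is.finite(multipliers)) || any(multipliers < 0 | multipliers > 1))
    stop("multipliers must lie in [0, 1]")
  if (any(state < 0))
    stop("negative pool amount: ",
         paste(names(state)[state < 0], collapse = ", "))
  invisible(TRUE)
}

.fluxes <- function(idx, x, m) {
  src_amt <- rep(1, length(idx$src))
  src_amt[idx$src > 0L] <- x[idx$src[idx$src > 0L]]
  tgt_amt <- rep(1, length(idx$tgt))
  tgt_amt[idx$tgt > 0L] <- x[idx$tgt[idx$tgt > 0L]]
  fl <- m * idx$k
  fo <- idx$law >= 2L
  fl[fo] <- fl[fo] * src_amt[fo]
  ma <- idx$law == 3L
  fl[ma] <- fl[ma] * tgt_amt[ma]
  stats::setNames(fl, idx$id)
}

.apply_fluxes <- function(idx, fl, n_pools, pool_names) {
  d <- numeric(n_pools)
  for (j in seq_along(fl)) {
    if (idx$src[j] > 0L) d[idx$src[j]] <- d[idx$src[j]] - fl[j]
    if (idx$tgt[j] > 0L) d[idx$tgt[j]] <- d[idx$tgt[j]] + fl[j]
  }
  stats::setNames(d, pool_names)
}
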