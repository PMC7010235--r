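#' One-at-a-time rate sensitivity sweep
#'
#' Applies a common reducing factor to a set of rates (typically the full
#' rate set mapped to one gene, since that is how mutations act), simulates
#' to the steady-state horizon, and records the resulting plasma HDL/LDL/TC
#' case/control ratios, for every factor of a grid in \[0.1, 1\].
#'
#' @param model a [kinetic_model()].
#' @param rate_set integer vector of rate ids reduced together.
#' @param factors multiplier grid, strictly increasing within \[0.1, 1\];
#'   default 0.1, 0.2, ..., 1.0.
#' @param label optional label (e.g. the gene symbol) carried in the output.
#' @param ... passed to [predict_ratios()].
#' @return A `sensitivity_curve` data.frame with columns `rate_set`,
#'   `factor`, `hdl_ratio`, `ldl_ratio`, `tc_ratio`; rows for factors whose
#'   simulation failed are dropped and the curve is marked partial.
#' @export
sweep_rates <- function(model, rate_set, factors = seq(0.1, 1, by = 0.1),
                        label = NULL, ...) {
  if (!length(rate_set)) stop("rate_set must be non-empty")
  if (!all(rate_set %in% model$rates$id))
    stop("unknown rate id: ",
         paste(setdiff(rate_set, model$rates$id), collapse = ", "))
  if (any(factors < 0.1 - 1e-12 | factors > 1 + 1e-12))
    stop("factors must lie in [0.1, 1]")
  if (is.unsorted(factors, strictly = TRUE))
    stop("factors must be strictly increasing")
  set_lab <- if (is.null(label)) paste(sort(rate_set), collapse = ",")
             else label
  rows <- vector("list", length(factors))
  partial <- FALSE
  for (i in seq_along(factors)) {
    m <- rep(1, nrow(model$rates))
    m[match(rate_set, sort(model$rates$id))] <- factors[i]
    r <- tryCatch(predict_ratios(model, multipliers = m, ...),
                  error = function(e) {
                    warning("sweep failed at factor ", factors[i], ": ",
                            conditionMessage(e))
                    NULL
                  })
    if (is.null(r)) { partial <- TRUE; next }
    rows[[i]] <- data.frame(rate_set = set_lab, factor = factors[i],
                            hdl_ratio = r[["hdl"]], ldl_ratio = r[["ldl"]],
                            tc_ratio = r[["tc"]], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("sensitivity_curve", "data.frame"),
            partial = partial)
}

#' Sensitivity sweep for one or more genes
#'
#' Convenience wrapper around [sweep_rates()]: each gene's full mapped rate
#' set is reduced together.
#'
#' @param model a [kinetic_model()].
#' @param genes gene symbols present in the model's gene map.
#' @inheritParams sweep_rates
#' @return A `sensitivity_curve` data.frame (all genes stacked, labelled by
#'   gene symbol).
#' @export
sweep_genes <- function(model, genes, factors = seq(0.1, 1, by = 0.1), ...) {
  curves <- lapply(genes, function(g) {
    ids <- model$gene_map[[g]]
    if (is.null(ids)) stop("gene ", g, " is not in the model's gene map")
    sweep_rates(model, ids, factors, label = g, ...)
  })
  out <- do.call(rbind, curves)
  structure(out, class = c("sensitivity_curve", "data.frame"))
}

#' Export a sensitivity curve as tabular text
#'
#' @param curve a `sensitivity_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
plot.sensitivity_curve <- function(x, ...) {
  sets <- unique(x$rate_set)
  op <- graphics::par(mfrow = c(1, length(sets)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in sets) {
    cx <- x[x$rate_set == s, ]
    graphics::matplot(cx$factor,
                      cbind(cx$hdl_ratio, cx$ldl_ratio, cx$tc_ratio),
                      type = "b", pch = 16, lty = 1,
                      col = c("goldenrod", "firebrick", "gray30"),
                      xlab = "rate reduction factor",
                      ylab = "case/control ratio", main = s, ...)
    graphics::abline(h = 1, lty = 3)
    graphics::legend("topleft", c("HDL", "LDL", "TC"), bty = "n",
                     col = c("goldenrod", "firebrick", "gray30"),
                     pch = 16, lty = 1)
  }
  invisible(x)
}
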