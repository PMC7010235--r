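#' Paired experimental/predicted cholesterol-ratio tables
#'
#' A `prediction_set` holds, per mutation entry, the experimental
#' case/control HDL/LDL/TC ratios and the corresponding predicted ratios
#' from up to two prediction sources (`reference` and `trained` f_mut).
#' Missing values are allowed (some mutations have only a total-cholesterol
#' measurement); a missing experimental or predicted value excludes that
#' entry pairwise from the affected lipid's metrics.
#'
#' Expected columns: `mutation` (id), `gene`, then `<src>_<lipid>` for
#' `src` in `exp`, `ref`, `trained` and `lipid` in `hdl`, `ldl`, `tc`
#' (`ref_*`/`trained_*` may be absent if the source is not available).
#'
#' @param entries data.frame as described above.
#' @return An object of class `prediction_set` (a data.frame).
#' @export
prediction_set <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("mutation", "gene", paste0("exp_", c("hdl", "ldl", "tc")))
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("prediction set is missing column(s): ", paste(miss, collapse = ", "))
  structure(entries, class = c("prediction_set", "data.frame"))
}

#' Read/write prediction tables
#'
#' Tab-separated text mirroring the test-set table: one row per mutation,
#' experimental and per-source predicted HDL/LDL/TC ratio columns, literal
#' `NA` for missing.
#'
#' @param path file path.
#' @return `read_prediction_table`: a [prediction_set()].
#' @export
read_prediction_table <- function(path) {
  prediction_set(utils::read.delim(path, stringsAsFactors = FALSE,
                                   na.strings = c("", "NA")))
}

#' @rdname read_prediction_table
#' @param pred a [prediction_set()].
#' @export
write_prediction_table <- function(pred, path) {
  utils::write.table(as.data.frame(pred), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.pair <- function(pred, lipid = c("tc", "hdl", "ldl"),
                  source = c("trained", "reference")) {
  lipid <- match.arg(lipid)
  source <- match.arg(source)
  pcol <- paste0(switch(source, trained = "trained", reference = "ref"),
                 "_", lipid)
  ecol <- paste0("exp_", lipid)
  if (!pcol %in% names(pred))
    stop("prediction set has no column ", pcol)
  y <- pred[[ecol]]
  yhat <- pred[[pcol]]
  ok <- !is.na(y) & !is.na(yhat)
  list(y = y[ok], yhat = yhat[ok], ok = ok)
}

#' Prediction error of one entry (ratio scale)
#'
#' The error is the predicted case/control ratio minus the experimental
#' case/control ratio, per lipid. A missing value yields `NA` (flagged
#' missing), never 0.
#'
#' @param pred a [prediction_set()].
#' @param lipid `"hdl"`, `"ldl"` or `"tc"`.
#' @param source `"trained"` or `"reference"`.
#' @return Numeric vector of errors, one per entry (with `NA` where either
#'   value is missing).
#' @export
ratio_error <- function(pred, lipid, source = "trained") {
  pcol <- paste0(switch(source, trained = "trained", reference = "ref"),
                 "_", lipid)
  pred[[pcol]] - pred[[paste0("exp_", lipid)]]
}

#' Percentage prediction error of one entry
#'
#' The ratio-scale error divided by the experimental ratio, times 100: the
#' error as a percentage of the experimentally observed case/control change.
#'
#' @inheritParams ratio_error
#' @return Numeric vector of percentage errors (NA where data is missing).
#' @export
percent_error <- function(pred, lipid, source = "trained") {
  e <- ratio_error(pred, lipid, source)
  y <- pred[[paste0("exp_", lipid)]]
  if (any(!is.na(y) & y == 0)) stop("zero experimental ratio")
  100 * e / y
}

#' Pearson correlation (product-moment formula)
#'
#' @param x,y numeric vectors of equal length (no missing values).
#' @return The correlation coefficient.
#' @export
pearson_cc <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  if (den == 0) return(NA_real_)
  num / den
}

#' Kendall rank correlation, tau-a (pair-sign form)
#'
#' `2 / (n (n - 1)) * sum_{i<j} sgn(x_i - x_j) sgn(y_i - y_j)`. Tied pairs
#' contribute 0; no tie correction is applied.
#'
#' @param x,y numeric vectors of equal length (no missing values).
#' @return The tau-a coefficient.
#' @export
kendall_tau_a <- function(x, y) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  ut <- upper.tri(sx)
  2 * sum(sx[ut] * sy[ut]) / (n * (n - 1))
}

.metric_funs <- list(
  pcc = function(y, yhat) pearson_cc(y, yhat),
  kcc = function(y, yhat) kendall_tau_a(y, yhat),
  mae = function(y, yhat) mean(abs(yhat - y)),
  rmse = function(y, yhat) sqrt(mean((yhat - y)^2)),
  r2 = function(y, yhat) pearson_cc(y, yhat)^2,
  r2_cod = function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))

# bootstrap tail direction per index: correlations and explained variance
# are "good when high" (p = P(perm >= obs)); error indices are "good when
# low" (p = P(perm <= obs)).
.metric_dir <- c(pcc = "ge", kcc = "ge", mae = "le", rmse = "le",
                 r2 = "ge", r2_cod = "ge")

#' Performance metrics for one lipid and prediction source
#'
#' Computes Pearson (PCC) and Kendall tau-a (KCC) correlations, MAE, RMSE
#' and R-squared between experimental and predicted case/control ratios,
#' using pairwise exclusion of missing entries. The primary `r2` field is
#' the squared Pearson coefficient (the form the headline results table
#' uses); the coefficient of determination is also reported as `r2_cod`.
#'
#' @inheritParams ratio_error
#' @param pred a [prediction_set()].
#' @return A one-row data.frame with `lipid`, `source`, `n_used`, `pcc`,
#'   `kcc`, `mae`, `rmse`, `r2`, `r2_cod`.
#' @export
compute_metrics <- function(pred, lipid, source = "trained") {
  pr <- .pair(pred, lipid, source)
  if (length(pr$y) < 2)
    stop("need at least 2 complete pairs for ", lipid, "/", source)
  vals <- lapply(.metric_funs, function(f) f(pr$y, pr$yhat))
  if (stats::var(pr$y) == 0 || stats::var(pr$yhat) == 0) {
    vals$pcc <- NA_real_
    vals$r2 <- NA_real_
    attr(vals, "reason") <- "zero variance: correlation undefined"
  }
  data.frame(lipid = lipid, source = source, n_used = length(pr$y),
             pcc = vals$pcc, kcc = vals$kcc, mae = vals$mae,
             rmse = vals$rmse, r2 = vals$r2, r2_cod = vals$r2_cod,
             stringsAsFactors = FALSE)
}

#' Permutation-bootstrap p-value of a performance index
#'
#' Shuffles the prediction vector uniformly at random `reps` times against
#' the fixed experimental vector and recomputes the index each time. The
#' p-value is the plain proportion of shuffles scoring at least as well as
#' the observed index: `perm >= obs` for correlation-type indices (PCC, KCC,
#' R-squared), `perm <= obs` for error indices (MAE, RMSE). Indices with
#' p < 0.05 are conventionally reported as significant.
#'
#' @inheritParams compute_metrics
#' @param index one of `"pcc"`, `"kcc"`, `"mae"`, `"rmse"`, `"r2"`.
#' @param reps number of shuffles (default 10000).
#' @param seed RNG seed (set for reproducibility; `NULL` leaves the RNG
#'   state alone).
#' @return Scalar p-value in (0, 1]; attributes `observed`, `reps`,
#'   `direction`.
#' @export
bootstrap_pvalue <- function(pred, lipid, source = "trained",
                             index = c("pcc", "kcc", "mae", "rmse", "r2"),
                             reps = 10000, seed = NULL) {
  index <- match.arg(index)
  if (reps < 1) stop("reps must be >= 1")
  pr <- .pair(pred, lipid, source)
  f <- .metric_funs[[index]]
  obs <- f(pr$y, pr$yhat)
  if (!is.finite(obs)) stop("observed ", index, " is not finite")
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(reps),
                 function(i) f(pr$y, sample(pr$yhat)), numeric(1))
  p <- if (.metric_dir[[index]] == "ge") mean(perm >= obs)
       else mean(perm <= obs)
  structure(p, observed = obs, reps = reps,
            direction = .metric_dir[[index]], n_used = length(pr$y))
}

#' Full assessment report
#'
#' Runs [compute_metrics()] (and optionally [bootstrap_pvalue()] per index)
#' for every available lipid and prediction source.
#'
#' @param pred a [prediction_set()].
#' @param sources prediction sources to assess (default: those present).
#' @param lipids lipids to assess.
#' @param reps bootstrap replicates per index; `0` skips p-values.
#' @param seed RNG seed for the bootstrap.
#' @return A `metric_report` data.frame, one row per (source, lipid), with
#'   metric columns and `p_<index>` columns when `reps > 0`.
#' @export
assess_predictions <- function(pred, sources = NULL,
                               lipids = c("hdl", "ldl", "tc"),
                               reps = 10000, seed = 1L) {
  if (is.null(sources)) {
    sources <- c()
    if ("ref_tc" %in% names(pred)) sources <- c(sources, "reference")
    if ("trained_tc" %in% names(pred)) sources <- c(sources, "trained")
  }
  rows <- list()
  if (!is.null(seed)) set.seed(seed)
  for (src in sources) for (lp in lipids) {
    row <- compute_metrics(pred, lp, src)
    if (reps > 0) {
      for (ix in c("pcc", "kcc", "mae", "rmse", "r2")) {
        row[[paste0("p_", ix)]] <-
          as.numeric(bootstrap_pvalue(pred, lp, src, ix, reps = reps))
      }
    }
    rows[[paste(src, lp)]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("metric_report", "data.frame"), reps = reps)
}

#' Write a metric report as tabular text
#'
#' @param report a `metric_report` from [assess_predictions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
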