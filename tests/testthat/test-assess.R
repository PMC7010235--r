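# Frozen expectations below were computed from the bundled test-set table
# with the independent formulas of this file's brute-force oracles.

test_that("ratio errors are plain prediction-minus-experiment differences", {
  ts <- load_bundled("test_set")
  e_tc <- ratio_error(ts, "tc", "trained")
  expect_equal(e_tc[ts$gene == "CETP"], 0)            # 1.01 - 1.01
  expect_equal(e_tc[ts$mutation == 1], 1.6 - 1.85)    # LDLR
  # missing stays missing, never coerced to zero
  expect_true(all(is.na(ratio_error(ts, "hdl", "trained")[
    ts$gene %in% c("APOE", "DHCR7")])))
})

test_that("percentage errors scale by the experimental ratio", {
  ts <- load_bundled("test_set")
  pe_hdl <- percent_error(ts, "hdl", "trained")
  expect_equal(pe_hdl[ts$gene == "ABCA1"], 100 * (0.66 - 0.22) / 0.22)
  pe_tc <- percent_error(ts, "tc", "trained")
  expect_equal(pe_tc[ts$gene == "DHCR7"], 100 * (0.54 - 0.2) / 0.2)
  # identical prediction and experiment give zero percent error
  ident <- prediction_set(data.frame(mutation = 1:2, gene = "X",
                                     exp_hdl = c(1, 2), exp_ldl = c(1, 2),
                                     exp_tc = c(1, 2), trained_hdl = c(1, 2),
                                     trained_ldl = c(1, 2),
                                     trained_tc = c(1, 2)))
  expect_equal(percent_error(ident, "tc"), c(0, 0))
})

test_that("pairwise missing-value exclusion gives n = 10 for TC, 8 for HDL/LDL", {
  ts <- load_bundled("test_set")
  for (src in c("trained", "reference")) {
    expect_equal(compute_metrics(ts, "tc", src)$n_used, 10L)
    expect_equal(compute_metrics(ts, "hdl", src)$n_used, 8L)
    expect_equal(compute_metrics(ts, "ldl", src)$n_used, 8L)
  }
})

test_that("perfect predictions give PCC = KCC = 1 and zero errors", {
  pred <- prediction_set(data.frame(
    mutation = 1:5, gene = "X",
    exp_hdl = c(0.2, 0.9, 1.1, 1.4, 2.2), exp_ldl = 1:5 / 2,
    exp_tc = c(3, 1, 4, 2, 5),
    trained_hdl = c(0.2, 0.9, 1.1, 1.4, 2.2), trained_ldl = 1:5 / 2,
    trained_tc = c(3, 1, 4, 2, 5)))
  for (lp in c("hdl", "ldl", "tc")) {
    mt <- compute_metrics(pred, lp, "trained")
    expect_equal(mt$pcc, 1)
    expect_equal(mt$kcc, 1)
    expect_equal(mt$mae, 0)
    expect_equal(mt$rmse, 0)
  }
})

test_that("Kendall tau-a equals exhaustive pair-sign counting", {
  ts <- load_bundled("test_set")
  brute_tau <- function(x, y) {
    n <- length(x)
    s <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      s <- s + sign(x[i] - x[j]) * sign(y[i] - y[j])
    2 * s / (n * (n - 1))
  }
  ok <- !is.na(ts$exp_tc) & !is.na(ts$trained_tc)
  expect_equal(kendall_tau_a(ts$exp_tc[ok], ts$trained_tc[ok]),
               brute_tau(ts$exp_tc[ok], ts$trained_tc[ok]),
               tolerance = 1e-15)
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(9)
    y <- rnorm(9)
    expect_equal(kendall_tau_a(x, y), brute_tau(x, y), tolerance = 1e-15)
    # without ties tau-a agrees with the standard tau implementation
    expect_equal(kendall_tau_a(x, y), cor(x, y, method = "kendall"),
                 tolerance = 1e-12)
  }
})

test_that("Pearson formula agrees with the covariance definition", {
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(10)
    y <- 2 * x + rnorm(10)
    expect_equal(pearson_cc(x, y), cor(x, y), tolerance = 1e-12)
  }
})

test_that("metrics are invariant to joint reordering; PCC to affine maps", {
  ts <- load_bundled("test_set")
  perm <- c(3, 1, 10, 5, 7, 2, 8, 6, 4, 9)
  shuffled <- prediction_set(as.data.frame(ts)[perm, ])
  m1 <- compute_metrics(ts, "tc", "trained")
  m2 <- compute_metrics(shuffled, "tc", "trained")
  expect_equal(m1[c("pcc", "kcc", "mae", "rmse", "r2")],
               m2[c("pcc", "kcc", "mae", "rmse", "r2")])
  ok <- !is.na(ts$exp_tc)
  x <- ts$exp_tc[ok]
  y <- ts$trained_tc[ok]
  expect_equal(pearson_cc(2 + 3 * x, -1 + 3 * y), pearson_cc(x, y),
               tolerance = 1e-12)
  # KCC is invariant under any monotone transform
  expect_equal(kendall_tau_a(exp(x), y^3), kendall_tau_a(x, y))
})

test_that("degenerate zero-variance vectors yield NA correlations", {
  pred <- prediction_set(data.frame(
    mutation = 1:3, gene = "X", exp_hdl = 1:3, exp_ldl = 1:3, exp_tc = 1:3,
    trained_hdl = 1, trained_ldl = 1, trained_tc = 1))
  mt <- compute_metrics(pred, "tc", "trained")
  expect_true(is.na(mt$pcc))
  expect_false(is.na(mt$mae))
})

test_that("anti-ordered predictions give bootstrap p = 1 for KCC", {
  pred <- prediction_set(data.frame(
    mutation = 1:8, gene = "X", exp_hdl = 1:8, exp_ldl = 1:8,
    exp_tc = 1:8, trained_hdl = 8:1, trained_ldl = 8:1, trained_tc = 8:1))
  p <- bootstrap_pvalue(pred, "tc", "trained", "kcc", reps = 200, seed = 1)
  expect_equal(as.numeric(p), 1)  # every permutation scores >= tau = -1
})

test_that("Monte-Carlo p-value matches exhaustive enumeration at n = 3", {
  pred <- prediction_set(data.frame(
    mutation = 1:3, gene = "X", exp_hdl = 1:3, exp_ldl = 1:3,
    exp_tc = c(1, 2, 3), trained_hdl = 1:3, trained_ldl = 1:3,
    trained_tc = c(1.1, 2.4, 2.9)))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  yhat <- c(1.1, 2.4, 2.9)
  obs <- pearson_cc(c(1, 2, 3), yhat)
  exact <- mean(vapply(perms,
                       function(p) pearson_cc(c(1, 2, 3), yhat[p]) >= obs,
                       logical(1)))
  reps <- 10000
  p_mc <- as.numeric(bootstrap_pvalue(pred, "tc", "trained", "pcc",
                                      reps = reps, seed = 3))
  se <- sqrt(exact * (1 - exact) / reps)
  expect_lt(abs(p_mc - exact), 3 * se + 1e-12)
})

test_that("seeded bootstraps reproduce; seeds differ within binomial error", {
  ts <- load_bundled("test_set")
  p1 <- bootstrap_pvalue(ts, "tc", "trained", "pcc", reps = 2000, seed = 7)
  p2 <- bootstrap_pvalue(ts, "tc", "trained", "pcc", reps = 2000, seed = 7)
  expect_identical(as.numeric(p1), as.numeric(p2))
  p3 <- bootstrap_pvalue(ts, "tc", "trained", "pcc", reps = 2000, seed = 8)
  se <- sqrt(as.numeric(p1) * (1 - as.numeric(p1)) / 2000)
  expect_lt(abs(as.numeric(p1) - as.numeric(p3)), 4 * se + 1e-3)
})

test_that("reports export with p-values and pair counts", {
  ts <- load_bundled("test_set")
  rep_ <- assess_predictions(ts, reps = 200, seed = 1)
  expect_equal(nrow(rep_), 6L)  # 2 sources x 3 lipids
  expect_true(all(c("n_used", "p_pcc", "p_rmse") %in% names(rep_)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metric_report(rep_, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 6L)
  expect_equal(back$n_used, rep_$n_used)
})
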