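test_that("residuals are zero when predictions match experiment exactly", {
  m <- test_model()
  pred <- cached_ratios(m, multipliers_for(m, c(5, 7), 0.6))
  pats <- make_patients("LDLR", "heterozygous",
                        hdl_ratio = pred[["hdl"]], ldl_ratio = pred[["ldl"]],
                        tc_ratio = pred[["tc"]])
  res <- residual_vector(m, 0.6, pats)
  expect_equal(res$component, c("dHDL", "dLDL"))
  expect_equal(res$value, c(0, 0), tolerance = 1e-9)
})

test_that("TC-only patients contribute exactly one residual component", {
  m <- test_model()
  pats <- make_patients("DHCR7", "heterozygous", tc_ratio = 0.2)
  res <- residual_vector(m, 0, pats)
  expect_equal(nrow(res), 1L)
  expect_equal(res$component, "dTC")
})

test_that("residuals are the plain difference of case/control ratios", {
  m <- test_model()
  # fixture with known ratios; prediction supplied explicitly so the check
  # is pure arithmetic on the training equations
  pats <- make_patients("LDLR", "heterozygous",
                        hdl_ratio = 0.80, ldl_ratio = 2.00, tc_ratio = 1.6)
  res <- residual_vector(m, 0.6, pats,
                         predicted = c(hdl = 0.74, ldl = 1.85, tc = 1.55))
  expect_equal(res$value, c(0.80 - 0.74, 2.00 - 1.85), tolerance = 1e-12)
})

test_that("noiseless synthetic cohorts are recovered exactly", {
  m <- test_model()
  spec <- cohort_spec(data.frame(
    gene = c("LDLR", "ABCA1", "CETP"),
    zygosity_class = "heterozygous",
    true_fmut = c(0.6, 0.5, 0.43),
    n = c(3, 2, 1)), cv = 0)
  coh <- generate_cohort(m, spec, seed = 5)
  fit <- as.data.frame(fit_fmut(m, coh))
  expect_equal(fit$fmut[match(c("LDLR", "ABCA1", "CETP"), fit$gene)],
               c(0.6, 0.5, 0.43), tolerance = 0.02)
  expect_true(all(fit$converged))
  # objective never worse than at the initial guess
  expect_true(all(fit$sse <= fit$sse_start + 1e-12))
})

test_that("fitted values respect the [0, 1] bounds for pathological data", {
  m <- test_model()
  # experimental ratios far beyond what any f_mut in [0, 1] can produce
  pats <- make_patients("LDLR", "heterozygous",
                        hdl_ratio = c(0.01, 0.02),
                        ldl_ratio = c(60, 70), tc_ratio = c(40, 45))
  fit <- as.data.frame(suppressWarnings(fit_fmut(m, pats)))
  expect_gte(fit$fmut, 0)
  expect_lte(fit$fmut, 1)
})

test_that("monotone-decreasing SSE clamps the estimate at 1", {
  m <- test_model()
  # homozygous LCAT deficiency: measured HDL far below control, but the
  # model responds to LCAT loss with an HDL increase, so no reduction of
  # f_mut can shrink the residuals and the estimate must stick at 1
  pats <- make_patients("LCAT", "homozygous",
                        hdl_ratio = rep(0.19, 7), ldl_ratio = rep(0.82, 7),
                        tc_ratio = rep(0.77, 7))
  fit <- as.data.frame(fit_fmut(m, pats))
  expect_equal(fit$fmut, 1, tolerance = 1e-6)
})

test_that("groups are fitted independently", {
  m <- test_model()
  spec <- cohort_spec(data.frame(
    gene = c("LDLR", "CETP"), zygosity_class = "heterozygous",
    true_fmut = c(0.6, 0.43), n = c(2, 1)), cv = 0)
  coh <- generate_cohort(m, spec, seed = 5)
  fit_joint <- as.data.frame(fit_fmut(m, coh))
  fit_solo <- as.data.frame(fit_fmut(m, coh[coh$gene == "CETP", ]))
  expect_equal(fit_joint$fmut[fit_joint$gene == "CETP"], fit_solo$fmut,
               tolerance = 1e-10)
})

test_that("patient tables round-trip and reject broken records", {
  m <- test_model()
  spec <- cohort_spec(data.frame(gene = "LDLR",
                                 zygosity_class = "heterozygous",
                                 true_fmut = 0.6, n = 3), cv = 0.1)
  coh <- generate_cohort(m, spec, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_patient_table(coh, path)
  back <- read_patient_table(path)
  expect_equal(back$hdl, coh$hdl, tolerance = 1e-9)

  bad <- coh
  bad$hdl <- NA
  bad$ldl <- NA
  bad$tc <- NA
  expect_error(validate_patients(bad), "without usable lipid data")
  bad2 <- coh
  bad2$hdl_control[1] <- -1
  expect_error(validate_patients(bad2), "non-positive")
})
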