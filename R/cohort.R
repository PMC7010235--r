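#' Specification of a synthetic training cohort
#'
#' Describes, per (gene, zygosity-class) entry, the true f_mut driving the
#' simulated patients, how many patients to emit (and how many of those are
#' compound heterozygous), and the noise level. [default_cohort_spec()]
#' mirrors the composition of the real training cohort: 67 patients over 9
#' entries, ABCA1 including one compound-heterozygous carrier, with the
#' trained f_mut values as ground truth.
#'
#' @param entries data.frame with columns `gene`, `zygosity_class`
#'   (`"heterozygous"`/`"homozygous"`), `true_fmut` in \[0, 1\], `n`
#'   (patients, >= 1) and optionally `n_compound` (of `n`, how many are
#'   compound heterozygous; only meaningful for heterozygous-class entries)
#'   and `tc_only` (logical: emit only total cholesterol, the
#'   DHCR7-style data-availability constraint).
#' @param cv coefficient of variation of the multiplicative lognormal noise
#'   applied to each patient's ratios (>= 0; 0 = noiseless).
#' @param control named control profile (absolute levels, mmol/l) used to
#'   synthesise absolute case levels; only ratios matter downstream.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(entries, cv = 0.1,
                        control = c(hdl = 1.3, ldl = 3.0, tc = 4.3)) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "zygosity_class", "true_fmut", "n")
                %in% names(entries)))
  if (is.null(entries$n_compound)) entries$n_compound <- 0L
  if (is.null(entries$tc_only)) entries$tc_only <- FALSE
  if (any(entries$n < 1)) stop("patient counts must be >= 1")
  if (any(entries$n_compound > entries$n))
    stop("n_compound cannot exceed n")
  if (any(entries$true_fmut < 0 | entries$true_fmut > 1))
    stop("true_fmut must lie in [0, 1]")
  if (cv < 0) stop("cv must be >= 0")
  structure(list(entries = entries, cv = cv, control = control),
            class = "cohort_spec")
}

#' Default synthetic-cohort specification
#'
#' Entry list and patient counts follow the real training cohort's
#' composition (LDLR 13, APOB 7, APOB hom 1, APOE 12, ABCA1 7 of which one
#' compound heterozygous, CETP 1, LCAT 17, LCAT hom 7, CYP7A1 2; 67 records
#' in total); the trained f_mut values serve as ground truth.
#'
#' @inheritParams cohort_spec
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(cv = 0.1) {
  comp <- load_bundled("training_composition")
  fm <- load_bundled("fmut_trained")
  true_fmut <- mapply(function(g, z) lookup_fmut(fm, g, z),
                      comp$gene, comp$zygosity_class)
  cohort_spec(data.frame(gene = comp$gene,
                         zygosity_class = comp$zygosity_class,
                         true_fmut = unname(true_fmut),
                         n = comp$patients,
                         n_compound = comp$n_compound,
                         tc_only = FALSE,
                         stringsAsFactors = FALSE),
              cv = cv)
}

#' Generate a synthetic patient cohort from the forward model
#'
#' For each entry, simulates the model at the entry's true f_mut to obtain
#' predicted case/control HDL/LDL/TC ratios, then emits `n` patient records
#' whose experimental ratios are the model ratios perturbed by independent
#' multiplicative lognormal noise with mean 1 and coefficient of variation
#' `cv` (lipid levels are positive and right-skewed, and mean-one noise
#' keeps cohort-average ratios centred on the model's; `cv = 0` reproduces
#' the model ratios exactly). Ratios are converted to absolute levels against
#' the spec's fixed control profile. Entries flagged `tc_only` emit records
#' with missing HDL/LDL, carrying total cholesterol only.
#'
#' @param model a [kinetic_model()].
#' @param spec a [cohort_spec()].
#' @param seed RNG seed; the same seed yields an identical cohort.
#' @return A patient data.frame (see [read_patient_table()] for the schema).
#' @export
generate_cohort <- function(model, spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  sdlog <- sqrt(log(1 + spec$cv^2))
  ctrl <- spec$control
  out <- list()
  pid <- 0L
  for (i in seq_len(nrow(spec$entries))) {
    e <- spec$entries[i, ]
    ratios <- predict_ratios(model, mutation_spec(e$gene, e$zygosity_class,
                                                  fmut = e$true_fmut))
    for (j in seq_len(e$n)) {
      pid <- pid + 1L
      zyg <- if (j <= e$n_compound) "compound_heterozygous"
             else e$zygosity_class
      noise <- if (spec$cv > 0)
        stats::rlnorm(3, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, 3)
      obs <- ratios * noise
      rec <- data.frame(
        patient_id = sprintf("SYN%03d", pid), gene = e$gene, zygosity = zyg,
        hdl = obs[["hdl"]] * ctrl[["hdl"]],
        ldl = obs[["ldl"]] * ctrl[["ldl"]],
        tc = obs[["tc"]] * ctrl[["tc"]],
        hdl_control = ctrl[["hdl"]], ldl_control = ctrl[["ldl"]],
        tc_control = ctrl[["tc"]],
        source_ref = "synthetic", stringsAsFactors = FALSE)
      if (isTRUE(e$tc_only))
        rec[c("hdl", "ldl", "hdl_control", "ldl_control")] <- NA_real_
      out[[pid]] <- rec
    }
  }
  do.call(rbind, out)
}
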