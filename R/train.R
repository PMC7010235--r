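#' Read and write patient tables
#'
#' Tab- or comma-separated text with header columns `patient_id`, `gene`,
#' `zygosity`, `hdl`, `ldl`, `tc`, `hdl_control`, `ldl_control`,
#' `tc_control`, `source_ref`; an empty cell (or `NA`) is a missing value.
#' Levels are used only as case/control ratios, so units must merely be
#' consistent within a row. Each record needs at least HDL and LDL with
#' their controls, or TC with its control (the TC-only case covers genes for
#' which only total cholesterol is reported, e.g. DHCR7).
#'
#' @param path file path.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @return A data.frame of validated patient records.
#' @export
read_patient_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  validate_patients(df)
}

#' @rdname read_patient_table
#' @param patients a patient data.frame.
#' @export
write_patient_table <- function(patients, path, sep = "\t") {
  utils::write.table(patients, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Validate patient records
#'
#' @param patients a patient data.frame (see [read_patient_table()]).
#' @return The data.frame, invisibly augmented (columns coerced to numeric).
#' @export
validate_patients <- function(patients) {
  need <- c("patient_id", "gene", "zygosity", "hdl", "ldl", "tc",
            "hdl_control", "ldl_control", "tc_control")
  miss <- setdiff(need, names(patients))
  if (length(miss))
    stop("patient table is missing column(s): ", paste(miss, collapse = ", "))
  for (col in need[-(1:3)]) patients[[col]] <- as.numeric(patients[[col]])
  bad_z <- setdiff(unique(patients$zygosity),
                   c("heterozygous", "homozygous", "compound_heterozygous"))
  if (length(bad_z))
    stop("unknown zygosity: ", paste(bad_z, collapse = ", "))
  has_hl <- with(patients, !is.na(hdl) & !is.na(ldl) &
                   !is.na(hdl_control) & !is.na(ldl_control))
  has_tc <- with(patients, !is.na(tc) & !is.na(tc_control))
  if (any(!has_hl & !has_tc))
    stop("patient(s) without usable lipid data (need HDL&LDL or TC, with ",
         "controls): ",
         paste(patients$patient_id[!has_hl & !has_tc], collapse = ", "))
  num <- as.matrix(patients[need[-(1:3)]])
  if (any(num <= 0, na.rm = TRUE))
    stop("non-positive lipid level or control for patient(s): ",
         paste(unique(patients$patient_id[rowSums(num <= 0, na.rm = TRUE)
                                          > 0]), collapse = ", "))
  patients
}

#' Training residuals for one candidate f_mut
#'
#' For each patient of a single (gene, zygosity-class) group, computes the
#' residual components used by the trainer: the difference between the
#' experimental case/control ratio and the model-predicted case/control
#' ratio, per lipid. Patients with HDL and LDL contribute a ΔHDL and a ΔLDL
#' component; patients with only total cholesterol contribute a single ΔTC
#' component.
#'
#' @param model a [kinetic_model()].
#' @param fmut candidate rate-reduction multiplier in \[0, 1\].
#' @param patients patient records sharing one (gene, zygosity-class).
#' @param predicted optional precomputed predicted ratio triple (internal
#'   use; avoids re-simulating).
#' @return A data.frame with columns `patient_id`, `component` (one of
#'   `"dHDL"`, `"dLDL"`, `"dTC"`) and `value`.
#' @export
residual_vector <- function(model, fmut, patients, predicted = NULL) {
  patients <- validate_patients(patients)
  gene <- unique(patients$gene)
  zyg <- unique(ifelse(patients$zygosity == "compound_heterozygous",
                       "heterozygous", patients$zygosity))
  if (length(gene) != 1L || length(zyg) != 1L)
    stop("residual_vector expects patients of a single (gene, zygosity-",
         "class) group; got ", paste(gene, collapse = "/"), " x ",
         paste(zyg, collapse = "/"))
  if (is.null(predicted))
    predicted <- predict_ratios(model,
                                mutation_spec(gene, zyg, fmut = fmut))
  out <- list()
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    if (!is.na(p$hdl) && !is.na(p$ldl) &&
        !is.na(p$hdl_control) && !is.na(p$ldl_control)) {
      out[[length(out) + 1L]] <- data.frame(
        patient_id = p$patient_id, component = c("dHDL", "dLDL"),
        value = c(p$hdl / p$hdl_control - predicted[["hdl"]],
                  p$ldl / p$ldl_control - predicted[["ldl"]]),
        stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        patient_id = p$patient_id, component = "dTC",
        value = p$tc / p$tc_control - predicted[["tc"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Fit f_mut rate-reduction parameters from patient lipid profiles
#'
#' For each (gene, zygosity-class) group present in `patients`, estimates the
#' single f_mut value minimising the sum of squared residual components (see
#' [residual_vector()]) over that group's patients, by Levenberg-Marquardt
#' least squares (`minpack.lm::nls.lm`) constrained to \[0, 1\]. Groups are
#' fitted independently: mutations are single-gene and the genes considered
#' map to disjoint rate sets. When shrinking the residuals requires pushing
#' f_mut against a bound the estimate clamps there (the homozygous-LCAT
#' situation, where no reduction of the parameter can reduce the error,
#' yields a clamp at 1).
#'
#' @param model a [kinetic_model()].
#' @param patients patient records (any mix of genes/zygosities).
#' @param start initial f_mut guess for every group.
#' @param max_iter maximum LM iterations per group.
#' @param ftol relative SSE-change convergence tolerance.
#' @return An [fmut_table()] (provenance `"trained"`) with extra columns
#'   `sse`, `sse_start`, `iterations`, `n_patients`, `n_components` and
#'   `converged`.
#' @export
fit_fmut <- function(model, patients, start = 0.5, max_iter = 100,
                     ftol = 1e-8) {
  patients <- validate_patients(patients)
  cls <- ifelse(patients$zygosity == "compound_heterozygous",
                "heterozygous", patients$zygosity)
  key <- paste(patients$gene, cls, sep = "|")
  rows <- list()
  for (k in unique(key)) {
    grp <- patients[key == k, , drop = FALSE]
    gene <- grp$gene[1]
    zyg <- cls[key == k][1]
    if (is.null(model$gene_map[[gene]]))
      stop("gene ", gene, " is not in the model's gene map")
    resid_fun <- function(par) {
      f <- min(max(par[1], 0), 1)
      residual_vector(model, f, grp)$value
    }
    r0 <- resid_fun(start)
    fit <- minpack.lm::nls.lm(
      par = c(fmut = start), lower = 0, upper = 1, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = ftol))
    converged <- fit$info %in% 1:4
    if (!converged)
      warning("f_mut fit for ", gene, " (", zyg, ") did not converge: ",
              fit$message)
    rows[[k]] <- data.frame(
      gene = gene, zygosity_class = zyg,
      fmut = min(max(unname(fit$par[1]), 0), 1),
      sse = fit$deviance, sse_start = sum(r0^2),
      iterations = fit$niter, n_patients = nrow(grp),
      n_components = length(r0), converged = converged,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  fmut_table(out, provenance = "trained")
}
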