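#' Construct a whole-body cholesterol kinetic model
#'
#' A `kinetic_model` describes a compartmental model of whole-body cholesterol
#' metabolism: a set of storage pools (grouped into plasma, intestine, liver
#' and periphery), a set of kinetic rates moving cholesterol between pools (or
#' to/from the exterior of the system), a map from gene symbols to the rate
#' ids they regulate, and reference-individual physiology (body weight, organ
#' volumes). The default model has 8 pools and 21 rates; see
#' [default_model()].
#'
#' Rate laws supported:
#' \describe{
#'   \item{`zero_order`}{constant flux `k` (synthesis and dietary intake;
#'     source is `EXTERNAL`).}
#'   \item{`first_order_in_source`}{flux `k * amount(source)`.}
#'   \item{`mass_action`}{flux `k * amount(source) * amount(target)`, used for
#'     carrier-mediated exchange whose throughput scales with the acceptor
#'     pool (CETP-mediated cholesteryl-ester transfer from HDL to LDL).}
#' }
#'
#' @param pools data.frame with columns `name`, `organ_group` (one of
#'   `"plasma"`, `"intestine"`, `"liver"`, `"periphery"`) and
#'   `initial_amount` (baseline cholesterol amount, mmol).
#' @param rates data.frame with columns `id` (integer), `process`, `source`,
#'   `target` (pool names or `"EXTERNAL"`), `law`, `k` (kinetic constant,
#'   positive) and `genes` (comma-separated gene symbols, may be empty).
#' @param gene_map named list mapping gene symbol to an integer vector of
#'   rate ids.
#' @param physiology list with `body_weight_kg` and `organ_volumes_l`
#'   (named list over the four organ groups).
#' @param validate logical; run [validate_kinetic_model()] (default `TRUE`).
#'
#' @return An object of class `kinetic_model`.
#' @seealso [default_model()], [read_model_config()], [simulate_mutation()]
#' @export
kinetic_model <- function(pools, rates, gene_map, physiology, validate = TRUE) {
  pools <- as.data.frame(pools, stringsAsFactors = FALSE)
  rates <- as.data.frame(rates, stringsAsFactors = FALSE)
  rates$id <- as.integer(rates$id)
  rates$k <- as.numeric(rates$k)
  pools$initial_amount <- as.numeric(pools$initial_amount)
  gene_map <- lapply(gene_map, function(v) as.integer(sort(v)))
  model <- structure(
    list(pools = pools, rates = rates, gene_map = gene_map,
         physiology = physiology),
    class = "kinetic_model")
  if (validate) validate_kinetic_model(model)
  model
}

# Tolerance for the baseline steady-state check and for the steady-state flag
# of simulations: max |net flux| per pool, relative to the baseline amount
# scale, per day.
.ss_tol <- 1e-6

#' Validate a kinetic model
#'
#' Enforces the structural invariants of the model class: pool count and
#' grouping, rate id range and uniqueness, positive kinetic constants,
#' external sources/targets restricted to synthesis/intake and loss/excretion
#' rates, a resolvable gene map, and a baseline state that is a steady state
#' (every pool's net flux below tolerance with all multipliers at 1).
#'
#' @param model a [kinetic_model()].
#' @param n_pools,n_rates expected pool and rate count (defaults 8 and 21).
#' @param ss_tol steady-state tolerance: max |net flux| allowed per pool,
#'   as a fraction of the mean baseline pool amount, per day.
#' @return `model`, invisibly. Errors name the offending entity.
#' @export
validate_kinetic_model <- function(model, n_pools = 8L, n_rates = 21L,
                                   ss_tol = .ss_tol) {
  pools <- model$pools
  rates <- model$rates
  if (nrow(pools) != n_pools)
    stop("expected ", n_pools, " pools, found ", nrow(pools))
  if (anyDuplicated(pools$name))
    stop("duplicate pool name: ",
         paste(unique(pools$name[duplicated(pools$name)]), collapse = ", "))
  bad_grp <- setdiff(unique(pools$organ_group),
                     c("plasma", "intestine", "liver", "periphery"))
  if (length(bad_grp))
    stop("unknown organ_group: ", paste(bad_grp, collapse = ", "))
  if (any(pools$initial_amount < 0))
    stop("negative initial_amount for pool: ",
         paste(pools$name[pools$initial_amount < 0], collapse = ", "))

  if (anyDuplicated(rates$id))
    stop("duplicate rate id: ",
         paste(unique(rates$id[duplicated(rates$id)]), collapse = ", "))
  out_of_range <- setdiff(rates$id, seq_len(n_rates))
  if (length(out_of_range))
    stop("rate id out of range 1..", n_rates, ": ",
         paste(out_of_range, collapse = ", "))
  if (nrow(rates) != n_rates)
    stop("expected ", n_rates, " rates, found ", nrow(rates))
  if (any(rates$k <= 0))
    stop("non-positive kinetic constant for rate: ",
         paste(rates$id[rates$k <= 0], collapse = ", "))
  bad_law <- setdiff(rates$law,
                     c("zero_order", "first_order_in_source", "mass_action"))
  if (length(bad_law))
    stop("unknown rate law: ", paste(bad_law, collapse = ", "))
  known <- c(pools$name, "EXTERNAL")
  for (col in c("source", "target")) {
    bad <- setdiff(rates[[col]], known)
    if (length(bad))
      stop("rate ", col, " references unknown pool: ",
           paste(bad, collapse = ", "))
  }
  ext_src <- rates$id[rates$source == "EXTERNAL"]
  if (!setequal(ext_src, 1:4))
    stop("EXTERNAL source allowed only for synthesis/intake rates 1-4, found: ",
         paste(sort(ext_src), collapse = ", "))
  ext_tgt <- rates$id[rates$target == "EXTERNAL"]
  if (!setequal(ext_tgt, c(12L, 15L, 18L)))
    stop("EXTERNAL target allowed only for loss/excretion rates 12, 15, 18, ",
         "found: ", paste(sort(ext_tgt), collapse = ", "))
  if (any(rates$law == "zero_order" & rates$source != "EXTERNAL"))
    stop("zero_order law requires EXTERNAL source (rate ",
         paste(rates$id[rates$law == "zero_order" &
                          rates$source != "EXTERNAL"], collapse = ", "), ")")

  for (g in names(model$gene_map)) {
    missing_ids <- setdiff(model$gene_map[[g]], rates$id)
    if (length(missing_ids))
      stop("gene_map entry ", g, " references unknown rate id: ",
           paste(missing_ids, collapse = ", "))
  }

  phys <- model$physiology
  if (is.null(phys$body_weight_kg) || phys$body_weight_kg <= 0)
    stop("physiology: body_weight_kg must be positive")
  vols <- phys$organ_volumes_l
  if (!all(c("plasma", "intestine", "liver", "periphery") %in% names(vols)))
    stop("physiology: organ_volumes_l must cover all four organ groups")

  # baseline steady state
  x0 <- baseline_state(model)
  d0 <- cholesterol_derivatives(model, x0, rep(1, nrow(rates)))
  scale <- mean(x0)
  worst <- max(abs(d0)) / scale
  if (worst > ss_tol)
    stop("baseline is not at steady state: max |net flux| = ",
         signif(max(abs(d0)), 4), " (", signif(worst, 4),
         " x baseline scale/day) in pool ",
         names(d0)[which.max(abs(d0))])
  invisible(model)
}

#' Baseline state of a model
#'
#' @param model a [kinetic_model()].
#' @return Named numeric vector of baseline pool amounts (mmol).
#' @export
baseline_state <- function(model) {
  stats::setNames(model$pools$initial_amount, model$pools$name)
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Whole-body cholesterol kinetic model\n")
  cat("  pools:", nrow(x$pools), "(",
      paste(sprintf("%s: %d", names(table(x$pools$organ_group)),
                    as.integer(table(x$pools$organ_group))), collapse = ", "),
      ")\n")
  cat("  rates:", nrow(x$rates), "  genes mapped:",
      length(x$gene_map), "\n")
  cat("  reference individual:", x$physiology$body_weight_kg, "kg\n")
  lv <- lipid_levels(x, baseline_state(x))
  cat(sprintf("  baseline plasma levels (mmol): HDL %.2f, LDL %.2f, TC %.2f\n",
              lv["hdl"], lv["ldl"], lv["tc"]))
  invisible(x)
}

#' Genes resolvable by a model
#'
#' @param model a [kinetic_model()].
#' @return Character vector of gene symbols in the model's gene-to-rate map.
#' @export
model_genes <- function(model) names(model$gene_map)

#' Read a kinetic model from a structured text (YAML) config
#'
#' The config has four sections: `pools` (name, organ_group, initial_amount),
#' `rates` (id, process, source, target, law, k, genes), `gene_map` and
#' `physiology` (body_weight_kg, organ_volumes_l). [write_model_config()]
#' writes the same layout, and a load/save/load round trip yields an
#' identical model.
#'
#' @param path path to a YAML model config.
#' @param validate run [validate_kinetic_model()] after parsing.
#' @return A [kinetic_model()].
#' @export
read_model_config <- function(path, validate = TRUE) {
  cfg <- yaml::read_yaml(path)
  for (sec in c("pools", "rates", "gene_map", "physiology"))
    if (is.null(cfg[[sec]])) stop("model config is missing section: ", sec)
  pools <- do.call(rbind, lapply(cfg$pools, function(p)
    data.frame(name = p$name, organ_group = p$organ_group,
               initial_amount = as.numeric(p$initial_amount),
               stringsAsFactors = FALSE)))
  rates <- do.call(rbind, lapply(cfg$rates, function(r)
    data.frame(id = as.integer(r$id), process = r$process,
               source = r$source, target = r$target, law = r$law,
               k = as.numeric(r$k),
               genes = if (is.null(r$genes)) "" else r$genes,
               stringsAsFactors = FALSE)))
  rates <- rates[order(rates$id), , drop = FALSE]
  rownames(rates) <- NULL
  kinetic_model(pools, rates, cfg$gene_map, cfg$physiology,
                validate = validate)
}

#' Write a kinetic model to a YAML config
#'
#' @param model a [kinetic_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    pools = lapply(seq_len(nrow(model$pools)), function(i)
      list(name = model$pools$name[i],
           organ_group = model$pools$organ_group[i],
           initial_amount = model$pools$initial_amount[i])),
    rates = lapply(seq_len(nrow(model$rates)), function(i)
      list(id = model$rates$id[i], process = model$rates$process[i],
           source = model$rates$source[i], target = model$rates$target[i],
           law = model$rates$law[i], k = model$rates$k[i],
           genes = model$rates$genes[i])),
    gene_map = model$gene_map,
    physiology = model$physiology)
  # 17 significant digits round-trips doubles exactly
  writeLines(yaml::as.yaml(cfg, precision = 17), path)
  invisible(path)
}

#' The bundled default model
#'
#' Loads the package's default parameterization: 8 pools (liver free/ester,
#' intestine free/ester, periphery, plasma HDL free/ester, plasma LDL+VLDL)
#' connected by 21 gene-annotated rates for a 70 kg reference individual.
#' The kinetic constants are self-calibrated: baseline pool amounts and
#' inter-pool fluxes were fixed at physiologically reasonable values and the
#' constants solved so that the baseline is an exact steady state. They are
#' a synthetic parameterization built for this package, not a transcription
#' of any published constant set, so absolute predictions are
#' model-specific; case/control ratios are the intended output.
#'
#' @return A validated [kinetic_model()].
#' @export
default_model <- function() {
  read_model_config(system.file("extdata", "model_default.yaml",
                                package = "cholsim", mustWork = TRUE))
}
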