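# Shared fixtures, built in code.

# The bundled default model, loaded once per test run.
.default_model_cache <- new.env(parent = emptyenv())
test_model <- function() {
  if (is.null(.default_model_cache$m))
    .default_model_cache$m <- default_model()
  .default_model_cache$m
}

# Memoized predicted ratios for the default model, keyed by multiplier
# vector, to avoid re-simulating identical scenarios across tests.
.ratio_cache <- new.env(parent = emptyenv())
cached_ratios <- function(model, multipliers, ...) {
  key <- paste(signif(multipliers, 12), collapse = ",")
  if (is.null(.ratio_cache[[key]]))
    .ratio_cache[[key]] <- predict_ratios(model, multipliers = multipliers,
                                          ...)
  .ratio_cache[[key]]
}

multipliers_for <- function(model, ids, f) {
  m <- rep(1, nrow(model$rates))
  m[match(ids, sort(model$rates$id))] <- f
  m
}

# A minimal 8-pool/21-rate model whose constants are solved from a balanced
# flux vector, used to perturb constants without touching the bundled asset.
rebalanced_model <- function(k_scale = rep(1, 21), validate = TRUE) {
  m <- test_model()
  r <- m$rates
  r$k <- r$k * k_scale
  kinetic_model(m$pools, r, m$gene_map, m$physiology, validate = validate)
}

# Tiny toy models for closed-form oracles. Pools reuse the standard pool
# names/groups so validation logic stays out of the way (validate = FALSE;
# these are not 8/21 models).
toy_linear_model <- function(k12 = 0.3, k23 = 0.2, k31 = 0.5) {
  pools <- data.frame(
    name = c("A", "B", "C"),
    organ_group = c("liver", "plasma", "periphery"),
    initial_amount = c(5, 1, 2), stringsAsFactors = FALSE)
  rates <- data.frame(
    id = 1:3, process = c("A to B", "B to C", "C to A"),
    source = c("A", "B", "C"), target = c("B", "C", "A"),
    law = "first_order_in_source", k = c(k12, k23, k31),
    genes = "", stringsAsFactors = FALSE)
  kinetic_model(pools, rates, list(),
                list(body_weight_kg = 70,
                     organ_volumes_l = list(plasma = 1, intestine = 1,
                                            liver = 1, periphery = 1)),
                validate = FALSE)
}

# Patient-record builder for trainer tests.
make_patients <- function(gene, zygosity, hdl_ratio = NA, ldl_ratio = NA,
                          tc_ratio = NA,
                          control = c(hdl = 1.3, ldl = 3.0, tc = 4.3)) {
  n <- max(length(hdl_ratio), length(tc_ratio))
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    gene = gene, zygosity = zygosity,
    hdl = hdl_ratio * control[["hdl"]],
    ldl = ldl_ratio * control[["ldl"]],
    tc = tc_ratio * control[["tc"]],
    hdl_control = ifelse(is.na(hdl_ratio), NA, control[["hdl"]]),
    ldl_control = ifelse(is.na(ldl_ratio), NA, control[["ldl"]]),
    tc_control = ifelse(is.na(tc_ratio), NA, control[["tc"]]),
    source_ref = "fixture", stringsAsFactors = FALSE)
}
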