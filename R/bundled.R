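# md5 checksums of the bundled plain-text assets, guarding against
# transcription drift. Regenerate with tools::md5sum() after any deliberate
# edit of the corresponding file under inst/extdata/.
.bundled_assets <- list(
  fmut_reference = list(file = "fmut_published.tsv",
                        md5 = "b1d5658e1e539e1bb8047dd1ad70ac71"),
  fmut_trained = list(file = "fmut_published.tsv",
                      md5 = "b1d5658e1e539e1bb8047dd1ad70ac71"),
  test_set = list(file = "test_set.tsv",
                  md5 = "4445420a2021b8be06e660f30d506d2f"),
  training_composition = list(file = "training_composition.tsv",
                              md5 = "5a4b1279e8b34ef002bfecb0105f48c8"))

#' Load a bundled data asset
#'
#' Bundled transcriptions of the published result tables, shipped as
#' tab-separated text under `inst/extdata/` and checksum-guarded:
#' \describe{
#'   \item{`fmut_trained`}{the optimised f_mut per (gene, zygosity class),
#'     as an [fmut_table()] with provenance `"trained"`.}
#'   \item{`fmut_reference`}{the earlier experimentally derived f_mut values
#'     the trained set is compared against (provenance `"reference"`).}
#'   \item{`test_set`}{the 10-mutation test set: experimental case/control
#'     HDL/LDL/TC ratios plus both sources' predicted ratios (and the
#'     reported standard deviations of the trained predictions), as a
#'     [prediction_set()]. Two entries (APOE, DHCR7) lack experimental HDL
#'     and LDL.}
#'   \item{`training_composition`}{the training-cohort composition: per
#'     (gene, zygosity class), number of patients (67 in total), distinct
#'     mutations, compound-heterozygous carriers and mapped rate ids.}
#' }
#'
#' @param name asset name (see above).
#' @return The validated table, with class depending on the asset.
#' @export
load_bundled <- function(name) {
  if (!name %in% names(.bundled_assets))
    stop("unknown bundled asset: ", name, " (available: ",
         paste(names(.bundled_assets), collapse = ", "), ")")
  spec <- .bundled_assets[[name]]
  path <- system.file("extdata", spec$file, package = "cholsim",
                      mustWork = TRUE)
  if (!is.null(spec$md5)) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, spec$md5))
      stop("checksum mismatch for bundled asset ", name, " (", spec$file,
           "): expected ", spec$md5, ", got ", got)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  switch(name,
    fmut_trained = fmut_table(
      data.frame(gene = df$gene, zygosity_class = df$zygosity_class,
                 fmut = df$fmut_trained, stringsAsFactors = FALSE),
      provenance = "trained"),
    fmut_reference = fmut_table(
      data.frame(gene = df$gene, zygosity_class = df$zygosity_class,
                 fmut = df$fmut_reference, stringsAsFactors = FALSE),
      provenance = "reference"),
    test_set = {
      stopifnot(nrow(df) == 10L,
                sum(is.na(df$exp_hdl) & is.na(df$exp_ldl)) == 2L)
      prediction_set(df)
    },
    training_composition = {
      stopifnot(sum(df$patients) == 67L)
      df
    })
}
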