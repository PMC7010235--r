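#' Table of mutation rate-reduction multipliers
#'
#' An `fmut_table` stores one rate-reduction multiplier `f_mut` in \[0, 1\]
#' per (gene, zygosity class). `f_mut = 1` means wild-type activity of every
#' rate the gene regulates; `f_mut = 0` means complete loss. Some genes carry
#' separate entries for the homozygous form (e.g. APOB, LCAT); a class of
#' `"any"` applies regardless of zygosity.
#'
#' @param entries data.frame with columns `gene`, `zygosity_class` (one of
#'   `"heterozygous"`, `"homozygous"`, `"any"`) and `fmut` in \[0, 1\].
#' @param provenance `"trained"` (fit from patient profiles) or
#'   `"reference"` (externally determined).
#' @return An object of class `fmut_table` (a data.frame).
#' @export
fmut_table <- function(entries, provenance = c("trained", "reference")) {
  provenance <- match.arg(provenance)
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "zygosity_class", "fmut") %in% names(entries)))
  bad <- !is.finite(entries$fmut) | entries$fmut < 0 | entries$fmut > 1
  if (any(bad))
    stop("fmut outside [0, 1] for: ",
         paste(entries$gene[bad], collapse = ", "))
  bad_cls <- setdiff(entries$zygosity_class,
                     c("heterozygous", "homozygous", "any"))
  if (length(bad_cls))
    stop("unknown zygosity_class: ", paste(bad_cls, collapse = ", "))
  if (anyDuplicated(entries[c("gene", "zygosity_class")]))
    stop("duplicate (gene, zygosity_class) entry")
  structure(entries, provenance = provenance,
            class = c("fmut_table", "data.frame"))
}

#' Look up the f_mut value for a mutation
#'
#' Resolution order: an exact (gene, zygosity) entry; compound-heterozygous
#' mutations use the gene's heterozygous entry; finally a `"any"` entry for
#' the gene. An explicit `fmut_override` in the mutation bypasses the table.
#'
#' @param table an [fmut_table()].
#' @param gene gene symbol.
#' @param zygosity `"heterozygous"`, `"homozygous"` or
#'   `"compound_heterozygous"`.
#' @return The scalar f_mut value.
#' @export
lookup_fmut <- function(table, gene, zygosity) {
  cls <- if (identical(zygosity, "compound_heterozygous"))
    "heterozygous" else zygosity
  hit <- table$gene == gene & table$zygosity_class == cls
  if (!any(hit)) hit <- table$gene == gene & table$zygosity_class == "any"
  if (!any(hit))
    stop("no f_mut entry for gene ", gene, " (", zygosity, ")")
  table$fmut[which(hit)[1]]
}

#' Specify a mutation to simulate
#'
#' @param gene gene symbol (must be resolvable through the model's gene map,
#'   unless `fmut` is given together with explicit `rates`).
#' @param zygosity zygosity of the mutation.
#' @param fmut optional explicit rate-reduction multiplier in \[0, 1\],
#'   bypassing any [fmut_table()].
#' @return An object of class `mutation_spec`.
#' @export
mutation_spec <- function(gene,
                          zygosity = c("heterozygous", "homozygous",
                                       "compound_heterozygous"),
                          fmut = NULL) {
  zygosity <- match.arg(zygosity)
  if (!is.null(fmut)) {
    stopifnot(is.numeric(fmut), length(fmut) == 1L)
    if (!is.finite(fmut) || fmut < 0 || fmut > 1)
      stop("fmut override must lie in [0, 1]")
  }
  structure(list(gene = gene, zygosity = zygosity, fmut = fmut),
            class = "mutation_spec")
}

#' Per-rate multipliers implied by a mutation
#'
#' Every rate id mapped to the mutated gene receives the gene's f_mut (from
#' the table, resolved by zygosity class, or the mutation's explicit
#' override); all other rates keep multiplier 1.
#'
#' @param model a [kinetic_model()].
#' @param mutation a [mutation_spec()].
#' @param table an [fmut_table()]; may be omitted when the mutation carries
#'   an explicit override.
#' @return Numeric vector of multipliers, one per rate id.
#' @export
fmut_multipliers <- function(model, mutation, table = NULL) {
  stopifnot(inherits(mutation, "mutation_spec"))
  ids <- model$gene_map[[mutation$gene]]
  if (is.null(ids))
    stop("gene ", mutation$gene, " is not in the model's gene map")
  f <- mutation$fmut
  if (is.null(f)) {
    if (is.null(table))
      stop("no fmut_table given and mutation carries no fmut override")
    f <- lookup_fmut(table, mutation$gene, mutation$zygosity)
  }
  m <- rep(1, nrow(model$rates))
  m[match(ids, sort(model$rates$id))] <- f
  m
}

#' Read/write f_mut tables as tabular text
#'
#' Tab-separated with header `gene`, `zygosity_class`, `fmut`.
#'
#' @param table an [fmut_table()].
#' @param path file path.
#' @param provenance provenance label used when reading.
#' @return `read_fmut_table`: an [fmut_table()]; `write_fmut_table`: `path`,
#'   invisibly.
#' @export
write_fmut_table <- function(table, path) {
  utils::write.table(as.data.frame(table)[c("gene", "zygosity_class", "fmut")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fmut_table
#' @export
read_fmut_table <- function(path, provenance = "trained") {
  fmut_table(utils::read.delim(path, stringsAsFactors = FALSE),
             provenance = provenance)
}
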