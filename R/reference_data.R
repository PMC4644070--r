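# Reference tables from a published pan-archaeal C/D box sRNA survey of
# seven species, shipped as plain text under inst/extdata.  They serve as
# inputs for summary arithmetic and as documented context; no pipeline stage
# depends on them.

#' Species registry of the seven-species pan-archaeal survey
#'
#' One row per organism: abbreviation, name, phylum/order, growth temperature,
#' genomic G+C percent and the number of C/D box sRNA genes identified in
#' that species.
#'
#' @return A data.frame with columns `abbreviation`, `name`, `phylum_order`,
#'   `growth_temp`, `gc_percent`, `srna_gene_count`.
#' @export
species_registry <- function() {
  path <- system.file("extdata", "species_registry.tsv", package = "cdguide",
                      mustWork = TRUE)
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(reg$abbreviation)) {
    stop("species registry has duplicate abbreviations", call. = FALSE)
  }
  reg
}

#' Published survey counts (guide interactions and conservation totals)
#'
#' Named numeric vector of the survey's reported counts: total sRNAs,
#' significant guide interactions, interactions with a mismatch at the
#' predicted site (non-productive), double-guide and no-target sRNA counts,
#' and the per-molecule methylation event / single-species / multi-species
#' site counts.  Derived quantities (productive interactions, distinct
#' positions, the multi-species fraction) are computed from these by the
#' package's accounting identities, not stored.
#'
#' @return A named numeric vector.
#' @export
survey_counts <- function() {
  path <- system.file("extdata", "survey_counts.tsv", package = "cdguide",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$value), tab$key)
}
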