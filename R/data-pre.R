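#' Bundled PRE reference tables
#'
#' Accessors for the small plain-text reference tables shipped with the
#' package: the literal TF binding-site catalog for the PRE (with reported
#' molecular weights), the wildtype and mutant EMSA oligomer cores, the
#' genomic wildtype and SNP variant sequences, the published per-variant
#' adjusted means and effect sizes of the mutant EMSA/ELISA experiments,
#' and the 35-species taxonomy with clade base weights.
#'
#' The mutant EMSA oligomers share a 5' cloning overhang (`TCGA...`) that
#' differs from the genomic context (`TCGG...`) of the SNP table; both
#' sequences are accepted by the scanner, labelled oligomer vs genomic.
#' Sites whose catalog entry carries lowercase 3' context letters are
#' matched against the oligomer core plus the downstream plasmid context
#' [pre_plasmid_context()].
#'
#' @param cell_line for [pre_effect_table()]: `"NB"` (human neuroblastoma)
#'   or `"PC12"` (rat pheochromocytoma).
#' @name pre_data
NULL

pre_extdata <- function(file) {
  path <- system.file("extdata", file, package = "apppre",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pre_data
#' @export
pre_site_catalog <- function() {
  site_catalog(pre_extdata("pre_site_catalog.tsv"))
}

#' @rdname pre_data
#' @export
pre_mutant_oligos <- function() {
  d <- pre_extdata("pre_mutant_oligos.tsv")
  stats::setNames(d$sequence, d$variant)
}

#' @rdname pre_data
#' @export
pre_snp_variants <- function() {
  d <- pre_extdata("pre_snp_variants.tsv")
  stats::setNames(d$sequence, d$variant)
}

#' Downstream plasmid context of the PRE oligomer cores
#'
#' The seven bases 3' of the PRE in the reporter plasmid, needed to match
#' catalog sites whose lowercase context letters extend past the 30-nt
#' core (e.g. `GGATCAGctgactc`).
#' @export
pre_plasmid_context <- function() "CTGACTC"

#' @rdname pre_data
#' @export
pre_effect_table <- function(cell_line = c("NB", "PC12")) {
  cell_line <- match.arg(cell_line)
  d <- pre_extdata("pre_effect_means.tsv")
  d[d$cell_line == cell_line, c("assay", "variant", "mean", "g")]
}

#' @rdname pre_data
#' @export
pre_effect_anova <- function(cell_line = c("NB", "PC12")) {
  cell_line <- match.arg(cell_line)
  d <- pre_extdata("pre_effect_anova.tsv")
  d[d$cell_line == cell_line, c("assay", "F", "psi")]
}

#' @rdname pre_data
#' @export
pre_taxonomy <- function() {
  pre_extdata("species_weights.tsv")
}
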