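#' Read gene sets from a GMT file
#'
#' Thin wrapper around `fgsea::gmtPathways()`.
#'
#' @param path GMT file (tab-separated: set name, description, symbols...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: '%s'", path))
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field written for every set (default "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  lines <- purrr::imap_chr(sets, function(genes, nm) {
    paste(c(nm, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Default human cell-cycle phase gene sets
#'
#' The widely used S-phase (43 symbols) and G2/M-phase (54 symbols) human
#' gene lists shipped in `inst/extdata/cell_cycle_human.gmt`. Intended as a
#' convenience default for real data; synthetic runs supply their own sets.
#'
#' @return list with elements `s` and `g2m`.
#' @export
cycle_gene_sets <- function() {
  path <- system.file("extdata", "cell_cycle_human.gmt", package = "dosagenet")
  sets <- read_gmt(path)
  list(s = sets[["S_PHASE"]], g2m = sets[["G2M_PHASE"]])
}
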