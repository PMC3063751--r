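#' Gain-of-function mutation sites of subtilisin Carlsberg (reconstructed)
#'
#' The 28 residue positions (subtilisin Carlsberg numbering, 274 residues)
#' reported across six directed-evolution and screening studies to enhance
#' the stability of subtilisin or its activity in a non-aqueous solvent,
#' used as the reference set for hit-rate and random-pick baselines.  The
#' twelve positions marked `attested = TRUE` are named explicitly in
#' published summaries of those studies; the remainder are reconstructed
#' from the primary reports mapped into Carlsberg numbering and should be
#' treated as a synthetic stand-in for a curated table.  Note that the
#' random-pick coverage statistics computed from this set depend only on
#' the number of sites and their distance to the chain termini, not on the
#' exact identities.
#'
#' @return Tibble with columns `residue` (1-based), `attested` (logical).
#' @seealso [random_baseline()]
#' @export
subtilisin_mutation_sites <- function() {
  attested <- c(9L, 14L, 59L, 72L, 75L, 96L, 102L, 160L, 165L, 180L, 193L, 217L)
  reconstructed <- c(2L, 3L, 5L, 43L, 50L, 62L, 76L, 117L, 128L, 168L,
                     205L, 206L, 212L, 216L, 248L, 270L)
  tibble(
    residue = sort(c(attested, reconstructed)),
    attested = sort(c(attested, reconstructed)) %in% attested
  )
}

#' Number of residues of mature subtilisin Carlsberg
#'
#' @return 274L
#' @export
subtilisin_n_residues <- function() 274L
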