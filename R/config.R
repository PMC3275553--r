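#' Analysis configuration
#'
#' Bundle of the tunable constants used across the toolkit. Defaults mirror
#' the published Mos1 collection protocol: amplicons must exceed 270 bp
#' (MboI digestion) or 325 bp (HaeIII); MosTIC can reach targets up to
#' 1.5 kb from an insertion; alleles more than 10 bp apart are considered
#' unique; redundant alleles from plate-local cross-contamination carry
#' allele numbers differing by fewer than 25.
#'
#' @param mostic_flank Reach of MosTIC editing from an insertion site, in bp.
#' @param dedupe_max_sep Maximum separation (bp) at which two alleles are
#'   considered the same insertion during redundancy collapse.
#' @param allele_number_proximity Allele-number difference below which a
#'   redundant exact match is attributed to plate-local contamination.
#' @param size_threshold_mboi,size_threshold_haeiii Minimum amplicon size
#'   (bp, strict) for a band to be purified and sequenced, per enzyme.
#' @param min_flank_map_len Minimum flank read length (bp) attempted for
#'   genome mapping; shorter reads are flagged `too_short`.
#' @param snap_radius Maximum distance (bp) over which a mapped junction is
#'   snapped to the nearest TA dinucleotide.
#'
#' @return A list of class `mos_config`.
#' @examples
#' cfg <- mos_config(dedupe_max_sep = 5)
#' cfg$dedupe_max_sep
#' @export
mos_config <- function(mostic_flank = 1500,
                       dedupe_max_sep = 10,
                       allele_number_proximity = 25,
                       size_threshold_mboi = 270,
                       size_threshold_haeiii = 325,
                       min_flank_map_len = 18,
                       snap_radius = 10) {
  cfg <- list(
    mostic_flank = mostic_flank,
    dedupe_max_sep = dedupe_max_sep,
    allele_number_proximity = allele_number_proximity,
    size_threshold_mboi = size_threshold_mboi,
    size_threshold_haeiii = size_threshold_haeiii,
    min_flank_map_len = min_flank_map_len,
    snap_radius = snap_radius
  )
  bad <- names(cfg)[!vapply(cfg, function(x) {
    is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0 && x == as.integer(x)
  }, logical(1))]
  if (length(bad) > 0) {
    stop("mos_config values must be positive integers: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(lapply(cfg, as.integer), class = "mos_config")
}

#' @export
print.mos_config <- function(x, ...) {
  cat("<mos_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %d\n", nm, x[[nm]]))
  invisible(x)
}
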