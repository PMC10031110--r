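#' Desikan-Killiany cortical region labels
#'
#' The 34 per-hemisphere labels of the Desikan-Killiany parcellation, in
#' the conventional FreeSurfer `aparc` order, and the 68 hemisphere-prefixed
#' column names used throughout the package (`lh_<region>_thickness` style
#' headers collapse to `lh_<region>` internally).
#'
#' @param prefixed if `TRUE` (default) return the 68 `lh_`/`rh_`-prefixed
#'   names; otherwise the 34 bare region labels.
#' @return character vector of region names.
#' @export
#' @examples
#' length(dk_regions())        # 68
#' head(dk_regions(FALSE))     # bare labels
dk_regions <- function(prefixed = TRUE) {
  base <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
    "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
    "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
    "postcentral", "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
    "temporalpole", "transversetemporal", "insula")
  if (!prefixed) return(base)
  c(paste0("lh_", base), paste0("rh_", base))
}

#' Posterior (occipital + parietal) region subset
#'
#' Default set of regions carrying the planted negative thickness effect in
#' the synthetic cohort: the occipital lobe (cuneus, lateral occipital,
#' lingual, pericalcarine) extending laterally into the parietal lobe
#' (inferior/superior parietal, precuneus, supramarginal), both hemispheres.
#'
#' @return character vector of prefixed region names (subset of
#'   [dk_regions()]).
#' @export
dk_posterior_regions <- function() {
  post <- c("cuneus", "lateraloccipital", "lingual", "pericalcarine",
            "inferiorparietal", "superiorparietal", "precuneus",
            "supramarginal")
  c(paste0("lh_", post), paste0("rh_", post))
}
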