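#' Region label sets
#'
#' Default node label sets for the three networks the package analyses:
#' 50 thalamic nuclei (25 per hemisphere, FreeSurfer thalamic segmentation
#' nomenclature), 68 cortical regions (34 per hemisphere, Desikan-Killiany
#' atlas) and 12 subcortical structures (6 per hemisphere). Labels are
#' prefixed `L_` / `R_` by hemisphere.
#'
#' @param hemisphere one of `"both"`, `"left"`, `"right"`.
#' @return character vector of region labels.
#' @examples
#' length(thalamic_nuclei_labels())   # 50
#' length(dk_cortical_labels())       # 68
#' length(subcortical_labels())       # 12
#' @name region_labels
NULL

.THALAMIC_NUCLEI <- c(
  "AV", "LD", "LP", "VA", "VAmc", "VLa", "VLp", "VPL", "VM",
  "CeM", "CL", "Pc", "CM", "Pf",
  "Pt", "MDm", "MDl", "Re",
  "LGN", "MGN", "LSg",
  "PuA", "PuM", "PuL", "PuI"
)

.DK_CORTEX <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)

.SUBCORTEX <- c("Caudate", "Putamen", "Pallidum", "Hippocampus",
                "Amygdala", "Accumbens")

.hemi_prefix <- function(base, hemisphere) {
  hemisphere <- match.arg(hemisphere, c("both", "left", "right"))
  left <- paste0("L_", base)
  right <- paste0("R_", base)
  switch(hemisphere, both = c(left, right), left = left, right = right)
}

#' @rdname region_labels
#' @export
thalamic_nuclei_labels <- function(hemisphere = "both") {
  .hemi_prefix(.THALAMIC_NUCLEI, hemisphere)
}

#' @rdname region_labels
#' @export
dk_cortical_labels <- function(hemisphere = "both") {
  .hemi_prefix(.DK_CORTEX, hemisphere)
}

#' @rdname region_labels
#' @export
subcortical_labels <- function(hemisphere = "both") {
  .hemi_prefix(.SUBCORTEX, hemisphere)
}
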