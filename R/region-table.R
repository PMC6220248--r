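#' Construct and validate a region table
#'
#' A region table fixes the node order of every connectome: 0-based node
#' indices, unique region names, and a hemisphere label ("left", "right" or
#' "none"). All files carrying region names are reconciled against this table
#' by name, never by position.
#'
#' @param region_name character vector of unique region names.
#' @param hemisphere character vector, one of "left", "right", "none".
#' @return data.frame with columns node_index (0-based), region_name,
#'   hemisphere.
#' @export
#' @examples
#' rt <- regionTable(c("A", "B", "C"), c("left", "right", "none"))
regionTable <- function(region_name, hemisphere) {
  rt <- data.frame(
    node_index = seq_along(region_name) - 1L,
    region_name = as.character(region_name),
    hemisphere = as.character(hemisphere),
    stringsAsFactors = FALSE
  )
  msg <- checkRegionTable(rt)
  if (!isTRUE(msg)) stop(paste(msg, collapse = "; "))
  rt
}

checkRegionTable <- function(rt) {
  msg <- character()
  need <- c("node_index", "region_name", "hemisphere")
  if (!all(need %in% names(rt)))
    return(paste("region table must contain columns:",
                 paste(need, collapse = ", ")))
  if (!identical(as.integer(rt$node_index), seq_len(nrow(rt)) - 1L))
    msg <- c(msg, "node indices must be 0..N-1 without gaps or duplicates")
  if (anyDuplicated(rt$region_name))
    msg <- c(msg, "region names must be unique")
  if (!all(rt$hemisphere %in% c("left", "right", "none")))
    msg <- c(msg, "hemisphere must be 'left', 'right' or 'none'")
  if (length(msg)) msg else TRUE
}

# Desikan-Killiany cortical parcels (34 per hemisphere) plus 7 subcortical
# structures per hemisphere and the brainstem: the standard 83-region scheme.
DK_CORTICAL <- c(
  "bankssts", "caudal anterior cingulate", "caudal middle frontal", "cuneus",
  "entorhinal", "frontal pole", "fusiform", "inferior parietal",
  "inferior temporal", "insula", "isthmus cingulate", "lateral occipital",
  "lateral orbitofrontal", "lingual", "medial orbitofrontal",
  "middle temporal", "paracentral", "parahippocampal", "pars opercularis",
  "pars orbitalis", "pars triangularis", "peri-calcarine", "postcentral",
  "posterior cingulate", "precentral", "precuneus",
  "rostral anterior cingulate", "rostral middle frontal", "superior frontal",
  "superior parietal", "superior temporal", "supramarginal",
  "temporal pole", "transverse temporal"
)
SUBCORTICAL <- c(
  "thalamus", "caudate", "putamen", "pallidum", "accumbens",
  "hippocampus", "amygdala"
)

#' Default 83-region parcellation table
#'
#' The Desikan-Killiany cortical atlas with subcortical segmentation:
#' 41 regions per hemisphere (34 cortical + 7 subcortical) plus the
#' brainstem, 83 regions in total.
#'
#' @return data.frame region table with 83 rows.
#' @export
#' @examples
#' nrow(defaultRegionTable())  # 83
defaultRegionTable <- function() {
  nm <- c(paste("lt.", c(DK_CORTICAL, SUBCORTICAL)),
          paste("rt.", c(DK_CORTICAL, SUBCORTICAL)),
          "brainstem")
  hemi <- c(rep("left", 41L), rep("right", 41L), "none")
  regionTable(nm, hemi)
}
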