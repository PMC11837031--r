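#' Region name sets used by the default atlas configuration
#'
#' `wm_atlas_tract_names()` returns the 48 white-matter tract labels of the
#' ICBM-DTI-81 style atlas used for tract-wise WMH volumes.
#' `tractography_tract_names()` returns the 27 tractography-defined bundles
#' whose thresholded volumes are emitted as IDPs.
#' `cortical_roi_names()` returns the 5 bilateral cortical grey-matter ROIs
#' (10 regions) used, together with the corrected hippocampus and amygdala
#' segmentations, for regional weighted MD/MO.
#'
#' Together with the 4 lobar masks, 2 NBM masks and PSMD these define the
#' default supplementary IDP set of 4 + 48 + 2 + 1 + 27 + 28 = 110 phenotypes.
#'
#' @return A character vector of unique region names.
#' @examples
#' length(wm_atlas_tract_names())
#' @export
wm_atlas_tract_names <- function() {
  singles <- c(
    "middle_cerebellar_peduncle", "pontine_crossing_tract",
    "genu_of_corpus_callosum", "body_of_corpus_callosum",
    "splenium_of_corpus_callosum", "fornix_column_and_body"
  )
  pairs <- c(
    "corticospinal_tract", "medial_lemniscus",
    "inferior_cerebellar_peduncle", "superior_cerebellar_peduncle",
    "cerebral_peduncle", "anterior_limb_of_internal_capsule",
    "posterior_limb_of_internal_capsule",
    "retrolenticular_part_of_internal_capsule",
    "anterior_corona_radiata", "superior_corona_radiata",
    "posterior_corona_radiata", "posterior_thalamic_radiation",
    "sagittal_stratum", "external_capsule", "cingulum_cingulate_gyrus",
    "cingulum_hippocampus", "fornix_cres_stria_terminalis",
    "superior_longitudinal_fasciculus",
    "superior_fronto_occipital_fasciculus", "uncinate_fasciculus",
    "tapetum"
  )
  c(singles, paste0(rep(pairs, each = 2L), c("_r", "_l")))
}

#' @rdname wm_atlas_tract_names
#' @export
tractography_tract_names <- function() {
  singles <- c("anterior_commissure", "forceps_major", "forceps_minor",
               "middle_cerebellar_peduncle_tr")
  pairs <- c("arcuate_fasciculus", "acoustic_radiation",
             "anterior_thalamic_radiation", "cingulum_dorsal",
             "corticospinal_tract_tr", "frontal_aslant",
             "fornix", "inferior_fronto_occipital_fasciculus",
             "inferior_longitudinal_fasciculus", "medial_lemniscus_tr",
             "optic_radiation", "superior_longitudinal_fasciculus_1")
  # 3 singles + 12 bilateral pairs = 27, the configured tractography set
  c(singles[1:3], paste0(rep(pairs, each = 2L), c("_l", "_r")))
}

#' @rdname wm_atlas_tract_names
#' @export
cortical_roi_names <- function() {
  c("parahippocampal_gyrus", "precuneus", "superior_frontal_cortex",
    "superior_parietal_cortex", "supramarginal_cortex")
}

lobe_names <- function() c("frontal", "parietal", "temporal", "occipital")
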