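#' Segmentation corrections for atrophic, high-lesion-load brains
#'
#' Upstream tissue segmentations misbehave in the presence of white-matter
#' hyperintensities (WMH) and enlarged CSF spaces: lesions are picked up as
#' grey matter, and subcortical surface fits can leak into ventricles or be
#' placed entirely in CSF. These operators apply the corrections the
#' downstream IDPs depend on.
#'
#' `lesion_mask_gm()` zeroes the GM partial-volume estimate inside the WMH
#' mask and leaves it unchanged elsewhere.
#'
#' `csf_mask_structure()` removes from a binary structure mask all voxels
#' whose CSF value exceeds `csf_threshold`.
#'
#' `detect_mislocalised()` reports whether a structure mask overlaps a binary
#' CSF mask by at least `overlap_threshold` of its own voxels (default 1:
#' complete overlap). Mislocalised structures should be excluded from
#' downstream IDPs rather than corrected.
#'
#' @param gm_pve GM partial-volume `volume_grid` with values in \[0, 1\].
#' @param wmh_mask Binary WMH `volume_grid` on the same grid.
#' @return `lesion_mask_gm()`: the corrected GM partial-volume `volume_grid`.
#' @examples
#' g <- volume_grid(array(1, c(16, 16, 16)))
#' w <- volume_grid(array(0, c(16, 16, 16)))
#' identical(lesion_mask_gm(g, w)$data, g$data)
#' @export
lesion_mask_gm <- function(gm_pve, wmh_mask) {
  assert_unit_interval(gm_pve, "gm_pve")
  assert_binary(wmh_mask, "wmh_mask")
  assert_compatible(gm_pve, wmh_mask, "gm_pve", "wmh_mask")
  volume_grid(gm_pve$data * (1 - wmh_mask$data), gm_pve$voxel_size)
}

#' @rdname lesion_mask_gm
#' @param structure_mask Binary `volume_grid` of a subcortical structure.
#' @param csf_map CSF `volume_grid` (partial volume in \[0, 1\], or binary).
#' @param csf_threshold Voxels with `csf_map > csf_threshold` are removed;
#'   in (0, 1].
#' @return `csf_mask_structure()`: the corrected structure mask.
#' @export
csf_mask_structure <- function(structure_mask, csf_map, csf_threshold = 0.5) {
  assert_binary(structure_mask, "structure_mask")
  assert_unit_interval(csf_map, "csf_map")
  assert_compatible(structure_mask, csf_map, "structure_mask", "csf_map")
  if (!is.numeric(csf_threshold) || csf_threshold <= 0 || csf_threshold > 1) {
    stop("`csf_threshold` must lie in (0, 1]", call. = FALSE)
  }
  volume_grid(structure_mask$data * (1 - (csf_map$data > csf_threshold)),
              structure_mask$voxel_size)
}

#' @rdname lesion_mask_gm
#' @param csf_mask Binary CSF `volume_grid`.
#' @param overlap_threshold Minimum fraction of the structure inside CSF that
#'   counts as mislocalised; default 1 (full overlap).
#' @return `detect_mislocalised()`: a single logical.
#' @export
detect_mislocalised <- function(structure_mask, csf_mask,
                                overlap_threshold = 1) {
  assert_binary(structure_mask, "structure_mask")
  assert_binary(csf_mask, "csf_mask")
  assert_compatible(structure_mask, csf_mask, "structure_mask", "csf_mask")
  n_str <- sum(structure_mask$data)
  if (n_str == 0) {
    stop("structure mask is empty: overlap fraction undefined", call. = FALSE)
  }
  sum(structure_mask$data * csf_mask$data) / n_str >= overlap_threshold
}
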