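#' Default configuration for dementia-informed IDP extraction
#'
#' Thresholds and the atlas composition for [extract_all()]. The default set
#' emits 110 supplementary IDPs: 4 lobar GM volumes, 48 tract-wise WMH
#' volumes, 2 NBM volumes, 1 PSMD, 27 tractography tract volumes, and
#' weighted MD + MO in 14 regions (bilateral hippocampus and amygdala from
#' the corrected structure segmentations, plus 5 bilateral cortical ROIs).
#'
#' @param csf_threshold CSF partial-volume value above which a voxel is
#'   removed from structure masks (binary CSF maps reduce to set removal).
#' @param mislocalised_threshold Overlap fraction with thresholded CSF at
#'   which a structure is declared mislocalised and its IDPs set missing.
#' @param tract_density_threshold Streamline-density binarisation threshold
#'   for tract volumes (strict inequality).
#' @param psmd_percentiles Lower/upper percentiles whose width defines PSMD.
#' @return A named list of configuration values.
#' @export
default_extract_config <- function(csf_threshold = 0.5,
                                   mislocalised_threshold = 1,
                                   tract_density_threshold = 0.005,
                                   psmd_percentiles = c(0.05, 0.95)) {
  stopifnot(csf_threshold > 0, csf_threshold <= 1,
            mislocalised_threshold > 0, mislocalised_threshold <= 1,
            tract_density_threshold >= 0,
            length(psmd_percentiles) == 2,
            psmd_percentiles[1] < psmd_percentiles[2])
  list(csf_threshold = csf_threshold,
       mislocalised_threshold = mislocalised_threshold,
       tract_density_threshold = tract_density_threshold,
       psmd_percentiles = psmd_percentiles)
}

named_grid_list <- function(x, what) {
  if (!is.list(x) || is.null(names(x)) || any(names(x) == "") ||
      anyDuplicated(names(x))) {
    stop(sprintf("`%s` must be a list of uniquely named volume_grids", what),
         call. = FALSE)
  }
  for (nm in names(x)) assert_grid(x[[nm]], paste0(what, "$", nm))
  invisible(x)
}

idp_row <- function(idp_name, modality, value) {
  tibble::tibble(idp_name = idp_name, modality = modality,
                 value = as.numeric(value))
}

#' Lobar grey-matter volumes
#'
#' Sums the (lesion-corrected) GM partial-volume estimate inside each of the
#' four lobar masks and scales by the voxel volume, yielding partial-volume-
#' weighted lobar GM volumes in mm^3.
#'
#' @param corrected_gm_pve GM partial-volume `volume_grid` after
#'   [lesion_mask_gm()].
#' @param lobar_masks Named list of exactly the four binary lobe masks
#'   `frontal`, `parietal`, `temporal`, `occipital`.
#' @return A tibble with columns `idp_name`, `modality` (`"T1"`), `value`
#'   (mm^3); one row per lobe.
#' @export
lobar_gm_volumes <- function(corrected_gm_pve, lobar_masks) {
  assert_unit_interval(corrected_gm_pve, "corrected_gm_pve")
  named_grid_list(lobar_masks, "lobar_masks")
  missing <- setdiff(lobe_names(), names(lobar_masks))
  if (length(missing) > 0) {
    stop("missing lobe mask(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vv <- voxel_volume(corrected_gm_pve)
  purrr::map_dfr(lobe_names(), function(nm) {
    m <- assert_binary(lobar_masks[[nm]], nm)
    assert_compatible(corrected_gm_pve, m, "corrected_gm_pve", nm)
    idp_row(paste0("gm_", nm, "_lobe_volume"), "T1",
            sum(corrected_gm_pve$data * m$data) * vv)
  })
}

#' Tract-wise white-matter-hyperintensity volumes
#'
#' Volume of the overlap between the WMH mask and each atlas WM tract mask,
#' one IDP per tract (48 with the default atlas).
#'
#' @param wmh_mask Binary WMH `volume_grid`.
#' @param wm_tract_masks Named list of binary tract masks; names must be
#'   unique.
#' @return A tibble (`idp_name`, `modality` = `"T2-FLAIR"`, `value` in mm^3),
#'   one row per tract, in the order of `wm_tract_masks`.
#' @export
tractwise_wmh_volumes <- function(wmh_mask, wm_tract_masks) {
  assert_binary(wmh_mask, "wmh_mask")
  named_grid_list(wm_tract_masks, "wm_tract_masks")
  vv <- voxel_volume(wmh_mask)
  purrr::map_dfr(names(wm_tract_masks), function(nm) {
    m <- assert_binary(wm_tract_masks[[nm]], nm)
    assert_compatible(wmh_mask, m, "wmh_mask", nm)
    idp_row(paste0(nm, "_wmh_volume"), "T2-FLAIR",
            sum(wmh_mask$data * m$data) * vv)
  })
}

#' Nucleus basalis of Meynert volumes
#'
#' GM-partial-volume-weighted volume of the left and right NBM masks in mm^3.
#'
#' @param nbm_masks Named list with binary masks `nbm_l` and `nbm_r`.
#' @param gm_pve GM partial-volume `volume_grid` (lesion-corrected upstream).
#' @return A tibble (`idp_name`, `modality` = `"T1"`, `value`), two rows.
#' @export
nbm_volumes <- function(nbm_masks, gm_pve) {
  assert_unit_interval(gm_pve, "gm_pve")
  named_grid_list(nbm_masks, "nbm_masks")
  missing <- setdiff(c("nbm_l", "nbm_r"), names(nbm_masks))
  if (length(missing) > 0) {
    stop("missing hemisphere mask(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vv <- voxel_volume(gm_pve)
  purrr::map_dfr(c("nbm_l", "nbm_r"), function(nm) {
    m <- assert_binary(nbm_masks[[nm]], nm)
    assert_compatible(gm_pve, m, "gm_pve", nm)
    idp_row(paste0(nm, "_volume"), "T1", sum(gm_pve$data * m$data) * vv)
  })
}

#' Peak width of skeletonised mean diffusivity (PSMD)
#'
#' The width between the lower and upper percentiles (default 5th and 95th)
#' of the MD values restricted to the white-matter skeleton; a compact marker
#' of diffuse cerebrovascular white-matter damage. Percentiles use linear
#' interpolation between closest order statistics (quantile type 7).
#'
#' @param md_map Mean-diffusivity `volume_grid` (mm^2/s).
#' @param skeleton_mask Binary skeleton `volume_grid`; must be nonempty.
#' @param percentiles Length-2 probabilities defining the width.
#' @return A single non-negative numeric (mm^2/s).
#' @examples
#' md <- volume_grid(array(seq(0, 1, length.out = 16^3), c(16, 16, 16)))
#' sk <- volume_grid(array(1, c(16, 16, 16)))
#' psmd(md, sk)
#' @export
psmd <- function(md_map, skeleton_mask, percentiles = c(0.05, 0.95)) {
  assert_grid(md_map, "md_map")
  assert_binary(skeleton_mask, "skeleton_mask")
  assert_compatible(md_map, skeleton_mask, "md_map", "skeleton_mask")
  vals <- md_map$data[skeleton_mask$data == 1]
  if (length(vals) == 0) {
    stop("skeleton mask is empty: PSMD undefined", call. = FALSE)
  }
  q <- stats::quantile(vals, probs = percentiles, type = 7, names = FALSE)
  q[2] - q[1]
}

#' Tractography tract volume
#'
#' Binarises a streamline-density map (normalised for the number of valid
#' streamlines, values in \[0, 1\]) at a threshold and returns the volume of
#' the surviving voxels. The comparison is strict (`density > threshold`), so
#' a map sitting exactly at the threshold has zero volume.
#'
#' @param tract_density `volume_grid` with values in \[0, 1\].
#' @param threshold Binarisation threshold; default 0.005.
#' @return A single numeric volume in mm^3.
#' @export
tract_volume <- function(tract_density, threshold = 0.005) {
  assert_grid(tract_density, "tract_density")
  if (min(tract_density$data) < 0) {
    stop("`tract_density` has negative values", call. = FALSE)
  }
  assert_unit_interval(tract_density, "tract_density")
  sum(tract_density$data > threshold) * voxel_volume(tract_density)
}

#' Partial-volume-weighted regional diffusion metrics
#'
#' Weighted mean MD and MO within each region, with weights given by the
#' (lesion-corrected) GM partial-volume estimate restricted to the region
#' mask: `sum(metric * gm * mask) / sum(gm * mask)`. A region whose total
#' weight is zero yields missing values (`NA`), never zero.
#'
#' @param md_map,mo_map Metric `volume_grid`s.
#' @param roi_masks Named list of binary region masks.
#' @param corrected_gm_pve GM partial-volume `volume_grid` after
#'   [lesion_mask_gm()].
#' @return A tibble (`idp_name`, `modality` = `"dMRI"`, `value`) with two
#'   rows per region (`<roi>_md`, `<roi>_mo`).
#' @export
regional_diffusion <- function(md_map, mo_map, roi_masks, corrected_gm_pve) {
  assert_grid(md_map, "md_map")
  assert_grid(mo_map, "mo_map")
  assert_unit_interval(corrected_gm_pve, "corrected_gm_pve")
  assert_compatible(md_map, mo_map, "md_map", "mo_map")
  assert_compatible(md_map, corrected_gm_pve, "md_map", "corrected_gm_pve")
  named_grid_list(roi_masks, "roi_masks")
  purrr::map_dfr(names(roi_masks), function(nm) {
    m <- assert_binary(roi_masks[[nm]], nm)
    assert_compatible(md_map, m, "md_map", nm)
    w <- corrected_gm_pve$data * m$data
    sw <- sum(w)
    if (sw > 0) {
      md <- sum(md_map$data * w) / sw
      mo <- sum(mo_map$data * w) / sw
    } else {
      md <- NA_real_
      mo <- NA_real_
    }
    dplyr::bind_rows(idp_row(paste0(nm, "_md"), "dMRI", md),
                     idp_row(paste0(nm, "_mo"), "dMRI", mo))
  })
}

#' Extract the full supplementary IDP set for one subject
#'
#' Applies the segmentation corrections (lesion-masking of GM, CSF-masking of
#' subcortical structures, mislocalisation detection), then every IDP
#' operator, returning one long-format row per IDP. With the default atlas
#' this is 110 rows: 4 lobar GM volumes and 2 NBM volumes (T1), 48 tract-wise
#' WMH volumes (T2-FLAIR), and PSMD, 27 tract volumes and 28 regional
#' diffusion metrics (dMRI). Structures flagged as mislocalised contribute
#' missing (`NA`) regional-diffusion values.
#'
#' @param subject A `subject_imagery` object (see [make_phantom()] or
#'   [read_imagery()]).
#' @param atlas An `atlas_bundle` object.
#' @param subject_id Identifier stored in the output.
#' @param config See [default_extract_config()].
#' @return A tibble with columns `subject_id`, `idp_name`, `modality`,
#'   `value`; `(subject_id, idp_name)` unique.
#' @examples
#' ph <- make_phantom(seed = 1)
#' idps <- extract_all(ph$subject, ph$atlas, subject_id = "phantom01")
#' dplyr::count(idps, modality)
#' @export
extract_all <- function(subject, atlas, subject_id = "subject",
                        config = default_extract_config()) {
  stopifnot(inherits(subject, "subject_imagery"),
            inherits(atlas, "atlas_bundle"))

  gm_corr <- lesion_mask_gm(subject$gm_pve, subject$wmh_mask)
  csf_bin <- volume_grid(
    (subject$csf_map$data > config$csf_threshold) * 1,
    subject$csf_map$voxel_size)

  # corrected structures; mislocalised ones are dropped to missing IDPs
  structures <- list()
  for (nm in names(subject$structure_masks)) {
    m <- subject$structure_masks[[nm]]
    mis <- detect_mislocalised(m, csf_bin, config$mislocalised_threshold)
    structures[[nm]] <- if (mis) NULL else
      csf_mask_structure(m, subject$csf_map, config$csf_threshold)
  }

  out <- dplyr::bind_rows(
    with_idp_errors("lobar GM volumes",
      lobar_gm_volumes(gm_corr, atlas$lobar_masks)),
    with_idp_errors("tract-wise WMH volumes",
      tractwise_wmh_volumes(subject$wmh_mask, atlas$wm_tract_masks)),
    with_idp_errors("NBM volumes", nbm_volumes(atlas$nbm_masks, gm_corr)),
    with_idp_errors("psmd",
      idp_row("psmd", "dMRI",
              psmd(subject$md_map, subject$skeleton_mask,
                   config$psmd_percentiles)))
  )

  tr <- atlas$tractography_tract_names
  missing_tr <- setdiff(tr, names(subject$tract_density))
  if (length(missing_tr) > 0) {
    stop("no density map for tract(s): ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::bind_rows(out, purrr::map_dfr(tr, function(nm) {
    with_idp_errors(paste0(nm, "_tract_volume"),
      idp_row(paste0(nm, "_tract_volume"), "dMRI",
              tract_volume(subject$tract_density[[nm]],
                           config$tract_density_threshold)))
  }))

  # regional diffusion: corrected structures first, then cortical atlas ROIs;
  # mislocalised structures keep their IDP names with missing values
  roi_masks <- c(purrr::compact(structures), atlas$gm_roi_masks)
  reg <- with_idp_errors("regional diffusion",
    regional_diffusion(subject$md_map, subject$mo_map, roi_masks, gm_corr))
  dropped <- setdiff(names(subject$structure_masks),
                     names(purrr::compact(structures)))
  if (length(dropped) > 0) {
    reg <- dplyr::bind_rows(reg, purrr::map_dfr(dropped, function(nm) {
      dplyr::bind_rows(idp_row(paste0(nm, "_md"), "dMRI", NA_real_),
                       idp_row(paste0(nm, "_mo"), "dMRI", NA_real_))
    }))
  }
  out <- dplyr::bind_rows(out, reg)

  out <- dplyr::mutate(out, subject_id = subject_id, .before = 1)
  if (anyDuplicated(out$idp_name) > 0) {
    stop("duplicate IDP names in output", call. = FALSE)
  }
  out
}

# Attach the IDP (group) name to any operator error.
with_idp_errors <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE)
  })
}
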