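#' Generate a synthetic single-subject phantom with countable ground truth
#'
#' Builds the full set of grid-aligned maps a preprocessed subject contributes
#' (GM partial-volume map, WMH mask, CSF map, subcortical structure masks,
#' MD/MO maps, WM skeleton, per-tract streamline-density maps) together with a
#' matching atlas bundle (4 lobar masks, 48 WM tract masks, 2 NBM masks, 5
#' bilateral cortical ROI masks) and the exact ground-truth value of every
#' volume and regional-diffusion IDP, obtained by direct voxel counting on the
#' constructed arrays.
#'
#' Regions are axis-aligned boxes placed at fixed coordinates designed to fit
#' the minimum 16^3 grid (larger grids simply carry empty margin), so every
#' overlap is an exact countable voxel set rather than an anatomically
#' realistic shape. Lesions are sampled inside the deep white-matter block and
#' the temporal lobe, so lesion-masking of GM and WMH-by-tract overlaps are
#' both exercised. The left hippocampus box partially overlaps the
#' high-CSF ventricle block so that CSF-masking removes a known voxel set.
#'
#' @param seed Integer seed; generation is fully reproducible.
#' @param shape Integer length-3 grid shape, each dimension >= 16.
#' @param voxel_size Voxel edge lengths in mm.
#' @param wmh_burden Fraction in \[0, 1\] of candidate deep-WM/temporal voxels
#'   converted to lesion.
#' @param atrophy Fraction in \[0, 1\]; GM partial volumes are scaled by
#'   `1 - atrophy`.
#' @param config Extraction configuration, see [default_extract_config()];
#'   ground truth honours its thresholds.
#' @return A list with elements `subject` (class `subject_imagery`), `atlas`
#'   (class `atlas_bundle`) and `ground_truth` (tibble: `idp_name`,
#'   `modality`, `value`).
#' @examples
#' ph <- make_phantom(seed = 1)
#' ph$ground_truth
#' @export
make_phantom <- function(seed, shape = c(32L, 32L, 32L), voxel_size = c(2, 2, 2),
                         wmh_burden = 0.02, atrophy = 0,
                         config = default_extract_config()) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L)) {
    stop("`shape` must be 3 integers, each >= 16", call. = FALSE)
  }
  if (wmh_burden < 0 || wmh_burden > 1 || atrophy < 0 || atrophy > 1) {
    stop("`wmh_burden` and `atrophy` must lie in [0, 1]", call. = FALSE)
  }

  box <- function(xr, yr, zr) {
    m <- array(0, shape)
    m[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- 1
    m
  }
  vg <- function(a) volume_grid(a, voxel_size)
  vv <- prod(voxel_size)

  withr::with_seed(seed, {
    brain <- box(c(2, 15), c(2, 15), c(2, 15))

    # lobar parcellation: four x/y quadrants of the upper brain band
    lobes <- list(
      frontal   = box(c(2, 8),  c(2, 8),  c(9, 14)),
      parietal  = box(c(9, 15), c(2, 8),  c(9, 14)),
      temporal  = box(c(2, 8),  c(9, 15), c(9, 14)),
      occipital = box(c(9, 15), c(9, 15), c(9, 14))
    )

    # deep WM block tiled into the 48 atlas tracts (3x3x2 voxels each)
    tract_names <- wm_atlas_tract_names()
    tracts <- vector("list", 48L)
    names(tracts) <- tract_names
    i <- 1L
    for (kz in 0:2) for (ky in 0:3) for (kx in 0:3) {
      tracts[[i]] <- box(c(4 + 3 * kx, 6 + 3 * kx),
                         c(4 + 3 * ky, 6 + 3 * ky),
                         c(3 + 2 * kz, 4 + 2 * kz))
      i <- i + 1L
    }
    wm_block <- box(c(4, 15), c(4, 15), c(3, 8))
    skeleton <- box(c(4, 15), c(4, 15), c(5, 5))

    # tractography bundles: 27 density maps on a 3x3x3 tiling of a 6^3 block
    tr_names <- tractography_tract_names()
    density <- vector("list", 27L)
    names(density) <- tr_names
    i <- 1L
    for (kz in 0:2) for (ky in 0:2) for (kx in 0:2) {
      tile <- box(c(4 + 2 * kx, 5 + 2 * kx),
                  c(4 + 2 * ky, 5 + 2 * ky),
                  c(10 + 2 * kz, 11 + 2 * kz))
      d <- array(0, shape)
      idx <- which(tile == 1)
      d[idx] <- stats::runif(length(idx))   # a few voxels may fall below 0.005
      density[[i]] <- d
      i <- i + 1L
    }

    # ventricle block: high CSF, partially overlapping the left hippocampus
    ventricle <- box(c(7, 10), c(7, 10), c(9, 12))
    csf <- array(0, shape)
    csf[brain == 1] <- stats::runif(sum(brain), 0, 0.3)
    csf[ventricle == 1] <- stats::runif(sum(ventricle), 0.65, 1)

    structures <- list(
      hippocampus_l = box(c(5, 7),   c(9, 11), c(9, 11)),
      hippocampus_r = box(c(11, 13), c(9, 11), c(9, 11)),
      amygdala_l    = box(c(5, 7),   c(4, 6),  c(9, 11)),
      amygdala_r    = box(c(11, 13), c(4, 6),  c(9, 11))
    )

    nbm <- list(
      nbm_l = box(c(7, 8),  c(4, 5), c(9, 10)),
      nbm_r = box(c(9, 10), c(4, 5), c(9, 10))
    )

    roi_boxes <- list(
      parahippocampal_gyrus_l    = box(c(2, 4),   c(9, 11),  c(13, 14)),
      parahippocampal_gyrus_r    = box(c(12, 14), c(9, 11),  c(13, 14)),
      precuneus_l                = box(c(2, 4),   c(12, 14), c(13, 14)),
      precuneus_r                = box(c(12, 14), c(12, 14), c(13, 14)),
      superior_frontal_cortex_l  = box(c(2, 4),   c(2, 4),   c(13, 14)),
      superior_frontal_cortex_r  = box(c(12, 14), c(2, 4),   c(13, 14)),
      superior_parietal_cortex_l = box(c(5, 7),   c(12, 14), c(13, 14)),
      superior_parietal_cortex_r = box(c(9, 11),  c(12, 14), c(13, 14)),
      supramarginal_cortex_l     = box(c(5, 7),   c(2, 4),   c(13, 14)),
      supramarginal_cortex_r     = box(c(9, 11),  c(2, 4),   c(13, 14))
    )

    gm <- array(0, shape)
    gm[brain == 1] <- stats::runif(sum(brain), 0.2, 0.9) * (1 - atrophy)

    # lesions: sampled without replacement from deep WM and the temporal lobe
    cand <- which(wm_block == 1 | lobes$temporal == 1)
    n_les <- round(wmh_burden * length(cand))
    wmh <- array(0, shape)
    if (n_les > 0) wmh[sample(cand, n_les)] <- 1

    md <- array((700 + 300 * stats::runif(prod(shape))) * 1e-6, shape)
    mo <- array(stats::runif(prod(shape), -0.5, 0.9), shape)
  })

  subject <- structure(list(
    gm_pve = vg(gm), wmh_mask = vg(wmh), csf_map = vg(csf),
    structure_masks = lapply(structures, vg),
    md_map = vg(md), mo_map = vg(mo), skeleton_mask = vg(skeleton),
    tract_density = lapply(density, vg), bold = NULL
  ), class = "subject_imagery")

  atlas <- structure(list(
    lobar_masks = lapply(lobes, vg),
    wm_tract_masks = lapply(tracts, vg),
    nbm_masks = lapply(nbm, vg),
    gm_roi_masks = lapply(roi_boxes, vg),
    tractography_tract_names = tr_names
  ), class = "atlas_bundle")

  # ground truth by direct arithmetic on the constructed arrays
  gm_corr <- gm * (1 - wmh)
  truth <- list()
  for (nm in names(lobes)) {
    truth[[paste0("gm_", nm, "_lobe_volume")]] <-
      list(value = sum(gm_corr * lobes[[nm]]) * vv, mod = "T1")
  }
  for (nm in tract_names) {
    truth[[paste0(nm, "_wmh_volume")]] <-
      list(value = sum(wmh * tracts[[nm]]) * vv, mod = "T2-FLAIR")
  }
  for (nm in names(nbm)) {
    truth[[paste0(nm, "_volume")]] <-
      list(value = sum(gm_corr * nbm[[nm]]) * vv, mod = "T1")
  }
  sk_md <- md[skeleton == 1]
  truth[["psmd"]] <- list(
    value = unname(diff(stats::quantile(sk_md, config$psmd_percentiles, type = 7))),
    mod = "dMRI")
  for (nm in tr_names) {
    truth[[paste0(nm, "_tract_volume")]] <-
      list(value = sum(density[[nm]] > config$tract_density_threshold) * vv,
           mod = "dMRI")
  }
  roi_all <- c(
    lapply(structures, function(m) m * (1 - (csf > config$csf_threshold))),
    roi_boxes
  )
  for (nm in names(roi_all)) {
    w <- gm_corr * roi_all[[nm]]
    sw <- sum(w)
    truth[[paste0(nm, "_md")]] <-
      list(value = if (sw > 0) sum(md * w) / sw else NA_real_, mod = "dMRI")
    truth[[paste0(nm, "_mo")]] <-
      list(value = if (sw > 0) sum(mo * w) / sw else NA_real_, mod = "dMRI")
  }

  ground_truth <- tibble::tibble(
    idp_name = names(truth),
    modality = vapply(truth, function(x) x[["mod"]], character(1)),
    value = unname(vapply(truth, function(x) as.numeric(x$value), numeric(1)))
  )

  list(subject = subject, atlas = atlas, ground_truth = ground_truth)
}

#' @export
print.subject_imagery <- function(x, ...) {
  cat(sprintf(
    "<subject_imagery %s: gm/wmh/csf/md/mo/skeleton, %d structures, %d tract densities%s>\n",
    paste(dim(x$gm_pve$data), collapse = "x"),
    length(x$structure_masks), length(x$tract_density),
    if (is.null(x$bold)) "" else ", bold"))
  invisible(x)
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf(
    "<atlas_bundle: %d lobes, %d WM tracts, %d NBM, %d GM ROIs, %d tractography tracts>\n",
    length(x$lobar_masks), length(x$wm_tract_masks), length(x$nbm_masks),
    length(x$gm_roi_masks), length(x$tractography_tract_names)))
  invisible(x)
}
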