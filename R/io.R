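#' Write and read subject imagery and atlas bundles as NIfTI + manifest
#'
#' `write_imagery()` stores every map of a `subject_imagery` and
#' `atlas_bundle` as a gzipped NIfTI file (one file per map, voxel
#' dimensions in the header) and writes a JSON manifest naming each file's
#' role, with the generation seed/parameters echoed when given.
#' `read_imagery()` reconstructs both objects from a manifest, so any
#' equivalently structured user-supplied bundle can feed [extract_all()].
#'
#' @param subject A `subject_imagery`.
#' @param atlas An `atlas_bundle` (optional for `write_imagery`).
#' @param dir Output directory, created if needed.
#' @param parameters Named list echoed verbatim into the manifest (seed,
#'   generation parameters).
#' @return `write_imagery()`: the manifest path, invisibly.
#'   `read_imagery()`: a list with `subject`, `atlas` (may be `NULL`) and
#'   `manifest`.
#' @export
write_imagery <- function(subject, atlas = NULL, dir,
                          parameters = list()) {
  stopifnot(inherits(subject, "subject_imagery"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- subject$gm_pve$voxel_size

  save_grid <- function(grid, name) {
    file <- paste0(name, ".nii.gz")
    img <- RNifti::asNifti(grid$data)
    RNifti::pixdim(img) <- grid$voxel_size
    RNifti::writeNifti(img, file.path(dir, file))
    file
  }

  manifest <- list(
    voxel_size = vox,
    shape = dim(subject$gm_pve$data),
    parameters = parameters,
    subject = list(
      gm_pve = save_grid(subject$gm_pve, "gm_pve"),
      wmh_mask = save_grid(subject$wmh_mask, "wmh_mask"),
      csf_map = save_grid(subject$csf_map, "csf_map"),
      md_map = save_grid(subject$md_map, "md_map"),
      mo_map = save_grid(subject$mo_map, "mo_map"),
      skeleton_mask = save_grid(subject$skeleton_mask, "skeleton_mask"),
      structure_masks = lapply(
        stats::setNames(nm = names(subject$structure_masks)),
        function(nm) save_grid(subject$structure_masks[[nm]],
                               paste0("structure_", nm))),
      tract_density = lapply(
        stats::setNames(nm = names(subject$tract_density)),
        function(nm) save_grid(subject$tract_density[[nm]],
                               paste0("density_", nm)))
    )
  )
  if (!is.null(atlas)) {
    stopifnot(inherits(atlas, "atlas_bundle"))
    manifest$atlas <- list(
      lobar_masks = lapply(
        stats::setNames(nm = names(atlas$lobar_masks)),
        function(nm) save_grid(atlas$lobar_masks[[nm]],
                               paste0("lobe_", nm))),
      wm_tract_masks = lapply(
        stats::setNames(nm = names(atlas$wm_tract_masks)),
        function(nm) save_grid(atlas$wm_tract_masks[[nm]],
                               paste0("tract_", nm))),
      nbm_masks = lapply(
        stats::setNames(nm = names(atlas$nbm_masks)),
        function(nm) save_grid(atlas$nbm_masks[[nm]], nm)),
      gm_roi_masks = lapply(
        stats::setNames(nm = names(atlas$gm_roi_masks)),
        function(nm) save_grid(atlas$gm_roi_masks[[nm]],
                               paste0("roi_", nm))),
      tractography_tract_names = atlas$tractography_tract_names
    )
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_imagery
#' @param manifest_path Path to a manifest written by `write_imagery()` (or
#'   hand-authored with the same structure).
#' @export
read_imagery <- function(manifest_path) {
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  vox <- as.numeric(manifest$voxel_size)

  load_grid <- function(file) {
    img <- RNifti::readNifti(file.path(dir, file))
    volume_grid(array(as.numeric(img), dim = dim(img)), vox)
  }
  load_named <- function(x) lapply(as.list(x), load_grid)

  s <- manifest$subject
  subject <- structure(list(
    gm_pve = load_grid(s$gm_pve),
    wmh_mask = load_grid(s$wmh_mask),
    csf_map = load_grid(s$csf_map),
    structure_masks = load_named(s$structure_masks),
    md_map = load_grid(s$md_map),
    mo_map = load_grid(s$mo_map),
    skeleton_mask = load_grid(s$skeleton_mask),
    tract_density = load_named(s$tract_density),
    bold = NULL
  ), class = "subject_imagery")

  atlas <- NULL
  if (!is.null(manifest$atlas)) {
    a <- manifest$atlas
    atlas <- structure(list(
      lobar_masks = load_named(a$lobar_masks),
      wm_tract_masks = load_named(a$wm_tract_masks),
      nbm_masks = load_named(a$nbm_masks),
      gm_roi_masks = load_named(a$gm_roi_masks),
      tractography_tract_names = unlist(a$tractography_tract_names)
    ), class = "atlas_bundle")
  }
  list(subject = subject, atlas = atlas, manifest = manifest)
}

#' Tab-separated table IO
#'
#' Thin wrappers fixing the TSV dialect used for all tabular outputs (header
#' row, tab separator, no quoting, `NA` for missing).
#'
#' @param x A data.frame/tibble.
#' @param path File path.
#' @return `read_tsv_table()`: a tibble. `write_tsv_table()`: `path`,
#'   invisibly.
#' @export
write_tsv_table <- function(x, path) {
  df <- as.data.frame(x)
  list_cols <- vapply(df, is.list, logical(1))
  for (nm in names(df)[list_cols]) {
    df[[nm]] <- vapply(df[[nm]], function(v) paste(v, collapse = ","),
                       character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}
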