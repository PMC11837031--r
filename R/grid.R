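#' Voxel-space scalar field on a regular grid
#'
#' A `volume_grid` is the unit all masks and maps in this package share: a 3D
#' numeric array plus the physical voxel dimensions in millimetres. Masks are
#' `volume_grid`s restricted to \{0, 1\}; partial-volume maps are restricted to
#' \[0, 1\]. No spatial transform is carried: all grids in one analysis are
#' assumed registered to the same space.
#'
#' @param data A 3D numeric array. All values must be finite.
#' @param voxel_size Numeric length-3 vector of voxel edge lengths in mm;
#'   strictly positive.
#' @return An object of class `volume_grid` with elements `data` and
#'   `voxel_size`.
#' @examples
#' g <- volume_grid(array(0, c(16, 16, 16)), c(2, 2, 2))
#' voxel_volume(g)
#' @export
volume_grid <- function(data, voxel_size = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("`data` must be finite everywhere", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 strictly positive lengths (mm)",
         call. = FALSE)
  }
  structure(list(data = data, voxel_size = voxel_size),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, voxel %s mm, range [%g, %g]>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname volume_grid
#' @param x A `volume_grid`.
#' @return `voxel_volume()`: the volume of one voxel in mm^3.
#' @export
voxel_volume <- function(x) {
  stopifnot(inherits(x, "volume_grid"))
  prod(x$voxel_size)
}

#' @rdname volume_grid
#' @export
is_volume_grid <- function(x) inherits(x, "volume_grid")

# Internal helpers ------------------------------------------------------------

grid_shape <- function(x) dim(x$data)

assert_grid <- function(x, what = "grid") {
  if (!is_volume_grid(x)) {
    stop(sprintf("`%s` must be a volume_grid", what), call. = FALSE)
  }
  invisible(x)
}

# Two grids live on the same lattice: identical shape and voxel size.
assert_compatible <- function(a, b, what_a = "first", what_b = "second") {
  assert_grid(a, what_a)
  assert_grid(b, what_b)
  if (!identical(dim(a$data), dim(b$data))) {
    stop(sprintf("shape mismatch: `%s` is %s but `%s` is %s",
                 what_a, paste(dim(a$data), collapse = "x"),
                 what_b, paste(dim(b$data), collapse = "x")), call. = FALSE)
  }
  if (!isTRUE(all.equal(a$voxel_size, b$voxel_size))) {
    stop(sprintf("voxel size mismatch between `%s` and `%s`",
                 what_a, what_b), call. = FALSE)
  }
  invisible(NULL)
}

assert_binary <- function(x, what = "mask") {
  assert_grid(x, what)
  if (!all(x$data %in% c(0, 1))) {
    stop(sprintf("`%s` must be binary (values in {0, 1})", what),
         call. = FALSE)
  }
  invisible(x)
}

assert_unit_interval <- function(x, what = "map") {
  assert_grid(x, what)
  if (min(x$data) < 0 || max(x$data) > 1) {
    stop(sprintf("`%s` must take values in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
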