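#' Voxel grid geometry
#'
#' A `volume_grid` ties a 3D voxel lattice to world (scanner / MNI-like)
#' millimetre coordinates through a 4x4 affine. Voxel indices are 0-based in
#' the affine convention (the first voxel of the array maps through
#' `affine %*% c(0, 0, 0, 1)`); the R-facing accessors below accept 1-based
#' array indices and convert.
#'
#' @param shape integer vector of length 3, voxels per axis (all > 0).
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world mm.
#'   Defaults to an isotropic `voxel_mm` scaling centred at the origin corner.
#' @param voxel_mm voxel edge length(s) in mm used to build the default affine.
#' @return An object of class `volume_grid` with fields `shape`, `affine`,
#'   `voxel_size` (mm per axis, derived from the affine columns).
#' @examples
#' g <- volume_grid(c(10, 10, 6), voxel_mm = 3)
#' voxel_to_world(g, c(1, 1, 1))  # first voxel -> affine origin
#' @export
volume_grid <- function(shape, affine = NULL, voxel_mm = 3) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(!is.finite(shape)) || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  if (is.null(affine)) {
    voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
    affine <- diag(c(voxel_mm, 1))
  }
  if (is.null(dim(affine)) || !all(dim(affine) == c(4L, 4L)) ||
      any(!is.finite(affine)))
    stop("'affine' must be a finite 4x4 matrix")
  affine <- matrix(as.numeric(affine), 4L, 4L)  # drop foreign attributes
  if (abs(det(affine)) < 1e-12) stop("'affine' must be invertible")
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxel_size <= 0)) stop("voxel sizes derived from affine must be > 0")
  structure(list(shape = shape, affine = affine, voxel_size = voxel_size),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Map voxel indices to world coordinates and back
#'
#' @param grid a [volume_grid()].
#' @param ijk numeric matrix (rows = voxels) or vector of 1-based array indices.
#' @param xyz numeric matrix (rows = points) or vector of world mm coordinates.
#' @return `voxel_to_world`: world mm coordinates; `world_to_voxel`: 1-based
#'   (possibly fractional) voxel indices.
#' @export
voxel_to_world <- function(grid, ijk) {
  vec <- is.null(dim(ijk))
  ijk <- rbind_vec(ijk)
  xyz <- cbind(ijk - 1, 1) %*% t(grid$affine)  # 0-based convention
  out <- xyz[, 1:3, drop = FALSE]
  if (vec) drop(out) else out
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(grid, xyz) {
  vec <- is.null(dim(xyz))
  xyz <- rbind_vec(xyz)
  ijk <- cbind(xyz, 1) %*% t(solve(grid$affine))
  out <- ijk[, 1:3, drop = FALSE] + 1
  if (vec) drop(out) else out
}

rbind_vec <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
}

#' Group analysis mask
#'
#' A `group_mask` fixes the set of analysed voxels and the ordering that every
#' voxel-wise vector in the package uses. Mask voxels are numbered
#' lexicographically by (i, j, k) with the LAST axis fastest (k varies first),
#' so ordinal 1 is the smallest (i, j, k) inside the mask under that rule.
#' The ordering is a bijection between ordinals `1..V` and 3D indices.
#'
#' @param grid a [volume_grid()].
#' @param inside logical 3D array of `grid$shape` marking in-mask voxels.
#' @return Object of class `group_mask`: `grid`, `inside`, `n_voxels`,
#'   `ijk` (V x 3 matrix of 1-based indices in mask-ordinal order), and
#'   `ordinal` (3D integer array, 0 outside the mask).
#' @export
group_mask <- function(grid, inside) {
  stopifnot(inherits(grid, "volume_grid"))
  inside <- array(as.logical(inside), dim = grid$shape)
  if (anyNA(inside)) stop("'inside' must not contain NA")
  n <- sum(inside)
  if (n < 2L) stop("mask must contain at least 2 voxels")
  ijk <- which(inside, arr.ind = TRUE)
  ord <- order(ijk[, 1L], ijk[, 2L], ijk[, 3L])  # last axis fastest
  ijk <- ijk[ord, , drop = FALSE]
  dimnames(ijk) <- NULL
  ordinal <- array(0L, dim = grid$shape)
  ordinal[ijk] <- seq_len(n)
  structure(list(grid = grid, inside = inside, n_voxels = n,
                 ijk = ijk, ordinal = ordinal),
            class = "group_mask")
}

#' @export
print.group_mask <- function(x, ...) {
  cat("<group_mask> ", x$n_voxels, " voxels on a ",
      paste(x$grid$shape, collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

#' Mask-ordinal bookkeeping
#'
#' @param mask a [group_mask()].
#' @param ordinal integer vector of mask ordinals (1-based).
#' @param ijk matrix (rows = voxels) of 1-based 3D indices.
#' @return `mask_ordinal_to_ijk`: V x 3 index matrix; `mask_ijk_to_ordinal`:
#'   integer ordinals (0 for out-of-mask voxels).
#' @export
mask_ordinal_to_ijk <- function(mask, ordinal) {
  stopifnot(all(ordinal >= 1L), all(ordinal <= mask$n_voxels))
  mask$ijk[ordinal, , drop = FALSE]
}

#' @rdname mask_ordinal_to_ijk
#' @export
mask_ijk_to_ordinal <- function(mask, ijk) {
  mask$ordinal[rbind_vec(ijk)]
}

#' Build a study-specific group mask
#'
#' Intersects per-subject coverage masks and applies a gray-matter probability
#' threshold: a voxel is retained when it is present in every subject's mask
#' and its gray-matter probability is at least `threshold` (default 0.25,
#' matching a 25% probability gray-matter mask).
#'
#' @param subject_masks list of logical 3D arrays, one per subject, sharing
#'   one grid shape.
#' @param gm_prob numeric 3D array of gray-matter probabilities in \[0, 1\],
#'   or `NULL` to skip the tissue criterion.
#' @param threshold gray-matter probability cut-off in \[0, 1\].
#' @param grid a [volume_grid()] describing the shared geometry.
#' @return A [group_mask()].
#' @export
make_group_mask <- function(subject_masks, gm_prob = NULL, threshold = 0.25,
                            grid = volume_grid(dim(subject_masks[[1]]))) {
  if (length(subject_masks) < 1L) stop("need at least one subject mask")
  shp <- grid$shape
  inside <- array(TRUE, dim = shp)
  for (m in subject_masks) {
    if (!all(dim(m) == shp)) stop("subject masks must share one grid shape")
    inside <- inside & as.logical(m)
  }
  if (!is.null(gm_prob)) {
    if (!all(dim(gm_prob) == shp)) stop("gm_prob grid mismatch")
    if (threshold < 0 || threshold > 1) stop("'threshold' must be in [0, 1]")
    inside <- inside & (gm_prob >= threshold)
  }
  if (sum(inside) < 2L)
    stop("resulting group mask is empty (fewer than 2 voxels)")
  group_mask(grid, inside)
}
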