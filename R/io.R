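#' Per-voxel statistic map
#'
#' A vector of values over the mask voxels (in mask-ordinal order) together
#' with the map kind. Values may be NA where a voxel was flagged missing.
#'
#' @param values numeric vector of length `mask$n_voxels`.
#' @param mask a [group_mask()].
#' @param kind one of `"pseudoF"`, `"p"`, `"z"`, `"t"`, `"r"`, `"fisherz"`.
#' @return Object of class `stat_map`.
#' @export
stat_map <- function(values, mask,
                     kind = c("z", "pseudoF", "p", "t", "r", "fisherz")) {
  kind <- match.arg(kind)
  stopifnot(inherits(mask, "group_mask"))
  values <- as.numeric(values)
  if (length(values) != mask$n_voxels)
    stop("length(values) must equal the mask voxel count")
  if (kind == "p") {
    bad <- which(is.finite(values) & (values <= 0 | values > 1))
    if (length(bad))
      stop("p-map values must lie in (0, 1]; first offender: voxel ", bad[1])
  }
  structure(list(values = values, mask = mask, kind = kind),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat("<stat_map:", x$kind, "> ", x$mask$n_voxels, " voxels, range [",
      signif(min(v), 4), ", ", signif(max(v), 4), "], ",
      sum(!is.finite(x$values)), " missing\n", sep = "")
  invisible(x)
}

#' Expand a mask-ordinal vector to a full 3D array
#'
#' @param x a `stat_map` or numeric vector over mask voxels.
#' @param mask a [group_mask()] (taken from `x` when it is a `stat_map`).
#' @param fill value for out-of-mask voxels.
#' @return 3D numeric array of the grid shape.
#' @export
map_to_volume <- function(x, mask = NULL, fill = 0) {
  if (inherits(x, "stat_map")) { mask <- x$mask; x <- x$values }
  stopifnot(inherits(mask, "group_mask"), length(x) == mask$n_voxels)
  vol <- array(fill, dim = mask$grid$shape)
  vol[mask$ijk] <- x
  vol
}

#' One subject's masked BOLD time series
#'
#' @param subject_id character scalar.
#' @param data T x V numeric matrix, columns in mask-ordinal order.
#' @param tr repetition time in seconds.
#' @param mask a [group_mask()].
#' @return Object of class `subject_ts`.
#' @export
subject_ts <- function(subject_id, data, tr, mask) {
  stopifnot(inherits(mask, "group_mask"))
  data <- as.matrix(data)
  if (nrow(data) < 3L) stop("need at least 3 timepoints")
  if (ncol(data) != mask$n_voxels)
    stop("data has ", ncol(data), " columns but mask has ",
         mask$n_voxels, " voxels")
  bad <- which(!is.finite(data))
  if (length(bad)) {
    vox <- ((bad[1] - 1L) %/% nrow(data)) + 1L
    stop("non-finite value inside the mask at voxel ordinal ", vox,
         " (t = ", ((bad[1] - 1L) %% nrow(data)) + 1L, ")")
  }
  if (!is.finite(tr) || tr <= 0) stop("'tr' must be a positive number")
  structure(list(subject_id = as.character(subject_id), data = data,
                 tr = as.numeric(tr), mask = mask),
            class = "subject_ts")
}

#' @export
print.subject_ts <- function(x, ...) {
  cat("<subject_ts> ", x$subject_id, ": ", nrow(x$data), " volumes x ",
      ncol(x$data), " voxels, TR = ", x$tr, " s\n", sep = "")
  invisible(x)
}

#' Read a 4D BOLD NIfTI into mask space
#'
#' Loads a 4D volume, checks its spatial dimensions against the mask grid,
#' and returns the in-mask time series as a T x V matrix in mask-ordinal
#' order. TR is taken from the NIfTI header (pixdim\[4\]) unless overridden.
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param mask a [group_mask()].
#' @param subject_id identifier stored on the result; defaults to the file
#'   base name.
#' @param tr override for the repetition time in seconds.
#' @return A [subject_ts()].
#' @export
read_bold <- function(path, mask, subject_id = NULL, tr = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D NIfTI, got ", length(d), "D")
  if (!all(d[1:3] == mask$grid$shape))
    stop("spatial dimensions ", paste(d[1:3], collapse = "x"),
         " do not match the mask grid ",
         paste(mask$grid$shape, collapse = "x"))
  if (d[4] < 3L) stop("fewer than 3 volumes")
  if (is.null(tr)) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0)
      stop("TR missing from header; pass 'tr' explicitly")
  }
  flat <- matrix(as.numeric(img), prod(d[1:3]), d[4])
  lin <- as.integer(mask$ijk[, 1] +
                    (mask$ijk[, 2] - 1L) * d[1] +
                    (mask$ijk[, 3] - 1L) * d[1] * d[2])
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  subject_ts(subject_id, t(flat[lin, , drop = FALSE]), tr, mask)
}

#' Write a statistic map as NIfTI
#'
#' Out-of-mask voxels are written as 0 (missing in-mask voxels as NA -> 0 with
#' a warning). Values are stored as float64 so the write/read round trip is
#' value-exact for finite inputs.
#'
#' @param map a [stat_map()].
#' @param path output file (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  vals <- map$values
  if (anyNA(vals)) {
    warning("writing ", sum(is.na(vals)), " missing voxels as 0")
    vals[is.na(vals)] <- 0
  }
  vol <- map_to_volume(vals, map$mask, fill = 0)
  img <- RNifti::asNifti(vol, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(map$mask$grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a mask volume as NIfTI
#' @param mask a [group_mask()].
#' @param path file path.
#' @rdname write_stat_map
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$inside),
                               dim = mask$grid$shape), datatype = "uint8")
  img <- RNifti::`sform<-`(img, structure(mask$grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param path NIfTI mask file.
#' @rdname write_stat_map
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D mask volume")
  grid <- volume_grid(d, affine = RNifti::xform(img))
  group_mask(grid, array(img != 0, dim = d))
}

#' Read a phenotype table
#'
#' CSV with a header row; a `subject_id` column is mandatory and must be
#' unique. Standard-score columns (`literacy_ss`, `numeracy_ss`) are checked
#' to be finite when present; `mean_fd` must be non-negative.
#'
#' @param path CSV file.
#' @return data.frame with `subject_id` as character.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_phenotypes(tab)
}

validate_phenotypes <- function(tab) {
  if (!"subject_id" %in% names(tab)) stop("phenotype table needs 'subject_id'")
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id)) stop("subject_id values must be unique")
  for (col in intersect(c("literacy_ss", "numeracy_ss"), names(tab)))
    if (any(!is.finite(tab[[col]])))
      stop("non-finite values in '", col, "'")
  if ("mean_fd" %in% names(tab) && any(tab$mean_fd < 0, na.rm = TRUE))
    stop("'mean_fd' must be >= 0")
  tab
}

#' Read a whitespace-delimited T x 6 motion trace
#'
#' Columns are 3 translations (mm) then 3 rotations (radians).
#'
#' @param path text file.
#' @return T x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  if (ncol(m) != 6L) stop("motion trace must have 6 columns")
  if (any(!is.finite(m))) stop("motion trace contains non-finite values")
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
  m
}
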