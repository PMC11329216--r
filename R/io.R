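# NIfTI / gradient-table readers and writers (FSL bval/bvec dialect)
# and atlas I/O.

B0_THRESHOLD <- 50  # s/mm^2: volumes below this count as b = 0

#' Read a 4D diffusion acquisition
#'
#' Reads a NIfTI volume plus FSL-dialect gradient tables (bval: one
#' whitespace-separated row; bvec: 3 rows x N columns). Volumes with
#' b < 50 s/mm^2 are taken as b = 0; gradient directions are renormalized
#' to unit length with a warning if any norm deviates by more than 1e-3.
#'
#' @param nifti_path 4D NIfTI file.
#' @param bval_path bval text file.
#' @param bvec_path bvec text file.
#' @param tau diffusion time in seconds (default 0.0387).
#' @return list: `dwi` (4D array, reordered so b0 volumes come first),
#'   `scheme` (a [gradient_scheme()]), `image` (the RNifti object for
#'   affine/header reuse), `volume_order` (the applied permutation).
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, tau = 0.0387) {
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("expected a 4D NIfTI volume")
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3L, byrow = TRUE)
  if (length(bvals) != dim(arr)[4] || ncol(bvecs) != dim(arr)[4])
    stop("bval/bvec length (", length(bvals), "/", ncol(bvecs),
         ") does not match ", dim(arr)[4], " volumes")
  is_b0 <- bvals < B0_THRESHOLD
  if (!any(is_b0)) stop("no b = 0 volume found (threshold ",
                        B0_THRESHOLD, " s/mm^2)")
  dirs <- t(bvecs[, !is_b0, drop = FALSE])
  nrm <- sqrt(rowSums(dirs^2))
  if (any(nrm == 0)) stop("zero-norm gradient direction in a DWI volume")
  if (any(abs(nrm - 1) > 1e-3))
    warning("renormalizing gradient directions (max norm deviation ",
            format(max(abs(nrm - 1))), ")")
  dirs <- dirs / nrm
  ord <- c(which(is_b0), which(!is_b0))
  scheme <- gradient_scheme(bval = mean(bvals[!is_b0]), directions = dirs,
                            tau = tau, n_b0 = sum(is_b0))
  list(dwi = arr[, , , ord, drop = FALSE], scheme = scheme, image = img,
       volume_order = ord)
}

#' Write a 4D acquisition as NIfTI plus FSL gradient tables
#'
#' @param dwi 4D array, b0 volumes first.
#' @param scheme a [gradient_scheme()].
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @return the NIfTI path, invisibly.
#' @export
write_dwi <- function(dwi, scheme, prefix) {
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(dwi), nii, datatype = "float")
  bvals <- c(rep(0, scheme$n_b0),
             rep(scheme$bval, nrow(scheme$directions)))
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  bvec <- cbind(matrix(0, 3, scheme$n_b0), t(scheme$directions))
  writeLines(apply(bvec, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")),
    paste0(prefix, ".bvec"))
  invisible(nii)
}

#' Write index maps as one float32 NIfTI per index plus a JSON sidecar
#'
#' @param maps an `index_maps` list from [compute_index_maps()].
#' @param dir output directory (created if missing).
#' @param reference optional RNifti image whose header/affine is copied.
#' @return character vector of written NIfTI paths, invisibly.
#' @export
write_index_maps <- function(maps, dir, reference = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(maps), function(nm) {
    vol <- if (is.null(reference)) RNifti::asNifti(maps[[nm]])
      else RNifti::asNifti(maps[[nm]], reference)
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(vol, p, datatype = "float")
    p
  }, character(1))
  cfg <- attr(maps, "cfg"); scheme <- attr(maps, "scheme")
  jsonlite::write_json(list(
    order = cfg$order, lambda_lb = cfg$lambda_lb,
    bval = scheme$bval, tau = scheme$tau, n_b0 = scheme$n_b0,
    n_directions = nrow(scheme$directions),
    r0_mode = attr(maps, "r0_mode"),
    signal_clip = c(SIGNAL_CLIP_LO, 1), adc_floor = ADC_FLOOR,
    n_degenerate = attr(maps, "n_degenerate"),
    version = as.character(utils::packageVersion("amura"))
  ), file.path(dir, "index_maps.json"), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write a ROI atlas as NIfTI volumes plus a TSV code/name table
#' @param atlas a [roi_atlas()].
#' @param prefix path prefix; writes `<prefix>_labels.nii.gz`,
#'   `<prefix>_skeleton.nii.gz`, `<prefix>_labels.tsv`.
#' @export
write_atlas <- function(atlas, prefix) {
  RNifti::writeNifti(RNifti::asNifti(atlas$labels * 1L),
                     paste0(prefix, "_labels.nii.gz"), datatype = "int16")
  RNifti::writeNifti(RNifti::asNifti(atlas$skeleton * 1L),
                     paste0(prefix, "_skeleton.nii.gz"), datatype = "int16")
  utils::write.table(atlas$table, paste0(prefix, "_labels.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read a ROI atlas written by [write_atlas()]
#' @param prefix the path prefix used when writing.
#' @return a [roi_atlas()].
#' @export
read_atlas <- function(prefix) {
  labels <- round(as.array(RNifti::readNifti(
    paste0(prefix, "_labels.nii.gz"))))
  skel <- as.array(RNifti::readNifti(
    paste0(prefix, "_skeleton.nii.gz"))) != 0
  tab <- utils::read.delim(paste0(prefix, "_labels.tsv"))
  roi_atlas(array(as.integer(labels), dim(labels)), tab, skel)
}
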