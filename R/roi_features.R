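# Skeleton-masked ROI mean extraction and a ROI-level max-statistic
# permutation test for group differences (two one-sided contrasts).

# 48 white-matter tract names in the style of the JHU ICBM-DTI-81 labels
jhu_style_names <- function() {
  unpaired <- c("Middle cerebellar peduncle", "Pontine crossing tract",
                "Genu of corpus callosum", "Body of corpus callosum",
                "Splenium of corpus callosum", "Fornix (column and body)")
  paired <- c("Corticospinal tract", "Medial lemniscus",
              "Inferior cerebellar peduncle", "Superior cerebellar peduncle",
              "Cerebral peduncle", "Anterior limb of internal capsule",
              "Posterior limb of internal capsule",
              "Retrolenticular part of internal capsule",
              "Anterior corona radiata", "Superior corona radiata",
              "Posterior corona radiata", "Posterior thalamic radiation",
              "Sagittal stratum", "External capsule",
              "Cingulum (cingulate gyrus)", "Cingulum (hippocampus)",
              "Fornix / stria terminalis", "Superior longitudinal fasciculus",
              "Superior fronto-occipital fasciculus", "Uncinate fasciculus",
              "Tapetum")
  c(unpaired, as.vector(t(outer(paired, c(" R", " L"), paste0))))
}

#' Synthetic block ROI atlas
#'
#' Partitions a small grid into `n_rois` labelled blocks with a
#' checkerboard skeleton mask, so ROI extraction is testable without an
#' external atlas. ROI names follow the JHU white-matter label style.
#'
#' @param dims grid shape; `prod(dims)` must be divisible by `n_rois`.
#' @param n_rois number of ROIs (default 48).
#' @return a list of class `roi_atlas`: `labels` (integer 3D array),
#'   `table` (data.frame code/name), `skeleton` (logical 3D array).
#' @export
synthetic_atlas <- function(dims = c(12L, 8L, 6L), n_rois = 48L) {
  nvox <- prod(dims)
  if (nvox %% n_rois != 0L)
    stop("grid size ", nvox, " not divisible by ", n_rois, " ROIs")
  per <- nvox / n_rois
  labels <- array(rep(seq_len(n_rois), each = per), dims)
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  skeleton <- array((idx[, 1] + idx[, 2] + idx[, 3]) %% 2L == 0L, dims)
  nm <- if (n_rois == 48L) jhu_style_names() else
    sprintf("ROI %02d", seq_len(n_rois))
  roi_atlas(labels, data.frame(code = seq_len(n_rois), name = nm,
                               stringsAsFactors = FALSE), skeleton)
}

#' Construct a ROI atlas object
#' @param labels integer 3D label volume (0 = background).
#' @param table data.frame with columns `code` and `name`.
#' @param skeleton logical 3D skeleton mask on the same grid.
#' @return an object of class `roi_atlas`.
#' @export
roi_atlas <- function(labels, table, skeleton) {
  if (!all(dim(labels) == dim(skeleton)))
    stop("label and skeleton grids differ")
  if (!all(c("code", "name") %in% names(table)))
    stop("atlas table needs 'code' and 'name' columns")
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, table$code)
  if (length(unknown))
    stop("label codes absent from the atlas table: ",
         paste(unknown, collapse = ", "))
  structure(list(labels = labels, table = table,
                 skeleton = skeleton != 0), class = "roi_atlas")
}

#' Skeleton-masked per-ROI means of an index map
#'
#' Mean over voxels with the ROI's label code, inside the skeleton mask,
#' with a finite map value. Empty ROIs yield NaN with a warning.
#'
#' @param index_map numeric 3D array on the atlas grid.
#' @param atlas a [roi_atlas()].
#' @return named numeric vector, one mean per atlas table row.
#' @export
roi_means <- function(index_map, atlas) {
  stopifnot(inherits(atlas, "roi_atlas"))
  if (!all(dim(index_map) == dim(atlas$labels)))
    stop("index map grid does not match the atlas")
  out <- vapply(atlas$table$code, function(code) {
    sel <- atlas$labels == code & atlas$skeleton & is.finite(index_map)
    if (!any(sel)) return(NaN)
    mean(index_map[sel])
  }, numeric(1))
  names(out) <- atlas$table$name
  if (any(is.nan(out)))
    warning("empty ROI(s): ",
            paste(atlas$table$name[is.nan(out)], collapse = "; "))
  out
}

#' Assemble a subjects-by-ROI feature matrix
#'
#' Subjects with any empty (NaN) ROI are excluded with a logged reason;
#' row order follows the input order of the retained subjects.
#'
#' @param subject_maps named list of 3D index maps (names = subject ids).
#' @param atlas a [roi_atlas()].
#' @return matrix (subjects x ROIs) with an `excluded` attribute naming
#'   dropped subjects.
#' @export
build_feature_matrix <- function(subject_maps, atlas) {
  ids <- names(subject_maps)
  if (is.null(ids) || anyDuplicated(ids))
    stop("subject_maps must be a named list with unique ids")
  rows <- lapply(subject_maps, function(m)
    suppressWarnings(roi_means(m, atlas)))
  keep <- !vapply(rows, function(r) any(is.nan(r)), logical(1))
  if (any(!keep))
    message("excluded subject(s) with empty ROI(s): ",
            paste(ids[!keep], collapse = ", "))
  X <- do.call(rbind, rows[keep])
  rownames(X) <- ids[keep]
  attr(X, "excluded") <- ids[!keep]
  X
}

# vectorized pooled-variance two-sample t statistics; X is n x p,
# a_mat is (n_draws x n) 0/1 membership of group A
pooled_t_matrix <- function(a_mat, X, X2, nA, nB) {
  sA <- a_mat %*% X
  ssA <- a_mat %*% X2
  sB <- matrix(colSums(X), nrow(a_mat), ncol(X), byrow = TRUE) - sA
  ssB <- matrix(colSums(X2), nrow(a_mat), ncol(X), byrow = TRUE) - ssA
  mA <- sA / nA
  mB <- sB / nB
  sp2 <- (ssA - nA * mA^2 + ssB - nB * mB^2) / (nA + nB - 2)
  denom <- sqrt(sp2 * (1 / nA + 1 / nB))
  t <- (mA - mB) / denom
  t[!is.finite(t)] <- 0
  t
}

#' ROI-level permutation group-difference test with maxT correction
#'
#' Two-sample pooled-variance t per ROI; family-wise correction by the
#' maximum statistic over ROIs across label permutations. Both one-sided
#' contrasts (A > B and B > A) are reported. Zero-variance ROIs get
#' statistic 0 and p = 1 with a warning.
#'
#' @param fa rows of group A (subjects x ROIs).
#' @param fb rows of group B on the same ROIs.
#' @param n_perm number of permutations (default 1000, minimum 100).
#' @param seed integer seed.
#' @return data.frame with per-ROI statistic, raw and corrected p-values
#'   for both contrasts (`p_*_a_gt_b`, `p_*_b_gt_a`).
#' @export
permutation_group_test <- function(fa, fb, n_perm = 1000L, seed = 1L) {
  fa <- as.matrix(fa); fb <- as.matrix(fb)
  if (nrow(fa) < 2L || nrow(fb) < 2L)
    stop("each group needs at least 2 subjects")
  if (ncol(fa) != ncol(fb)) stop("groups have different ROI counts")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  X <- rbind(fa, fb)
  X2 <- X^2
  n <- nrow(X); nA <- nrow(fa); nB <- nrow(fb)
  zero_var <- apply(X, 2, stats::var) == 0
  if (any(zero_var))
    warning("zero-variance ROI(s): ",
            paste(which(zero_var), collapse = ", "))
  obs <- drop(pooled_t_matrix(matrix(c(rep(1, nA), rep(0, nB)), 1), X, X2,
                              nA, nB))
  set.seed(seed)
  a_mat <- matrix(0, n_perm, n)
  for (p in seq_len(n_perm))
    a_mat[p, sample.int(n, nA)] <- 1
  tp <- pooled_t_matrix(a_mat, X, X2, nA, nB)
  # one-sided raw and maxT-corrected p-values
  p_raw_ab <- (1 + colSums(tp >= rep(obs, each = n_perm))) / (n_perm + 1)
  p_raw_ba <- (1 + colSums(-tp >= rep(-obs, each = n_perm))) / (n_perm + 1)
  max_ab <- apply(tp, 1, max)
  max_ba <- apply(-tp, 1, max)
  p_cor_ab <- vapply(obs, function(t0) (1 + sum(max_ab >= t0)) /
                       (n_perm + 1), numeric(1))
  p_cor_ba <- vapply(-obs, function(t0) (1 + sum(max_ba >= t0)) /
                       (n_perm + 1), numeric(1))
  one <- function(p) { p[zero_var] <- 1; pmin(p, 1) }
  data.frame(roi = if (!is.null(colnames(X))) colnames(X) else
               sprintf("ROI%02d", seq_len(ncol(X))),
             statistic = ifelse(zero_var, 0, obs),
             p_raw_a_gt_b = one(p_raw_ab),
             p_corr_a_gt_b = one(pmax(p_cor_ab, p_raw_ab)),
             p_raw_b_gt_a = one(p_raw_ba),
             p_corr_b_gt_a = one(pmax(p_cor_ba, p_raw_ba)),
             row.names = NULL)
}
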