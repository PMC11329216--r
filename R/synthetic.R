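# Synthetic data: multi-tensor single-shell phantoms with Rician noise,
# a block ROI atlas, and subject-level cohort feature tables with
# planted group effects emulating amyloid/tau contrasts.

#' Diffusion tensor from eigenvalues and a principal axis
#'
#' Builds a symmetric 3 x 3 tensor with the given eigenvalues, the first
#' eigenvector aligned with `axis` and the remaining two completing an
#' orthonormal triad.
#'
#' @param eigenvalues length-3, mm^2/s, in the order (axis, radial, radial).
#' @param axis principal direction (any nonzero 3-vector; normalized).
#' @return 3 x 3 numeric matrix.
#' @export
tensor_from_axis <- function(eigenvalues, axis = c(0, 0, 1)) {
  stopifnot(length(eigenvalues) == 3L)
  a <- axis / sqrt(sum(axis^2))
  # complete the triad with the least-aligned cardinal axis
  ref <- diag(3)[, which.min(abs(a))]
  b <- ref - sum(ref * a) * a
  b <- b / sqrt(sum(b^2))
  cc <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  V <- cbind(a, b, cc)
  V %*% diag(eigenvalues) %*% t(V)
}

#' One mixture component of a multi-tensor voxel model
#' @param eigenvalues length-3 tensor eigenvalues (mm^2/s).
#' @param axis principal direction.
#' @param fraction volume fraction in the voxel.
#' @return a list usable in `mixture` arguments.
#' @export
tensor_component <- function(eigenvalues, axis = c(0, 0, 1), fraction = 1) {
  list(tensor = tensor_from_axis(eigenvalues, axis), fraction = fraction)
}

#' Simulate the single-shell signal of one multi-tensor voxel
#'
#' Noise-free signal `sum_k f_k exp(-b u' D_k u)` per gradient direction,
#' with unit b = 0 signal. Rician noise is applied as the magnitude of
#' the complex signal plus circular Gaussian noise of standard deviation
#' `1/snr` per channel; `snr = Inf` returns the noise-free signal.
#'
#' @param mixture list of [tensor_component()]s; fractions must sum to 1.
#' @param scheme a [gradient_scheme()].
#' @param snr b0 signal-to-noise ratio (> 0, may be `Inf`).
#' @param seed integer seed (used only when `snr` is finite).
#' @return list with `signal` (per direction) and `b0` (length
#'   `scheme$n_b0`).
#' @export
simulate_voxel_signal <- function(mixture, scheme, snr = Inf, seed = 1L) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  fr <- vapply(mixture, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-12)
    stop("mixture fractions sum to ", sum(fr), ", expected 1")
  if (snr <= 0) stop("snr must be positive")
  u <- scheme$directions
  s <- rep(0, nrow(u))
  for (comp in mixture) {
    q <- rowSums((u %*% comp$tensor) * u)
    s <- s + comp$fraction * exp(-scheme$bval * q)
  }
  b0 <- rep(1, scheme$n_b0)
  if (is.finite(snr)) {
    set.seed(seed)
    sigma <- 1 / snr
    s <- sqrt((s + stats::rnorm(length(s), 0, sigma))^2 +
                stats::rnorm(length(s), 0, sigma)^2)
    b0 <- sqrt((b0 + stats::rnorm(length(b0), 0, sigma))^2 +
                 stats::rnorm(length(b0), 0, sigma)^2)
  }
  list(signal = s, b0 = b0)
}

#' Phantom specification
#'
#' @param dims length-3 grid shape.
#' @param regions list of mixtures (each a list of [tensor_component()]s);
#'   region r occupies the r-th slab of the grid along the first axis.
#' @param scheme a [gradient_scheme()].
#' @param snr b0 signal-to-noise ratio.
#' @param seed integer seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims, regions, scheme, snr = Inf, seed = 1L) {
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive")
  if (length(regions) < 1L) stop("at least one region required")
  if (length(regions) > dims[1])
    stop("more regions than slabs along the first axis")
  structure(list(dims = as.integer(dims), regions = regions,
                 scheme = scheme, snr = snr, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a labelled multi-tensor phantom image
#'
#' Deterministic given the spec seed: every voxel of region r carries the
#' Rician-noised signal of that region's tensor mixture, with a
#' voxel-specific noise stream.
#'
#' @param spec a [phantom_spec()].
#' @return list: `dwi` (4D array, b0 volumes first), `labels` (3D integer
#'   region map), `mask` (logical 3D, all TRUE).
#' @export
generate_phantom_image <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$dims
  nreg <- length(spec$regions)
  scheme <- spec$scheme
  nvol <- scheme$n_b0 + nrow(scheme$directions)
  dwi <- array(0, c(dm, nvol))
  labels <- array(0L, dm)
  # slab boundaries along x
  edges <- round(seq(0, dm[1], length.out = nreg + 1))
  for (r in seq_len(nreg)) {
    xs <- seq(edges[r] + 1L, edges[r + 1L])
    labels[xs, , ] <- r
  }
  set.seed(spec$seed)
  vox_seeds <- sample.int(.Machine$integer.max - 1L, prod(dm))
  k <- 0L
  for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
    k <- k + 1L
    sig <- simulate_voxel_signal(spec$regions[[labels[x, y, z]]], scheme,
                                 snr = spec$snr, seed = vox_seeds[k])
    dwi[x, y, z, ] <- c(sig$b0, sig$signal)
  }
  list(dwi = dwi, labels = labels, mask = array(TRUE, dm))
}

# biomarker ranges consistent with the 980 / 24 pg/mL stratification rules
GROUP_LEVELS <- c("Abeta-/tau-", "Abeta+/tau-", "Abeta+/tau+")
GROUP_SEVERITY <- c("Abeta-/tau-" = 0, "Abeta+/tau-" = 0.5,
                    "Abeta+/tau+" = 1)

sample_biomarkers <- function(group, n) {
  abeta <- switch(substr(group, 1, 6),
                  "Abeta-" = stats::runif(n, 981, 1800),
                  "Abeta+" = stats::runif(n, 400, 980))
  taupos <- grepl("tau\\+$", group)
  tau <- if (taupos) stats::runif(n, 24, 60) else stats::runif(n, 8, 23.9)
  data.frame(abeta = abeta, tau = tau)
}

#' Cohort specification
#'
#' @param n_per_group named or ordered counts for the three groups
#'   (Abeta-/tau-, Abeta+/tau-, Abeta+/tau+); use 0 to omit a group.
#' @param n_rois number of ROI features (default 48).
#' @param planted_rois integer indices of ROIs carrying a group effect.
#' @param effect_size standardized mean difference between the -/- and
#'   +/+ groups in each planted ROI.
#' @param roi_correlation exchangeable within-subject ROI correlation
#'   (default 0.3).
#' @param direction sign of the planted effect in positive groups: -1 for
#'   restriction/FA-like indices (decrease with pathology), +1 for
#'   MD-like.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(60L, 60L, 60L), n_rois = 48L,
                        planted_rois = integer(0), effect_size = 0,
                        roi_correlation = 0.3, direction = -1, seed = 1L) {
  if (length(n_per_group) != 3L) stop("three group counts required")
  if (any(n_per_group > 0 & n_per_group < 2L))
    stop("groups need at least 2 subjects for cross-validation")
  if (any(planted_rois < 1L | planted_rois > n_rois))
    stop("planted_rois out of range")
  if (effect_size < 0) stop("effect_size must be non-negative")
  if (abs(roi_correlation) >= 1) stop("|roi_correlation| must be < 1")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_rois = as.integer(n_rois),
                 planted_rois = as.integer(planted_rois),
                 effect_size = effect_size,
                 roi_correlation = roi_correlation,
                 direction = sign(direction),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic ROI-feature cohort with planted group effects
#'
#' Features are drawn from a unit-variance multivariate normal with
#' exchangeable correlation; planted ROIs receive a mean shift of
#' `effect_size * direction * severity` with severity 0 / 0.5 / 1 for the
#' -/-, +/- and +/+ groups. CSF biomarker values are sampled on the
#' correct side of the 980 (amyloid) and 24 (tau) pg/mL thresholds for
#' each label.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort`: `features` (N x n_rois),
#'   `labels` (factor), `biomarkers` (data.frame abeta/tau in pg/mL),
#'   `truth` (planted ROI indices), `subject_id`.
#' @export
generate_cohort_features <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- sum(spec$n_per_group)
  labels <- factor(rep(GROUP_LEVELS, spec$n_per_group),
                   levels = GROUP_LEVELS[spec$n_per_group > 0])
  rho <- spec$roi_correlation
  # exchangeable correlation: shared factor + independent residual
  z <- stats::rnorm(n)
  eps <- matrix(stats::rnorm(n * spec$n_rois), n, spec$n_rois)
  feats <- sqrt(abs(rho)) * sign(rho) * z + sqrt(1 - abs(rho)) * eps
  sev <- GROUP_SEVERITY[as.character(labels)]
  for (j in spec$planted_rois)
    feats[, j] <- feats[, j] + spec$effect_size * spec$direction * sev
  colnames(feats) <- sprintf("ROI%02d", seq_len(spec$n_rois))
  bio <- do.call(rbind, lapply(levels(labels), function(g)
    sample_biomarkers(g, sum(labels == g))))
  ord <- order(order(as.integer(labels)))  # biomarkers back to subject order
  bio <- bio[ord, , drop = FALSE]
  rownames(bio) <- NULL
  structure(list(features = feats, labels = labels, biomarkers = bio,
                 truth = spec$planted_rois,
                 subject_id = sprintf("sub-%03d", seq_len(n))),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to CSV plus a JSON truth file
#' @param cohort a `synthetic_cohort`.
#' @param csv_path output CSV (one row per subject).
#' @param truth_path output JSON recording the planted ROI indices.
#' @export
write_cohort <- function(cohort, csv_path, truth_path = NULL) {
  df <- data.frame(id = cohort$subject_id, group = cohort$labels,
                   abeta = cohort$biomarkers$abeta,
                   tau = cohort$biomarkers$tau,
                   cohort$features, check.names = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(truth_path))
    jsonlite::write_json(list(planted_rois = cohort$truth), truth_path,
                         auto_unbox = FALSE)
  invisible(csv_path)
}

#' Read a cohort CSV written by [write_cohort()]
#' @param csv_path input CSV.
#' @return a `synthetic_cohort` (truth empty unless supplied separately).
#' @export
read_cohort <- function(csv_path) {
  df <- utils::read.csv(csv_path, check.names = FALSE)
  fcols <- setdiff(names(df), c("id", "group", "abeta", "tau"))
  structure(list(features = as.matrix(df[, fcols, drop = FALSE]),
                 labels = factor(df$group),
                 biomarkers = df[, c("abeta", "tau")],
                 truth = integer(0), subject_id = df$id),
            class = "synthetic_cohort")
}
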