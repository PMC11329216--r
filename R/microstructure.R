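# Single-shell microstructural indices: ADC inversion, the three
# spherical-harmonic restriction indices (RTOP/RTAP/RTPP), the diffusion
# tensor fit and its closed-form counterparts, MD and FA.

# numerical floors (degenerate voxels): normalized signal is clipped to
# [SIGNAL_CLIP_LO, 1] before the log; ADC and tensor eigenvalues are
# floored at ADC_FLOOR mm^2/s so D^(-3/2) and 1/D stay finite.
SIGNAL_CLIP_LO <- 1e-6
ADC_FLOOR <- 1e-7

#' Single-shell acquisition geometry
#'
#' Holds the b-value (s/mm^2), the unit gradient directions of the shell,
#' the diffusion time tau (seconds) and the number of b=0 volumes. The
#' shell wave number q0 is implied by `b = 4 pi^2 tau q0^2` and never
#' stored.
#'
#' @param bval shell b-value in s/mm^2 (> 0).
#' @param directions n x 3 matrix of unit gradient directions.
#' @param tau diffusion time in seconds (default 0.0387, i.e. 38.7 ms).
#' @param n_b0 number of b = 0 volumes acquired (default 1).
#' @return an object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(bval, directions, tau = 0.0387, n_b0 = 1L) {
  if (bval <= 0) stop("bval must be positive")
  if (tau <= 0) stop("tau must be positive")
  directions <- if (is.null(dim(directions)))
    matrix(directions, ncol = 3L) else directions
  check_directions(directions, tol = 1e-6)
  structure(list(bval = bval, directions = directions,
                 tau = tau, n_b0 = as.integer(n_b0)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("Gradient scheme: b =", x$bval, "s/mm^2,",
      nrow(x$directions), "directions,",
      x$n_b0, "b0 volume(s), tau =", x$tau, "s\n")
  invisible(x)
}

#' SH fitting configuration
#' @param order even SH order (default 6).
#' @param lambda_lb Laplace-Beltrami regularization weight (default 0.001).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(order = 6L, lambda_lb = 0.001) {
  if (order %% 2L != 0L || order < 0L) stop("order must be even and >= 0")
  if (lambda_lb < 0) stop("lambda_lb must be non-negative")
  structure(list(order = as.integer(order), lambda_lb = lambda_lb),
            class = "fit_config")
}

#' Apparent diffusion coefficient from normalized single-shell signal
#'
#' Inverts the monoexponential attenuation `E = exp(-b D)` per direction.
#' The signal is clipped to `[1e-6, 1]` before the logarithm and the
#' resulting ADC floored at 1e-7 mm^2/s; the number of floored values is
#' attached as attribute `n_floored`.
#'
#' @param signal normalized signal E (per direction, b0-normalized).
#' @param scheme a [gradient_scheme()].
#' @return numeric ADC vector (mm^2/s) with attribute `n_floored`.
#' @export
adc_from_signal <- function(signal, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  e <- pmin(pmax(signal, SIGNAL_CLIP_LO), 1)
  d <- -log(e) / scheme$bval
  n_floored <- sum(d < ADC_FLOOR)
  d <- pmax(d, ADC_FLOOR)
  attr(d, "n_floored") <- n_floored
  d
}

# Shared SH stage for the three restriction indices: fits D, 1/D and
# D^(-3/2) on the acquisition directions and locates the maximum-diffusion
# axis r0. `r0_mode` = "sh" (argmax of the SH-fitted ADC, default) or a
# unit vector supplied by the caller (e.g. the tensor eigenvector).
amura_fits <- function(adc, scheme, cfg = fit_config(),
                       grid = sphere_grid_symmetric(), r0 = NULL) {
  if (!all(is.finite(adc)) || any(adc <= 0))
    stop("ADC samples must be positive and finite (apply adc_from_signal)")
  dirs <- scheme$directions
  f_d <- fit_sh(adc, dirs, cfg$order, cfg$lambda_lb)
  f_inv <- fit_sh(1 / adc, dirs, cfg$order, cfg$lambda_lb)
  f_pow <- fit_sh(adc^(-1.5), dirs, cfg$order, cfg$lambda_lb)
  if (!all(is.finite(f_pow$coeffs)))
    stop("non-finite D^(-3/2) SH fit")
  if (is.null(r0)) r0 <- max_direction_refined(f_d, grid)
  list(d = f_d, inv = f_inv, pow = f_pow, r0 = r0)
}

#' Return-to-origin probability (SH formulation)
#'
#' `RTOP = C00 { D^(-3/2) } / ((4 pi)^2 tau^(3/2))` with C00 the degree-0
#' coefficient of the orthonormal SH fit of D^(-3/2). With tau in seconds
#' and D in mm^2/s the result is in mm^-3.
#'
#' @param adc per-direction ADC samples (mm^2/s).
#' @param scheme a [gradient_scheme()].
#' @param cfg a [fit_config()].
#' @return RTOP in mm^-3.
#' @export
amura_rtop <- function(adc, scheme, cfg = fit_config()) {
  f <- amura_fits(adc, scheme, cfg)
  f$pow$coeffs[1] / ((4 * pi)^2 * scheme$tau^1.5)
}

#' Return-to-axis probability (SH formulation)
#'
#' Funk-Radon transform of 1/D evaluated at the maximum-diffusion axis
#' r0, scaled by `1 / (8 pi^2 tau)`; units mm^-2.
#'
#' @inheritParams amura_rtop
#' @param r0 optional fixed axis; by default the argmax of the SH-fitted
#'   ADC over a 724-point symmetric grid.
#' @return RTAP in mm^-2.
#' @export
amura_rtap <- function(adc, scheme, cfg = fit_config(), r0 = NULL) {
  f <- amura_fits(adc, scheme, cfg, r0 = r0)
  frt <- funk_radon_sh(f$inv)
  eval_sh(frt, f$r0) / (8 * pi^2 * scheme$tau)
}

#' Return-to-plane probability (SH formulation)
#'
#' `RTPP = (4 pi tau D_SH(r0))^(-1/2)` with D_SH the SH-regularized ADC;
#' units mm^-1.
#'
#' @inheritParams amura_rtap
#' @return RTPP in mm^-1.
#' @export
amura_rtpp <- function(adc, scheme, cfg = fit_config(), r0 = NULL) {
  f <- amura_fits(adc, scheme, cfg, r0 = r0)
  d0 <- eval_sh(f$d, f$r0)
  if (d0 <= 0) stop("SH-regularized ADC non-positive at r0")
  1 / sqrt(4 * pi * scheme$tau * d0)
}

#' Weighted log-linear diffusion tensor fit
#'
#' Single-pass weighted least squares on the log-signal with
#' signal-squared weights; eigenvalues are floored at 1e-7 mm^2/s and
#' sorted descending.
#'
#' @param signal normalized signal E per direction.
#' @param scheme a [gradient_scheme()].
#' @return a list with class `tensor_fit`: `eigenvalues` (descending,
#'   mm^2/s), `eigenvectors` (columns, orthonormal), `tensor` (3 x 3).
#' @export
fit_tensor <- function(signal, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  u <- scheme$directions
  if (nrow(u) < 6L) stop("tensor fit needs at least 6 directions, got ",
                         nrow(u))
  e <- pmin(pmax(signal, SIGNAL_CLIP_LO), 1)
  X <- scheme$bval * cbind(u[, 1]^2, u[, 2]^2, u[, 3]^2,
                           2 * u[, 1] * u[, 2],
                           2 * u[, 1] * u[, 3],
                           2 * u[, 2] * u[, 3])
  y <- -log(e)
  w <- e^2
  beta <- tryCatch(solve(crossprod(X, X * w), crossprod(X, w * y)),
                   error = function(err)
                     stop("tensor design is rank deficient: need >= 6 ",
                          "non-collinear directions"))
  D <- matrix(c(beta[1], beta[4], beta[5],
                beta[4], beta[2], beta[6],
                beta[5], beta[6], beta[3]), 3, 3)
  eg <- eigen(D, symmetric = TRUE)
  structure(list(eigenvalues = pmax(eg$values, ADC_FLOOR),
                 eigenvectors = eg$vectors, tensor = D),
            class = "tensor_fit")
}

#' Closed-form tensor-based descriptors
#'
#' Gaussian-propagator restriction indices plus MD and FA:
#' `RTOP = (4 pi tau)^(-3/2) (l1 l2 l3)^(-1/2)`,
#' `RTAP = (4 pi tau)^(-1) (l2 l3)^(-1/2)`,
#' `RTPP = (4 pi tau)^(-1/2) l1^(-1/2)`; RTAP * RTPP = RTOP identically.
#'
#' @param tensor a `tensor_fit`.
#' @param scheme a [gradient_scheme()] (only tau is used).
#' @return named numeric vector: rtop_dti, rtap_dti, rtpp_dti, md, fa.
#' @export
dti_indices <- function(tensor, scheme) {
  stopifnot(inherits(tensor, "tensor_fit"))
  l <- tensor$eigenvalues
  if (any(l <= 0)) stop("non-positive eigenvalue after flooring")
  tau <- scheme$tau
  md <- mean(l)
  fa <- sqrt(1.5 * sum((l - md)^2) / sum(l^2))
  c(rtop_dti = (4 * pi * tau)^-1.5 / sqrt(prod(l)),
    rtap_dti = (4 * pi * tau)^-1 / sqrt(l[2] * l[3]),
    rtpp_dti = (4 * pi * tau)^-0.5 / sqrt(l[1]),
    md = md, fa = fa)
}

#' Voxelwise microstructural index maps
#'
#' Normalizes each voxel by its mean b = 0 signal, then computes the
#' three SH restriction indices, their tensor closed forms, MD and FA.
#' Voxels outside the mask are NaN; all-zero voxels inside the mask are
#' flagged, set to NaN and counted in the `n_degenerate` attribute.
#'
#' @param dwi 4D array: the first `scheme$n_b0` volumes are b = 0, the
#'   remaining ones follow `scheme$directions` in order.
#' @param scheme a [gradient_scheme()].
#' @param mask logical 3D array matching the spatial grid.
#' @param cfg a [fit_config()].
#' @param r0_mode "sh" (argmax of the SH-fitted ADC, default) or
#'   "tensor" (principal eigenvector of the tensor fit).
#' @param verbose log per-slab progress to stderr.
#' @return a named list of eight 3D arrays (class `index_maps`):
#'   rtop_amura, rtap_amura, rtpp_amura, rtop_dti, rtap_dti, rtpp_dti,
#'   md, fa; attributes record cfg, scheme, r0_mode and degenerate count.
#' @export
compute_index_maps <- function(dwi, scheme, mask, cfg = fit_config(),
                               r0_mode = c("sh", "tensor"),
                               verbose = FALSE) {
  r0_mode <- match.arg(r0_mode)
  dm <- dim(dwi)
  if (length(dm) != 4L) stop("dwi must be a 4D array")
  if (!all(dm[1:3] == dim(mask))) stop("mask grid does not match dwi")
  nvol <- scheme$n_b0 + nrow(scheme$directions)
  if (dm[4] != nvol)
    stop("scheme implies ", nvol, " volumes but dwi has ", dm[4])
  if (scheme$n_b0 < 1L) stop("at least one b0 volume is required")

  names8 <- c("rtop_amura", "rtap_amura", "rtpp_amura",
              "rtop_dti", "rtap_dti", "rtpp_dti", "md", "fa")
  maps <- lapply(names8, function(nm) array(NaN, dm[1:3]))
  names(maps) <- names8

  # precompute shared SH solve operators and the search-grid basis
  dirs <- scheme$directions
  B <- real_sh_basis(dirs, cfg$order)
  idx <- sh_index_table(cfg$order)
  pen <- idx$l^2 * (idx$l + 1)^2
  solve_op <- solve(crossprod(B) + cfg$lambda_lb * diag(pen, ncol(B)), t(B))
  grid <- sphere_grid_symmetric()
  Bg <- real_sh_basis(grid, cfg$order)
  frt_fac <- {
    f <- 2 * pi * legendre_at_zero(unique(idx$l))
    names(f) <- as.character(unique(idx$l))
    f[as.character(idx$l)]
  }
  tau <- scheme$tau
  b0_idx <- seq_len(scheme$n_b0)
  vox <- which(mask, arr.ind = TRUE)
  n_degenerate <- 0L
  dwi_mat <- matrix(dwi, prod(dm[1:3]), dm[4])
  lin <- which(mask)
  for (i in seq_along(lin)) {
    s <- dwi_mat[lin[i], ]
    s0 <- mean(s[b0_idx])
    if (!is.finite(s0) || s0 <= 0 || all(s == 0)) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    e <- s[-b0_idx] / s0
    adc <- adc_from_signal(e, scheme)
    tf <- fit_tensor(e, scheme)
    dti <- dti_indices(tf, scheme)
    c_d <- drop(solve_op %*% adc)
    c_inv <- drop(solve_op %*% (1 / adc))
    c_pow <- drop(solve_op %*% adc^(-1.5))
    r0 <- if (r0_mode == "tensor") {
      canonical_sign(tf$eigenvectors[, 1])
    } else {
      cap <- polar_cap(canonical_sign(grid[which.max(Bg %*% c_d), ]),
                       0.12, 8L, 16L)
      canonical_sign(cap[which.max(real_sh_basis(cap, cfg$order) %*%
                                     c_d), ])
    }
    br0 <- real_sh_basis(matrix(r0, 1), cfg$order)
    d_r0 <- drop(br0 %*% c_d)
    rtpp <- if (d_r0 > 0) 1 / sqrt(4 * pi * tau * d_r0) else NaN
    rtap <- drop(br0 %*% (c_inv * frt_fac)) / (8 * pi^2 * tau)
    rtop <- c_pow[1] / ((4 * pi)^2 * tau^1.5)
    v <- vox[i, ]
    maps$rtop_amura[v[1], v[2], v[3]] <- rtop
    maps$rtap_amura[v[1], v[2], v[3]] <- rtap
    maps$rtpp_amura[v[1], v[2], v[3]] <- rtpp
    maps$rtop_dti[v[1], v[2], v[3]] <- dti["rtop_dti"]
    maps$rtap_dti[v[1], v[2], v[3]] <- dti["rtap_dti"]
    maps$rtpp_dti[v[1], v[2], v[3]] <- dti["rtpp_dti"]
    maps$md[v[1], v[2], v[3]] <- dti["md"]
    maps$fa[v[1], v[2], v[3]] <- dti["fa"]
    if (verbose && i %% 500L == 0L)
      message("  processed ", i, "/", length(lin), " voxels")
  }
  if (n_degenerate > 0L)
    message(n_degenerate,
            " degenerate voxel(s) inside the mask set to NaN")
  structure(maps, class = "index_maps", cfg = cfg,
            scheme = scheme, r0_mode = r0_mode,
            n_degenerate = n_degenerate)
}
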