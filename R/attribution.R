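# Model-agnostic feature attributions for the selected fold's validation
# subjects: Shapley values via the weighted-linear-regression (KernelSHAP)
# scheme, local surrogate explanations (LIME) for tabular features, and
# cross-method top-k agreement.

# sample coalition membership vectors: sizes drawn from the Shapley
# kernel size distribution p(s) ~ (M-1)/(s(M-s)), subsets uniform within
# size; sizes 1 and M-1 are fully enumerated first.
sample_coalitions <- function(M, nsamples) {
  Z <- matrix(FALSE, nsamples, M)
  r <- 1L
  for (j in seq_len(M)) { Z[r, j] <- TRUE; r <- r + 1L }
  for (j in seq_len(M)) { Z[r, ] <- TRUE; Z[r, j] <- FALSE; r <- r + 1L }
  if (r <= nsamples && M > 3L) {
    sizes <- 2:(M - 2L)
    pr <- (M - 1) / (sizes * (M - sizes))
    draw <- sample(sizes, nsamples - r + 1L, replace = TRUE,
                   prob = pr / sum(pr))
    for (i in seq_along(draw)) {
      Z[r, sample.int(M, draw[i])] <- TRUE
      r <- r + 1L
    }
  }
  Z[seq_len(r - 1L), , drop = FALSE]
}

shapley_kernel_weight <- function(M, s) {
  (M - 1) / (choose(M, s) * s * (M - s))
}

#' KernelSHAP feature attributions
#'
#' Shapley-value estimates by weighted linear regression over sampled
#' feature coalitions. The value of a coalition is the mean model score
#' over the background set with the out-of-coalition features replaced by
#' background values. Local accuracy (attributions sum to the model score
#' minus the background mean score) holds by construction.
#'
#' @param f vectorized model score function: matrix rows -> numeric.
#' @param background matrix of reference rows (e.g. the training fold).
#' @param X_explain matrix of rows to explain.
#' @param nsamples number of coalitions (default 2 * M + 2048).
#' @param seed integer seed for coalition sampling.
#' @return matrix (n_explain x M) of signed attributions, class
#'   `attribution_matrix`, with attributes `method`, `base_value`,
#'   `scores`, `seed`.
#' @export
kernel_shap <- function(f, background, X_explain,
                        nsamples = NULL, seed = 1L) {
  background <- as.matrix(background)
  X_explain <- if (is.null(dim(X_explain))) matrix(X_explain, nrow = 1)
    else as.matrix(X_explain)
  M <- ncol(background)
  if (ncol(X_explain) != M) stop("feature count mismatch")
  if (nrow(background) < 1L) stop("empty background")
  if (all(apply(background, 2, stats::var) == 0))
    warning("background has zero variance in every feature; ",
            "attributions of a constant model are identically 0")
  if (is.null(nsamples)) nsamples <- 2L * M + 2048L
  set.seed(seed)
  Z <- sample_coalitions(M, nsamples)
  C <- nrow(Z)
  w <- shapley_kernel_weight(M, rowSums(Z))
  base <- mean(f(background))
  fx <- f(X_explain)
  nb <- nrow(background)
  # coalition design with the sum constraint eliminated via feature M
  X2 <- sweep(Z[, -M, drop = FALSE], 1, Z[, M])
  XtWX <- crossprod(X2 * w, X2) + diag(1e-10, M - 1L)
  mask <- Z[rep(seq_len(C), each = nb), , drop = FALSE]
  Bg <- background[rep(seq_len(nb), C), , drop = FALSE]
  phi <- matrix(0, nrow(X_explain), M)
  for (i in seq_len(nrow(X_explain))) {
    Synth <- Bg
    Xrep <- matrix(X_explain[i, ], nrow(Synth), M, byrow = TRUE)
    Synth[mask] <- Xrep[mask]
    v <- colMeans(matrix(f(Synth), nb, C))
    y <- drop(v) - base - Z[, M] * (fx[i] - base)
    ph <- drop(solve(XtWX, crossprod(X2 * w, y)))
    phi[i, ] <- c(ph, (fx[i] - base) - sum(ph))
  }
  colnames(phi) <- colnames(background)
  structure(phi, class = c("attribution_matrix", "matrix"),
            method = "shap", base_value = base, scores = fx, seed = seed)
}

#' LIME explanations for tabular features
#'
#' For each row: perturbed samples are drawn from independent Gaussians
#' with the training means and standard deviations, weighted by an
#' exponential kernel on the Euclidean distance to the explained row in
#' standardized space, and a weighted linear regression of the model
#' scores on the standardized features is fitted; its coefficients are
#' the attributions. Discretization is disabled (continuous features).
#'
#' @param f vectorized model score function.
#' @param training matrix providing the perturbation statistics.
#' @param X_explain matrix of rows to explain.
#' @param n_samples perturbed samples per row (default 5000); must be at
#'   least the number of features.
#' @param kernel_width exponential kernel width (default 0.75 * sqrt(M)).
#' @param seed integer seed.
#' @return `attribution_matrix` (n_explain x M) of surrogate
#'   coefficients on the standardized feature scale.
#' @export
lime_tabular <- function(f, training, X_explain, n_samples = 5000L,
                         kernel_width = NULL, seed = 1L) {
  training <- as.matrix(training)
  X_explain <- if (is.null(dim(X_explain))) matrix(X_explain, nrow = 1)
    else as.matrix(X_explain)
  M <- ncol(training)
  if (n_samples < M)
    stop("n_samples (", n_samples, ") must be >= number of features (",
         M, ")")
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(M)
  mu <- colMeans(training)
  sdv <- apply(training, 2, stats::sd)
  sdv[sdv == 0] <- 1
  set.seed(seed)
  phi <- matrix(0, nrow(X_explain), M)
  for (i in seq_len(nrow(X_explain))) {
    Zstd <- matrix(stats::rnorm(n_samples * M), n_samples, M)
    S <- sweep(sweep(Zstd, 2, sdv, `*`), 2, mu, `+`)
    x_std <- (X_explain[i, ] - mu) / sdv
    d2 <- rowSums(sweep(Zstd, 2, x_std)^2)
    w <- exp(-d2 / kernel_width^2)
    y <- f(S)
    Xd <- cbind(1, Zstd)
    beta <- solve(crossprod(Xd * w, Xd) + diag(1e-10, M + 1L),
                  crossprod(Xd * w, y))
    phi[i, ] <- beta[-1L]
  }
  colnames(phi) <- colnames(training)
  structure(phi, class = c("attribution_matrix", "matrix"),
            method = "lime", base_value = NA_real_,
            scores = f(X_explain), seed = seed)
}

#' Mean attribution over the explained subjects
#' @param m an `attribution_matrix`.
#' @return signed column-mean vector.
#' @export
mean_attribution <- function(m) {
  if (nrow(m) < 1L) stop("empty attribution matrix")
  colMeans(unclass(m))
}

#' Mean absolute attribution over the explained subjects
#'
#' The magnitude summary used for importance ranking (the standard
#' SHAP-summary ordering): for a class-balanced validation set the
#' signed means of a discriminative feature cancel across the two
#' classes, so impact is ranked on the mean magnitude while the signed
#' means are still reported alongside.
#'
#' @param m an `attribution_matrix`.
#' @return non-negative column-mean-of-absolute-values vector.
#' @export
mean_abs_attribution <- function(m) {
  if (nrow(m) < 1L) stop("empty attribution matrix")
  colMeans(abs(unclass(m)))
}

#' Top-k features by absolute mean attribution
#'
#' Ranked by descending magnitude; ties broken alphabetically by name.
#' Signed values are retained in the `values` attribute.
#'
#' @param mean_vec named mean-attribution vector.
#' @param roi_names feature names (default `names(mean_vec)`).
#' @param k list length (default 5).
#' @return character vector of k names with attribute `values`.
#' @export
top_k <- function(mean_vec, roi_names = names(mean_vec), k = 5L) {
  if (k > length(mean_vec)) stop("k exceeds the number of features")
  if (is.null(roi_names)) roi_names <- sprintf("F%02d", seq_along(mean_vec))
  ord <- order(-abs(mean_vec), roi_names)
  sel <- ord[seq_len(k)]
  structure(roi_names[sel], values = unname(mean_vec[sel]))
}

#' Agreement between two top-k rankings
#'
#' @param top_a,top_b character vectors of length k (no duplicates).
#' @param k list length (default 5).
#' @return list: `overlap` (set intersection size), `jaccard`
#'   (overlap / (2k - overlap)), `top2_match` (whether the first two
#'   names coincide in order).
#' @export
method_agreement <- function(top_a, top_b, k = 5L) {
  if (length(top_a) != k || length(top_b) != k)
    stop("both lists must have length ", k)
  if (anyDuplicated(top_a) || anyDuplicated(top_b))
    stop("duplicate names within a top-k list")
  ov <- length(intersect(top_a, top_b))
  list(overlap = ov, jaccard = ov / (2 * k - ov),
       top2_match = identical(top_a[1:2], top_b[1:2]))
}

#' Attribution report for one model: SHAP vs LIME
#'
#' Runs both explainers on the same subjects, summarizes mean
#' attributions, top-k rankings and their agreement.
#'
#' @param f vectorized model score function.
#' @param background reference rows for the SHAP background and the LIME
#'   perturbation statistics; typically the control-group training rows
#'   of the selected fold, so attributions are measured relative to the
#'   healthy reference.
#' @param X_explain validation-fold rows.
#' @param k ranking depth (default 5).
#' @param seed integer seed for both explainers.
#' @param shap_nsamples,lime_n_samples sampling budgets.
#' @return list of class `attribution_report`: `shap`, `lime`
#'   (matrices), `mean_shap`, `mean_lime`, `top_shap`, `top_lime`,
#'   `agreement`, `seed`.
#' @export
attribution_report <- function(f, background, X_explain, k = 5L,
                               seed = 1L, shap_nsamples = NULL,
                               lime_n_samples = 5000L) {
  sh <- kernel_shap(f, background, X_explain, nsamples = shap_nsamples,
                    seed = seed)
  lm_ <- lime_tabular(f, background, X_explain, n_samples = lime_n_samples,
                      seed = seed)
  ms <- mean_attribution(sh); ml <- mean_attribution(lm_)
  ts <- top_k(mean_abs_attribution(sh), k = k)
  tl <- top_k(mean_abs_attribution(lm_), k = k)
  structure(list(shap = sh, lime = lm_, mean_shap = ms, mean_lime = ml,
                 mean_abs_shap = mean_abs_attribution(sh),
                 mean_abs_lime = mean_abs_attribution(lm_),
                 top_shap = ts, top_lime = tl,
                 agreement = method_agreement(ts, tl, k), k = k,
                 seed = seed,
                 background = sprintf("%d training rows", nrow(background))),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat("Attribution report (k =", x$k, ")\n")
  cat("  SHAP top:", paste(x$top_shap, collapse = ", "), "\n")
  cat("  LIME top:", paste(x$top_lime, collapse = ", "), "\n")
  cat("  overlap:", x$agreement$overlap, " Jaccard:",
      round(x$agreement$jaccard, 3), "\n")
  invisible(x)
}

#' Serialize an attribution report to JSON
#' @param report an `attribution_report`.
#' @param path output JSON file.
#' @export
write_attribution_report <- function(report, path) {
  jsonlite::write_json(list(
    method = c("shap", "lime"),
    mean_shap = as.list(report$mean_shap),
    mean_lime = as.list(report$mean_lime),
    mean_abs_shap = as.list(report$mean_abs_shap),
    mean_abs_lime = as.list(report$mean_abs_lime),
    top_shap = as.character(report$top_shap),
    top_lime = as.character(report$top_lime),
    overlap = report$agreement$overlap,
    jaccard = report$agreement$jaccard,
    top2_match = report$agreement$top2_match,
    seed = report$seed, background = report$background
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
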