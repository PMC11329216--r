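# CSF-biomarker stratification and stratified k-fold SVM classification
# with the accuracy / precision / sensitivity / specificity metric set.

ABETA_POSITIVE_MAX <- 980  # pg/mL, amyloid-positive iff <= this
TAU_POSITIVE_MIN <- 24     # pg/mL, tau-positive iff >= this

#' Stratify a subject by CSF amyloid-beta and tau concentrations
#'
#' Amyloid-positive iff abeta <= 980 pg/mL (inclusive); tau-positive iff
#' tau >= 24 pg/mL (inclusive). The Abeta-/tau+ combination is labelled
#' but excluded from the two classification tasks; missing values give
#' "unknown".
#'
#' @param abeta amyloid-beta concentration, pg/mL (vectorized).
#' @param tau tau concentration, pg/mL.
#' @return character vector of labels: "Abeta-/tau-", "Abeta+/tau-",
#'   "Abeta+/tau+", "Abeta-/tau+" or "unknown".
#' @export
stratify_subject <- function(abeta, tau) {
  out <- rep("unknown", length(abeta))
  ok <- !is.na(abeta) & !is.na(tau)
  ab <- abeta[ok] <= ABETA_POSITIVE_MAX
  tp <- tau[ok] >= TAU_POSITIVE_MIN
  out[ok] <- paste0(ifelse(ab, "Abeta+", "Abeta-"),
                    ifelse(tp, "/tau+", "/tau-"))
  out
}

#' SVM configuration
#' @param kernel one of "linear", "polynomial", "rbf", "sigmoid".
#' @param C regularization cost (default 0.4).
#' @param k_folds folds for stratified cross-validation (default 10).
#' @param seed fold-assignment seed (default 20240717).
#' @return an object of class `svm_config`.
#' @export
svm_config <- function(kernel = "linear", C = 0.4, k_folds = 10L,
                       seed = 20240717L) {
  kernel <- match.arg(kernel, c("linear", "polynomial", "rbf", "sigmoid"))
  if (C <= 0) stop("C must be positive")
  structure(list(kernel = kernel, C = C, k_folds = as.integer(k_folds),
                 seed = as.integer(seed)), class = "svm_config")
}

# e1071 kernel name mapping
e1071_kernel <- function(kernel) {
  switch(kernel, rbf = "radial", kernel)
}

#' Stratified fold assignment
#'
#' Shuffles each class independently and deals subjects round-robin, so
#' per-fold class counts differ by at most one from exact stratification.
#'
#' @param y factor of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer fold id per subject (1..k).
#' @export
make_stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  if (any(table(y) < k))
    stop("smallest class has fewer members than k = ", k,
         "; use a smaller k")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

binary_metrics <- function(truth_pos, pred_pos) {
  tp <- sum(truth_pos & pred_pos); tn <- sum(!truth_pos & !pred_pos)
  fp <- sum(!truth_pos & pred_pos); fn <- sum(truth_pos & !pred_pos)
  c(accuracy = (tp + tn) / length(truth_pos),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Stratified k-fold cross-validated SVM
#'
#' Features are standardized with training-fold statistics only; one SVM
#' is fitted per fold and evaluated on its validation fold. The positive
#' class for sensitivity/specificity is the biomarker-positive
#' (pathological) group.
#'
#' @param X feature matrix (subjects x features).
#' @param y two-level factor of group labels.
#' @param cfg an [svm_config()].
#' @param positive label of the positive class; by default the level
#'   that is not "Abeta-/tau-" (or the second level).
#' @return list of class `cv_result`: `folds` (per-fold metric
#'   data.frame), `mean`, `sd`, `models`, `val_indices`, `scalers`,
#'   `config`, `positive`.
#' @export
cross_validate_svm <- function(X, y, cfg = svm_config(), positive = NULL) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("y must have exactly 2 classes")
  if (is.null(positive)) {
    positive <- setdiff(levels(y), "Abeta-/tau-")
    positive <- if (length(positive) == 1L) positive else levels(y)[2L]
  }
  ybin <- factor(ifelse(y == positive, "pos", "neg"),
                 levels = c("neg", "pos"))
  fold <- make_stratified_folds(ybin, cfg$k_folds, cfg$seed)
  metrics <- models <- val_idx <- scalers <- vector("list", cfg$k_folds)
  for (f in seq_len(cfg$k_folds)) {
    tr <- fold != f; va <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- scale(X[tr, , drop = FALSE], mu, sdv)
    Zva <- scale(X[va, , drop = FALSE], mu, sdv)
    m <- e1071::svm(Ztr, ybin[tr], kernel = e1071_kernel(cfg$kernel),
                    cost = cfg$C, scale = FALSE)
    pred <- stats::predict(m, Zva)
    metrics[[f]] <- binary_metrics(ybin[va] == "pos", pred == "pos")
    models[[f]] <- m
    val_idx[[f]] <- which(va)
    scalers[[f]] <- list(center = mu, scale = sdv)
  }
  tab <- do.call(rbind, metrics)
  structure(list(folds = data.frame(fold = seq_len(cfg$k_folds), tab),
                 mean = colMeans(tab, na.rm = TRUE),
                 sd = apply(tab, 2, stats::sd, na.rm = TRUE),
                 models = models, val_indices = val_idx,
                 scalers = scalers, fold_id = fold,
                 config = cfg, positive = positive),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Stratified", x$config$k_folds, "fold SVM (", x$config$kernel,
      "kernel, C =", x$config$C, ")\n")
  m <- x$mean; s <- x$sd
  for (nm in names(m))
    cat(sprintf("  %-12s %.3f +/- %.3f\n", nm, m[nm], s[nm]))
  invisible(x)
}

#' Default regularization grid for the hyperparameter search
#' @return the numeric C grid.
#' @export
default_c_grid <- function() {
  c(0.01, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1, 10, 20)
}

#' Exhaustive kernel / cost grid search by cross-validated accuracy
#'
#' Evaluates every (kernel, C) pair with the same stratified folds and
#' returns the pair with the highest mean accuracy; ties are broken by
#' kernel order as listed, then smaller C.
#'
#' @param X feature matrix.
#' @param y two-level factor.
#' @param kernels kernels to try, in tie-break order.
#' @param c_grid cost values (default [default_c_grid()]).
#' @param cfg base [svm_config()] providing k_folds and seed.
#' @return list: `kernel`, `C`, `accuracy`, `table` of all pairs.
#' @export
grid_search_svm <- function(X, y,
                            kernels = c("linear", "polynomial", "rbf",
                                        "sigmoid"),
                            c_grid = default_c_grid(),
                            cfg = svm_config()) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("grid search needs at least 2 classes")
  c_grid <- sort(c_grid)
  rows <- list(); best <- list(acc = -Inf)
  for (k in kernels) for (C in c_grid) {
    cv <- cross_validate_svm(X, y, svm_config(k, C, cfg$k_folds, cfg$seed))
    acc <- unname(cv$mean["accuracy"])
    rows[[length(rows) + 1L]] <- data.frame(kernel = k, C = C,
                                            accuracy = acc)
    if (acc > best$acc + 1e-12)
      best <- list(kernel = k, C = C, acc = acc)
  }
  list(kernel = best$kernel, C = best$C, accuracy = best$acc,
       table = do.call(rbind, rows))
}

#' Select the best-accuracy fold of a cross-validation result
#'
#' Argmax of per-fold accuracy; ties broken by lowest fold index. Used to
#' choose the model/validation pair on which attributions are computed.
#'
#' @param cv a `cv_result`.
#' @return list: `fold` (1-based id), `model`, `val_indices`, `scaler`,
#'   `accuracy`.
#' @export
select_best_fold <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  f <- which.max(cv$folds$accuracy)
  list(fold = f, model = cv$models[[f]],
       val_indices = cv$val_indices[[f]],
       scaler = cv$scalers[[f]],
       accuracy = cv$folds$accuracy[f])
}

#' Decision-score function of a fitted fold
#'
#' Returns a vectorized function mapping raw-feature rows to the SVM
#' decision margin, oriented so that positive scores favour the positive
#' class. Standardization with the fold's training statistics is applied
#' internally.
#'
#' @param model an e1071 svm fitted on standardized features with levels
#'   c("neg", "pos").
#' @param scaler list with `center` and `scale` from the training fold.
#' @return function(matrix) -> numeric scores.
#' @export
svm_decision_function <- function(model, scaler) {
  force(model); force(scaler)
  if (model$kernel == 0L) {
    # linear kernel: the primal form w'z + b gives identical margins and
    # avoids the support-vector expansion on large perturbation batches
    w <- drop(crossprod(model$coefs, model$SV))
    b <- -model$rho
    p1 <- stats::predict(model, model$SV[1, , drop = FALSE],
                         decision.values = TRUE)
    flip <- if (startsWith(colnames(attr(p1, "decision.values"))[1],
                           "pos")) 1 else -1
    return(function(X) {
      X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
      Z <- scale(X, scaler$center, scaler$scale)
      unname(flip * (drop(Z %*% w) + b))
    })
  }
  function(X) {
    X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
    Z <- scale(X, scaler$center, scaler$scale)
    p <- stats::predict(model, Z, decision.values = TRUE)
    dv <- drop(attr(p, "decision.values"))
    # e1071 orients the margin toward the first named class of the pair
    flip <- if (startsWith(colnames(attr(p, "decision.values"))[1], "pos"))
      1 else -1
    unname(flip * dv)
  }
}
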