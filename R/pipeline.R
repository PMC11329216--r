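# End-to-end orchestration: phantom simulation, index maps, ROI feature
# extraction, permutation statistics, SVM classification and attribution,
# with a provenance record sufficient to replay the run.

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "indices", "features", "stats", "classify",
#'   "explain")` in that order.
#' @param phantom_dims phantom grid shape.
#' @param snr phantom b0 signal-to-noise ratio.
#' @param bval,tau,n_dirs,n_b0 acquisition parameters (s/mm^2, s).
#' @param fit a [fit_config()].
#' @param cohort_n_per_group cohort sizes for the three biomarker groups.
#' @param planted_rois,effect_size,roi_correlation,effect_direction
#'   cohort generator parameters (see [cohort_spec()]).
#' @param svm an [svm_config()].
#' @param task which group contrast to classify: "pp" (-/- vs +/+) or
#'   "pn" (-/- vs +/-).
#' @param n_perm permutations for the group test.
#' @param shap_nsamples,lime_n_samples explainer budgets.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "indices", "features",
                                       "stats", "classify", "explain"),
                            phantom_dims = c(10L, 10L, 3L), snr = 30,
                            bval = 1000, tau = 0.0387, n_dirs = 48L,
                            n_b0 = 1L, fit = fit_config(),
                            cohort_n_per_group = c(60L, 60L, 60L),
                            planted_rois = c(7L, 22L, 40L),
                            effect_size = 1.0, roi_correlation = 0.3,
                            effect_direction = -1,
                            svm = svm_config(), task = c("pp", "pn"),
                            n_perm = 1000L,
                            shap_nsamples = NULL, lime_n_samples = 5000L) {
  task <- match.arg(task)
  stages <- match.arg(stages, c("simulate", "indices", "features",
                                "stats", "classify", "explain"),
                      several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, indices = 211L, features = 307L,
            stats = 401L, classify = 503L, explain = 601L)
  (as.integer(seed) * 7L + offs[[stage]]) %% .Machine$integer.max
}

log_stage <- function(name, expr) {
  t0 <- Sys.time()
  message("[", name, "] started")
  out <- expr
  message("[", name, "] done in ",
          round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1),
          " s")
  out
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Stages: `simulate` writes a multi-tensor phantom (NIfTI + bval/bvec)
#' and a planted-effect cohort CSV; `indices` computes the eight index
#' maps of the phantom; `features` extracts skeleton-masked ROI means on
#' a synthetic block atlas and writes the cohort feature matrix;
#' `stats` runs the maxT permutation group test; `classify` the
#' stratified-CV SVM; `explain` SHAP/LIME attribution on the best fold.
#' A provenance JSON (parameters, seeds, input hashes, versions) is
#' always written.
#'
#' @param cfg a [pipeline_config()].
#' @return a run-report list (stage outputs and artifact paths).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg, artifacts = list())
  scheme <- gradient_scheme(cfg$bval, sphere_fibonacci(cfg$n_dirs),
                            tau = cfg$tau, n_b0 = cfg$n_b0)
  phantom <- cohort <- maps <- fm <- cv <- NULL

  if ("simulate" %in% cfg$stages) {
    phantom <- log_stage("simulate", {
      regions <- list(
        list(tensor_component(c(1.7, 0.3, 0.3) * 1e-3, c(0, 0, 1))),
        list(tensor_component(c(1.7, 0.3, 0.3) * 1e-3, c(0, 0, 1), 0.5),
             tensor_component(c(1.7, 0.3, 0.3) * 1e-3, c(0, 1, 0), 0.5)),
        list(tensor_component(c(0.9, 0.9, 0.9) * 1e-3, c(0, 0, 1))))
      spec <- phantom_spec(cfg$phantom_dims, regions, scheme,
                           snr = cfg$snr,
                           seed = stage_seed(cfg$seed, "simulate"))
      p <- generate_phantom_image(spec)
      write_dwi(p$dwi, scheme, file.path(cfg$out_dir, "phantom"))
      p
    })
    cohort <- generate_cohort_features(cohort_spec(
      n_per_group = cfg$cohort_n_per_group,
      planted_rois = cfg$planted_rois, effect_size = cfg$effect_size,
      roi_correlation = cfg$roi_correlation,
      direction = cfg$effect_direction,
      seed = stage_seed(cfg$seed, "simulate")))
    write_cohort(cohort, file.path(cfg$out_dir, "cohort.csv"),
                 file.path(cfg$out_dir, "cohort_truth.json"))
    report$artifacts$phantom <- file.path(cfg$out_dir, "phantom.nii.gz")
    report$artifacts$cohort <- file.path(cfg$out_dir, "cohort.csv")
  }

  if ("indices" %in% cfg$stages) {
    if (is.null(phantom)) stop("indices stage requires simulate")
    maps <- log_stage("indices",
      compute_index_maps(phantom$dwi, scheme, phantom$mask, cfg$fit))
    write_index_maps(maps, file.path(cfg$out_dir, "indices"))
    report$artifacts$indices <- file.path(cfg$out_dir, "indices")
    report$index_maps <- maps
  }

  if ("features" %in% cfg$stages) {
    if (is.null(maps)) stop("features stage requires indices")
    fm <- log_stage("features", {
      atlas <- synthetic_atlas(dim(phantom$labels), n_rois = 3L)
      rm3 <- roi_means(maps$rtpp_dti, atlas)
      utils::write.csv(
        data.frame(roi = names(rm3), rtpp_dti = rm3, row.names = NULL),
        file.path(cfg$out_dir, "phantom_roi_means.csv"),
        row.names = FALSE)
      cohort$features
    })
    report$artifacts$features <- file.path(cfg$out_dir, "cohort.csv")
  }

  lbl <- if (is.null(cohort)) NULL else as.character(cohort$labels)
  pos_group <- if (cfg$task == "pp") "Abeta+/tau+" else "Abeta+/tau-"
  sel <- if (is.null(lbl)) NULL else
    lbl %in% c("Abeta-/tau-", pos_group)

  if ("stats" %in% cfg$stages) {
    if (is.null(cohort)) stop("stats stage requires simulate")
    report$stats <- log_stage("stats", {
      res <- permutation_group_test(
        cohort$features[lbl == "Abeta-/tau-", , drop = FALSE],
        cohort$features[lbl == pos_group, , drop = FALSE],
        n_perm = cfg$n_perm, seed = stage_seed(cfg$seed, "stats"))
      jsonlite::write_json(res, file.path(cfg$out_dir, "group_test.json"),
                           dataframe = "rows", digits = NA)
      res
    })
    report$artifacts$stats <- file.path(cfg$out_dir, "group_test.json")
  }

  if ("classify" %in% cfg$stages) {
    if (is.null(cohort)) stop("classify stage requires simulate")
    cv <- log_stage("classify", {
      scv <- svm_config(cfg$svm$kernel, cfg$svm$C, cfg$svm$k_folds,
                        stage_seed(cfg$seed, "classify"))
      cross_validate_svm(cohort$features[sel, , drop = FALSE],
                         factor(lbl[sel]), scv, positive = pos_group)
    })
    jsonlite::write_json(list(
      folds = cv$folds, mean = as.list(cv$mean), sd = as.list(cv$sd),
      kernel = cv$config$kernel, C = cv$config$C,
      k_folds = cv$config$k_folds, seed = cv$config$seed,
      positive = cv$positive, standardized = TRUE
    ), file.path(cfg$out_dir, "cv_result.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
    report$cv <- cv
    report$artifacts$classify <- file.path(cfg$out_dir, "cv_result.json")
  }

  if ("explain" %in% cfg$stages) {
    if (is.null(cv))
      stop("explain stage requires the classify stage to have run")
    report$attribution <- log_stage("explain", {
      Xtask <- cohort$features[sel, , drop = FALSE]
      best <- select_best_fold(cv)
      f <- svm_decision_function(best$model, best$scaler)
      lbl_task <- lbl[sel]
      tr_idx <- setdiff(seq_len(nrow(Xtask)), best$val_indices)
      bg <- Xtask[tr_idx[lbl_task[tr_idx] == "Abeta-/tau-"], ,
                  drop = FALSE]
      rep_ <- attribution_report(
        f, bg, Xtask[best$val_indices, , drop = FALSE],
        seed = stage_seed(cfg$seed, "explain"),
        shap_nsamples = cfg$shap_nsamples,
        lime_n_samples = cfg$lime_n_samples)
      write_attribution_report(rep_, file.path(cfg$out_dir,
                                               "attribution.json"))
      utils::write.csv(as.data.frame(unclass(rep_$shap)),
                       file.path(cfg$out_dir, "shap_values.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(unclass(rep_$lime)),
                       file.path(cfg$out_dir, "lime_values.csv"),
                       row.names = FALSE)
      rep_
    })
    report$artifacts$explain <- file.path(cfg$out_dir, "attribution.json")
  }

  prov <- list(
    package_version = as.character(utils::packageVersion("amura")),
    r_version = R.version.string,
    seed = cfg$seed,
    stage_seeds = as.list(vapply(cfg$stages, function(s)
      stage_seed(cfg$seed, s), numeric(1))),
    parameters = list(
      bval = cfg$bval, tau = cfg$tau, n_dirs = cfg$n_dirs,
      n_b0 = cfg$n_b0, snr = cfg$snr, phantom_dims = cfg$phantom_dims,
      sh_order = cfg$fit$order, lambda_lb = cfg$fit$lambda_lb,
      abeta_threshold = ABETA_POSITIVE_MAX,
      tau_threshold = TAU_POSITIVE_MIN,
      cohort_n_per_group = cfg$cohort_n_per_group,
      planted_rois = cfg$planted_rois, effect_size = cfg$effect_size,
      roi_correlation = cfg$roi_correlation,
      kernel = cfg$svm$kernel, C = cfg$svm$C, k_folds = cfg$svm$k_folds,
      task = cfg$task, n_perm = cfg$n_perm,
      lime_n_samples = cfg$lime_n_samples),
    stages = cfg$stages)
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  report$artifacts$provenance <- file.path(cfg$out_dir, "provenance.json")
  report
}
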