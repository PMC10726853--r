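# map_core: the mosaic statistic. Per-patch z-scores of one patient against
# a healthy reference cohort, exhaustive leave-one-as-singleton permutation
# p-values, FWE thresholding, thin-patch fraction.

#' Fit a reference model from control patch profiles
#'
#' Per-patch mean and sample standard deviation (n-1 denominator) across
#' the reference (healthy control) cohort. Patches whose reference SD is
#' zero or undefined are flagged degenerate and excluded from inference.
#'
#' @param profiles list of [patch_means()] profiles from controls (>= 2),
#'   all on the same parcellation scheme.
#' @return object of class `reference_model` with `patch_mean_ref`,
#'   `patch_sd_ref`, `n_ref`, `reference_profiles` (n_ref x N matrix,
#'   retained for the permutation null), `evaluable` and `degenerate`.
#' @export
fit_reference <- function(profiles) {
  .assert(is.list(profiles) && length(profiles) >= 2,
          "at least 2 control profiles are required")
  .assert(all(vapply(profiles, inherits, TRUE, "patch_profile")),
          "profiles must be patch_profile objects")
  ns <- vapply(profiles, function(p) length(p$patch_means), 0L)
  if (length(unique(ns)) != 1)
    stop("control profiles come from mixed parcellation schemes (patch counts ",
         paste(unique(ns), collapse = ", "), ")", call. = FALSE)
  mat <- do.call(rbind, lapply(profiles, `[[`, "patch_means"))
  ms <- .col_mean_sd(mat)
  degenerate <- !is.finite(ms$sd) | ms$sd == 0
  structure(list(patch_mean_ref = ms$mean,
                 patch_sd_ref = ms$sd,
                 n_ref = nrow(mat),
                 reference_profiles = mat,
                 degenerate = degenerate,
                 evaluable = !degenerate),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("<reference_model> n_ref = %d, %d patches (%d degenerate)\n",
              x$n_ref, length(x$patch_mean_ref), sum(x$degenerate)))
  invisible(x)
}

#' Per-patch z-scores of a patient against the reference
#'
#' `z[k] = (patient_mean[k] - ref_mean[k]) / ref_sd[k]`; degenerate patches
#' (reference SD zero/undefined) yield `NA`, never a silent infinity.
#'
#' @param patient a [patch_means()] profile.
#' @param ref a [fit_reference()] model on the same scheme.
#' @param ch_correction if TRUE, divide additionally by
#'   `sqrt(1 + 1/n_ref)` (the Crawford-Howell prediction-error scaling);
#'   default FALSE (plain z-scores).
#' @return numeric vector of z-scores, length N.
#' @export
zscore_patches <- function(patient, ref, ch_correction = FALSE) {
  .assert(inherits(patient, "patch_profile"), "patient must be a patch_profile")
  .assert(inherits(ref, "reference_model"), "ref must be a reference_model")
  if (length(patient$patch_means) != length(ref$patch_mean_ref))
    stop("patient and reference are on different schemes", call. = FALSE)
  denom <- ref$patch_sd_ref
  if (ch_correction) denom <- denom * sqrt(1 + 1 / ref$n_ref)
  z <- (patient$patch_means - ref$patch_mean_ref) / denom
  z[ref$degenerate | !is.finite(z)] <- NA_real_
  z
}

#' Exhaustive leave-one-as-singleton permutation null
#'
#' Pools the patient with the n_ref controls and, for each of the n_ref+1
#' pooled subjects in turn, treats that subject as the singleton and the
#' remaining n_ref as the reference, recomputing the per-patch z-score.
#' This is the exhaustive relabeling scheme for a singleton-versus-group
#' design; each patch gets its own null to respect regional differences in
#' thickness. Row 1 is the true patient (pooled-subject order: patient
#' first, then controls in input order) and reproduces [zscore_patches()]
#' bit-exactly. Fully deterministic.
#'
#' @inheritParams zscore_patches
#' @return matrix `(n_ref + 1) x N` of null z-scores; cells where the
#'   leave-one-out reference SD is zero/undefined are `NA`.
#' @export
exhaustive_null <- function(patient, ref, ch_correction = FALSE) {
  .assert(inherits(patient, "patch_profile"), "patient must be a patch_profile")
  .assert(inherits(ref, "reference_model"), "ref must be a reference_model")
  if (length(patient$patch_means) != length(ref$patch_mean_ref))
    stop("patient and reference are on different schemes", call. = FALSE)
  pooled <- rbind(patient$patch_means, ref$reference_profiles)
  n1 <- nrow(pooled)                     # n_ref + 1
  null_z <- matrix(NA_real_, n1, ncol(pooled))
  ch <- if (ch_correction) sqrt(1 + 1 / ref$n_ref) else 1
  for (i in seq_len(n1)) {
    ms <- .col_mean_sd(pooled[-i, , drop = FALSE])
    zi <- (pooled[i, ] - ms$mean) / (ms$sd * ch)
    zi[!is.finite(zi)] <- NA_real_
    null_z[i, ] <- zi
  }
  null_z
}

#' Permutation p-values from an exhaustive null
#'
#' `p[k]` is the fraction of null rows whose z-score is less than or equal
#' to the observed z (tie-inclusive, so the observed relabeling always
#' counts and `p >= 1/(n_ref+1)`). Undefined null cells count as not
#' smaller; an undefined observed z yields `NA`.
#'
#' @param observed_z numeric vector from [zscore_patches()].
#' @param null_z matrix from [exhaustive_null()] (includes the observed
#'   relabeling as one row).
#' @return numeric vector of p-values on the grid `k/(n_ref+1)`.
#' @export
patch_pvalues <- function(observed_z, null_z) {
  .assert(is.matrix(null_z) && length(observed_z) == ncol(null_z),
          "observed_z length must match ncol(null_z)")
  n_iter <- nrow(null_z)
  cnt <- colSums(sweep(null_z, 2L, observed_z, "<=") , na.rm = TRUE)
  p <- cnt / n_iter
  p[!is.finite(observed_z)] <- NA_real_
  p
}

#' Threshold a p-value map into thin-patch calls
#'
#' `"per-patch"`: `thin[k] = p[k] <= alpha` (the permutation p already
#' embodies the subject's personalized null). `"max-stat"`: a patch is thin
#' when its observed z falls at or below the alpha-quantile of the null
#' distribution of the per-row minimum z across patches (family-wise error
#' control by the minimum-statistic distribution); implemented through the
#' FWE p-value `#\{row minima <= z[k]\}/rows`, which reduces exactly to the
#' per-patch test when N = 1.
#'
#' @param p vector of per-patch p-values.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param correction `"per-patch"` or `"max-stat"`.
#' @param observed_z,null_z required for `"max-stat"`; also used to warn
#'   when `alpha` is below the attainable grid minimum `1/(n_ref+1)`.
#' @return logical vector of thin calls (NA p -> FALSE).
#' @export
threshold_map <- function(p, alpha = 0.05,
                          correction = c("per-patch", "max-stat"),
                          observed_z = NULL, null_z = NULL) {
  correction <- match.arg(correction)
  .assert(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1,
          "alpha must be a single number in (0, 1)")
  if (!is.null(null_z) && alpha < 1 / nrow(null_z))
    warning(sprintf(paste0("alpha = %g is below the attainable permutation ",
                           "minimum 1/%d; no patch can be called thin"),
                    alpha, nrow(null_z)))
  if (correction == "per-patch")
    return(!is.na(p) & p <= alpha)
  .assert(!is.null(observed_z) && !is.null(null_z),
          "max-stat correction requires observed_z and null_z")
  minima <- suppressWarnings(apply(null_z, 1L, min, na.rm = TRUE))
  minima <- minima[is.finite(minima)]
  .assert(length(minima) > 0, "max-stat: null minima are all undefined")
  p_fwe <- vapply(observed_z, function(z) {
    if (!is.finite(z)) return(NA_real_)
    sum(minima <= z) / length(minima)
  }, 0)
  !is.na(p_fwe) & p_fwe <= alpha
}

#' Thin-patch fraction
#'
#' The scalar biomarker: the fraction of evaluable patches called thin.
#'
#' @param thin logical vector of thin calls.
#' @param evaluable logical vector marking patches with a defined statistic.
#' @return ratio in `[0, 1]`.
#' @export
thin_patch_fraction <- function(thin, evaluable = rep(TRUE, length(thin))) {
  .assert(length(thin) == length(evaluable),
          "thin and evaluable must have the same length")
  n_eval <- sum(evaluable)
  .assert(n_eval > 0, "no evaluable patches")
  sum(thin & evaluable) / n_eval
}

#' Run the full mosaic analysis for one subject (patch-profile level)
#'
#' @param patient a [patch_means()] profile.
#' @param ref a [fit_reference()] model.
#' @param alpha significance level (default 0.05).
#' @param correction `"per-patch"` or `"max-stat"`.
#' @param ch_correction see [zscore_patches()].
#' @return object of class `atrophy_result` with `subject_id`, `z`, `p`,
#'   `thin`, `evaluable`, `alpha`, `correction`, `n_permutations`
#'   (= n_ref + 1), `patch_sizes` and `thin_patch_fraction`.
#' @export
map_profile <- function(patient, ref, alpha = 0.05,
                        correction = c("per-patch", "max-stat"),
                        ch_correction = FALSE) {
  correction <- match.arg(correction)
  z <- zscore_patches(patient, ref, ch_correction)
  null_z <- exhaustive_null(patient, ref, ch_correction)
  p <- patch_pvalues(z, null_z)
  thin <- threshold_map(p, alpha, correction, observed_z = z, null_z = null_z)
  evaluable <- !is.na(z)
  structure(list(subject_id = patient$subject_id,
                 z = z, p = p, thin = thin, evaluable = evaluable,
                 alpha = alpha, correction = correction,
                 n_permutations = nrow(null_z),
                 patch_sizes = patient$patch_sizes,
                 thin_patch_fraction = thin_patch_fraction(thin, evaluable)),
            class = "atrophy_result")
}

#' Run the full mosaic analysis for one subject (vertex level)
#'
#' Composes [patch_means()], [fit_reference()], [exhaustive_null()],
#' [patch_pvalues()], [threshold_map()] and [thin_patch_fraction()]. The
#' whole pipeline is deterministic: the permutation is exhaustive, so no
#' random number is drawn anywhere.
#'
#' @param patient a [vertex_map()].
#' @param controls list of control [vertex_map()]s (>= 2).
#' @param scheme a [parcellation()].
#' @param mask optional [cortical_mask()].
#' @inheritParams map_profile
#' @return an `atrophy_result` (see [map_profile()]).
#' @export
run_map_subject <- function(patient, controls, scheme, mask = NULL,
                            alpha = 0.05,
                            correction = c("per-patch", "max-stat"),
                            ch_correction = FALSE) {
  correction <- match.arg(correction)
  .assert(inherits(patient, "vertex_map"), "patient must be a vertex_map")
  .assert(is.list(controls) && length(controls) >= 2,
          "at least 2 control maps are required")
  ref <- fit_reference(lapply(controls, patch_means, scheme = scheme,
                              mask = mask))
  map_profile(patch_means(patient, scheme, mask), ref,
              alpha = alpha, correction = correction,
              ch_correction = ch_correction)
}

#' @export
print.atrophy_result <- function(x, ...) {
  cat(sprintf(paste0("<atrophy_result> subject '%s': %d/%d evaluable patches ",
                     "thin (fraction %.4f) at alpha %.3g [%s, %d relabelings]\n"),
              x$subject_id, sum(x$thin), sum(x$evaluable),
              x$thin_patch_fraction, x$alpha, x$correction, x$n_permutations))
  invisible(x)
}

#' Thin-patch fractions for a whole cohort of patients
#'
#' Fits the reference once and applies [map_profile()] to every patient.
#' Optionally residualizes patch means on age and sex before scoring, with
#' coefficients estimated on the controls only.
#'
#' @param patients list of patient [vertex_map()]s.
#' @param controls list of control [vertex_map()]s.
#' @param scheme a [parcellation()].
#' @param mask optional [cortical_mask()].
#' @param covariates optional data.frame with columns `age` and `sex`
#'   (rows: patients first, then controls, matching the input order);
#'   enables control-based residualization.
#' @inheritParams map_profile
#' @return data.frame with `subject_id` and `thin_patch_fraction`, plus the
#'   per-patient results in attribute `"results"`.
#' @export
run_map_cohort <- function(patients, controls, scheme, mask = NULL,
                           alpha = 0.05,
                           correction = c("per-patch", "max-stat"),
                           ch_correction = FALSE, covariates = NULL) {
  correction <- match.arg(correction)
  prof_pat <- lapply(patients, patch_means, scheme = scheme, mask = mask)
  prof_ctl <- lapply(controls, patch_means, scheme = scheme, mask = mask)
  if (!is.null(covariates)) {
    .assert(nrow(covariates) == length(patients) + length(controls),
            "covariates must have one row per subject (patients then controls)")
    adj <- .residualize_on_controls(prof_pat, prof_ctl, covariates)
    prof_pat <- adj$patients
    prof_ctl <- adj$controls
  }
  ref <- fit_reference(prof_ctl)
  results <- lapply(prof_pat, map_profile, ref = ref, alpha = alpha,
                    correction = correction, ch_correction = ch_correction)
  out <- data.frame(
    subject_id = vapply(results, `[[`, "", "subject_id"),
    thin_patch_fraction = vapply(results, `[[`, 0, "thin_patch_fraction"),
    stringsAsFactors = FALSE)
  attr(out, "results") <- results
  out
}

#' Residualize patch means on age and sex, coefficients from controls only.
#' The control-group mean structure is preserved (fitted values at each
#' subject's covariates are replaced by the control grand mean).
#' @noRd
.residualize_on_controls <- function(prof_pat, prof_ctl, covariates) {
  n_pat <- length(prof_pat); n_ctl <- length(prof_ctl)
  sex01 <- as.integer(toupper(as.character(covariates$sex)) == "M")
  X <- cbind(1, as.double(covariates$age), sex01)
  Xc <- X[n_pat + seq_len(n_ctl), , drop = FALSE]
  .assert(qr(Xc)$rank == ncol(Xc), "covariate design is rank deficient")
  Yc <- do.call(rbind, lapply(prof_ctl, `[[`, "patch_means"))
  beta <- solve(crossprod(Xc), crossprod(Xc, Yc))
  adjust_one <- function(prof, xrow) {
    fit <- drop(xrow %*% beta)
    ctr <- drop(colMeans(Xc) %*% beta)   # control grand-mean prediction
    prof$patch_means <- prof$patch_means - fit + ctr
    prof
  }
  list(
    patients = lapply(seq_len(n_pat), function(i)
      adjust_one(prof_pat[[i]], X[i, , drop = FALSE])),
    controls = lapply(seq_len(n_ctl), function(i)
      adjust_one(prof_ctl[[i]], X[n_pat + i, , drop = FALSE]))
  )
}
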