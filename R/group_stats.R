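# group_stats: nonparametric group-level patch contrast (patients vs
# controls) on patch thickness means.

#' Nonparametric group-level patch contrast
#'
#' Per patch, the statistic is `mean(patients) - mean(controls)` of patch
#' thickness; the null is built by permuting group labels. When the total
#' number of subjects is <= 10 all `choose(n, n_patients)` assignments are
#' enumerated and p-values are pure ratios; otherwise `n_perm` seeded
#' Monte-Carlo draws are used with +1 smoothing,
#' `p = (1 + #\{null <= observed\}) / (n_perm + 1)`. One-sided for
#' patients < controls, tie-inclusive. Correction across patches is either
#' max-statistic FWE (minimum-statistic distribution) or BH-FDR.
#'
#' @param patients,controls lists of [patch_means()] profiles on a common
#'   scheme.
#' @param n_perm Monte-Carlo permutation count (default 5000).
#' @param seed RNG seed for Monte-Carlo mode.
#' @param correction `"maxstat"` or `"fdr"`.
#' @param alpha significance level; default 0.05.
#' @param exhaustive force (`TRUE`/`FALSE`) or auto-select (`NULL`,
#'   default: total subjects <= 10) full enumeration.
#' @return object of class `group_contrast` with `patch_stat`, `p`,
#'   `significant`, `n_permutations`, `exhaustive`.
#' @export
group_permutation_test <- function(patients, controls, n_perm = 5000,
                                   seed = NULL,
                                   correction = c("maxstat", "fdr"),
                                   alpha = 0.05, exhaustive = NULL) {
  correction <- match.arg(correction)
  .assert(length(patients) >= 2 && length(controls) >= 2,
          "at least 2 subjects per group are required")
  all_prof <- c(patients, controls)
  ns <- vapply(all_prof, function(p) length(p$patch_means), 0L)
  .assert(length(unique(ns)) == 1, "profiles are on mixed schemes")
  Y <- do.call(rbind, lapply(all_prof, `[[`, "patch_means"))
  n_pat <- length(patients)
  n_tot <- nrow(Y)
  observed <- colMeans(Y[seq_len(n_pat), , drop = FALSE]) -
    colMeans(Y[-seq_len(n_pat), , drop = FALSE])
  stat_for <- function(idx) {
    colMeans(Y[idx, , drop = FALSE]) - colMeans(Y[-idx, , drop = FALSE])
  }
  if (is.null(exhaustive)) exhaustive <- n_tot <= 10
  if (exhaustive) {
    combos <- utils::combn(n_tot, n_pat)
    null_stats <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j)
      stat_for(combos[, j])))
    cnt <- colSums(sweep(null_stats, 2L, observed, "<="), na.rm = TRUE)
    p <- cnt / ncol(combos)
    n_permutations <- ncol(combos)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_stats <- matrix(NA_real_, n_perm, ncol(Y))
    for (b in seq_len(n_perm))
      null_stats[b, ] <- stat_for(sample.int(n_tot, n_pat))
    cnt <- colSums(sweep(null_stats, 2L, observed, "<="), na.rm = TRUE)
    p <- (1 + cnt) / (n_perm + 1)
    n_permutations <- n_perm
  }
  evaluable <- is.finite(observed)
  significant <- if (correction == "fdr") {
    fdr_bh(ifelse(evaluable, p, NA_real_), alpha)
  } else {
    maxstat_fwe(observed, null_stats, alpha)
  }
  significant <- significant & evaluable
  structure(list(patch_stat = observed, p = p, significant = significant,
                 n_permutations = n_permutations, exhaustive = exhaustive,
                 correction = correction, alpha = alpha),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf(paste0("<group_contrast> %d patches, %d significant ",
                     "(%s, alpha %.3g, %d %s permutations)\n"),
              length(x$patch_stat), sum(x$significant), x$correction,
              x$alpha, x$n_permutations,
              if (x$exhaustive) "exhaustive" else "Monte-Carlo"))
  invisible(x)
}

#' Residualize patch profiles on age and sex
#'
#' Per patch, thickness is regressed on intercept + age + sex across all
#' subjects; residuals (with the grand mean added back, to stay on the mm
#' scale) replace the patch means. Group labels are untouched, so a group
#' difference orthogonal to the covariates is preserved.
#'
#' @param profiles list of [patch_means()] profiles.
#' @param covariates data.frame with columns `age` and `sex`, one row per
#'   profile in order.
#' @return list of adjusted `patch_profile`s.
#' @export
residualize_covariates <- function(profiles, covariates) {
  .assert(is.list(profiles) && length(profiles) >= 3,
          "at least 3 profiles are required")
  .assert(nrow(covariates) == length(profiles),
          "covariates must have one row per profile")
  sex01 <- as.integer(toupper(as.character(covariates$sex)) == "M")
  X <- cbind(intercept = 1, age = as.double(covariates$age), sex = sex01)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
               collapse = ", "), call. = FALSE)
  Y <- do.call(rbind, lapply(profiles, `[[`, "patch_means"))
  fit <- X %*% solve(crossprod(X), crossprod(X, Y))
  resid <- Y - fit
  grand <- matrix(colMeans(Y), nrow(Y), ncol(Y), byrow = TRUE)
  adj <- resid + grand
  lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    p$patch_means <- adj[i, ]
    p
  })
}
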