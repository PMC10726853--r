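# baselines: the standard vertexwise alternatives -- smoothing, the
# singleton-versus-group GLM (Crawford-Howell when covariate-free), FDR and
# max-statistic permutation correction, burden fraction.

#' Convert a Gaussian smoothing sigma to FWHM
#'
#' `FWHM = sigma * 2 * sqrt(2 * ln 2)` (factor 2.35482...).
#'
#' @param sigma kernel standard deviation, mm (>= 0).
#' @return FWHM in mm.
#' @export
sigma_to_fwhm <- function(sigma) {
  .assert(is.numeric(sigma) && all(sigma >= 0), "sigma must be >= 0")
  sigma * 2 * sqrt(2 * log(2))
}

#' Convert a Gaussian FWHM to sigma
#' @param fwhm full width at half maximum, mm (>= 0).
#' @return sigma in mm.
#' @export
fwhm_to_sigma <- function(fwhm) {
  .assert(is.numeric(fwhm) && all(fwhm >= 0), "fwhm must be >= 0")
  fwhm / (2 * sqrt(2 * log(2)))
}

#' Smooth a vertex map on a mesh
#'
#' Iterated symmetric neighbor diffusion: with self-retention weight `w`,
#' each edge carries weight `(1 - w)/max_degree` and the remainder stays on
#' the vertex, so the operator is symmetric and doubly stochastic --
#' constants are preserved exactly, the global mean is conserved and
#' variance contracts. The iteration count is chosen so the accumulated
#' kernel variance approximates `(sigma/edge_length)^2` (per-iteration
#' variance `(1 - w) * edge_length^2`). `sigma = 0` returns the input
#' unchanged. Vertices outside the mask never contribute; isolated masked
#' vertices are left unchanged with a warning.
#'
#' @param map a [vertex_map()].
#' @param mesh a mesh from [make_mesh()] (adjacency + nominal edge length).
#' @param sigma Gaussian-equivalent kernel SD in mm (e.g. 0, 2, 3, 4).
#' @param mask optional [cortical_mask()].
#' @param w self-retention weight per iteration, in (0, 1); default 0.5.
#' @return a smoothed [vertex_map()].
#' @export
smooth_on_mesh <- function(map, mesh, sigma, mask = NULL, w = 0.5) {
  .assert(inherits(map, "vertex_map"), "map must be a vertex_map")
  .assert(inherits(mesh, "mosaic_mesh"), "mesh must come from make_mesh()")
  .assert(is.numeric(sigma) && length(sigma) == 1 && sigma >= 0,
          "sigma must be a single number >= 0")
  v <- map$vertex_count
  .assert(mesh$vertex_count == v, "mesh does not match vertex count")
  if (sigma == 0) return(map)
  m <- .as_mask(mask, v)
  adj <- lapply(seq_len(v), function(i) {
    nb <- mesh$adjacency[[i]]
    nb[m[nb]]
  })
  deg <- lengths(adj)
  iso <- which(m & deg == 0L)
  if (length(iso) > 0)
    warning("isolated vertex(es) left unsmoothed: ",
            paste(utils::head(iso, 5), collapse = ", "))
  deg_max <- max(deg, 1L)
  n_iter <- max(1L, ceiling((sigma / mesh$edge_length)^2 / (1 - w)))
  x <- map$values
  wn <- (1 - w) / deg_max
  # flattened (vertex, neighbor) edge list for fast accumulation
  ei <- rep.int(seq_len(v), deg)
  ej <- unlist(adj, use.names = FALSE)
  for (it in seq_len(n_iter)) {
    nb_sum <- numeric(v)
    if (length(ej) > 0) {
      s <- rowsum(x[ej], ei)
      nb_sum[as.integer(rownames(s))] <- s[, 1]
    }
    x_new <- (1 - wn * deg) * x + wn * nb_sum
    x_new[!m] <- x[!m]
    x <- x_new
  }
  vertex_map(pmax(x, 0), map$subject_id)
}

#' Singleton-versus-group test (vertexwise)
#'
#' Tests one patient against a control group at every masked vertex with a
#' prediction-interval GLM: control thickness is regressed on intercept,
#' age and sex; the patient's residual is scaled by the prediction standard
#' error, `t = r0 / (s * sqrt(1 + x0' (X'X)^-1 x0))` with
#' `df = n_controls - rank`. With no covariates this reduces exactly to the
#' Crawford-Howell single-case test `t = (x - mean)/(SD * sqrt(1 + 1/n))`.
#' One-sided p-values for thinness (patient < controls).
#'
#' @param patient a [vertex_map()].
#' @param controls list of control [vertex_map()]s.
#' @param covariates optional data.frame with columns `age` and `sex` and
#'   `length(controls) + 1` rows: the controls in order, then the patient
#'   as the last row.
#' @param mask optional [cortical_mask()]; vertices outside get `NA`.
#' @return list with vectors `t`, `p` (one-sided, lower) and scalar `df`.
#' @export
singleton_vs_group <- function(patient, controls, covariates = NULL,
                               mask = NULL) {
  .assert(inherits(patient, "vertex_map"), "patient must be a vertex_map")
  n <- length(controls)
  .assert(n >= 2, "at least 2 controls are required")
  v <- patient$vertex_count
  Y <- do.call(rbind, lapply(controls, function(cm) {
    .assert(inherits(cm, "vertex_map") && cm$vertex_count == v,
            "controls must be vertex_maps on the same vertex set")
    cm$values
  }))
  m <- .as_mask(mask, v)
  if (is.null(covariates)) {
    X <- matrix(1, n, 1)
    x0 <- matrix(1, 1, 1)
  } else {
    .assert(n >= 3, "at least 3 controls are required with covariates")
    .assert(nrow(covariates) == n + 1,
            "covariates must have length(controls) + 1 rows (patient last)")
    sex01 <- as.integer(toupper(as.character(covariates$sex)) == "M")
    Xa <- cbind(intercept = 1, age = as.double(covariates$age), sex = sex01)
    X <- Xa[seq_len(n), , drop = FALSE]
    x0 <- Xa[n + 1, , drop = FALSE]
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("rank-deficient covariate design; collinear column(s): ",
           paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]],
                 collapse = ", "), call. = FALSE)
  }
  r <- ncol(X)
  df <- n - r
  .assert(df >= 1, "not enough controls for the requested design")
  XtX_inv <- solve(crossprod(X))
  beta <- XtX_inv %*% crossprod(X, Y)
  resid <- Y - X %*% beta
  s2 <- colSums(resid^2) / df
  h <- drop(1 + x0 %*% XtX_inv %*% t(x0))
  tval <- (patient$values - drop(x0 %*% beta)) / sqrt(s2 * h)
  tval[!m | !is.finite(tval)] <- NA_real_
  pval <- stats::pt(tval, df = df)
  list(t = tval, p = pval, df = df)
}

#' Benjamini-Hochberg FDR rejections
#'
#' Step-up control of the false discovery rate at level `alpha`: all
#' p-values at or below the largest `p(k) <= k * alpha / m` are rejected.
#'
#' @param p vector of p-values in `[0, 1]` (NA allowed, never rejected).
#' @param alpha FDR level; default 0.05.
#' @return logical rejection vector.
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(logical(0))
  .assert(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must be in [0, 1]")
  padj <- stats::p.adjust(p, method = "BH")
  !is.na(padj) & padj <= alpha
}

#' Max-statistic (minimum-t) permutation FWE rejections
#'
#' Rejects element k when the observed statistic falls at or below the
#' alpha-quantile of the permutation distribution of the per-replicate
#' minimum statistic (one-sided, small = atrophic). With a single element
#' this is identical to the element-wise permutation test.
#'
#' @param observed_stat observed statistic vector (z or t; lower = thinner).
#' @param null_stats matrix of permutation replicates (rows) of the full
#'   statistic map (columns).
#' @param alpha FWE level; default 0.05.
#' @return logical rejection vector.
#' @export
maxstat_fwe <- function(observed_stat, null_stats, alpha = 0.05) {
  .assert(is.matrix(null_stats) && ncol(null_stats) == length(observed_stat),
          "null_stats must be a matrix with one column per element")
  if (nrow(null_stats) < 1 / alpha)
    warning(sprintf("only %d permutation replicates for alpha = %g; the %g-quantile is unreliable",
                    nrow(null_stats), alpha, alpha))
  minima <- suppressWarnings(apply(null_stats, 1L, min, na.rm = TRUE))
  minima <- minima[is.finite(minima)]
  .assert(length(minima) > 0, "all null replicates are undefined")
  p_fwe <- vapply(observed_stat, function(s) {
    if (!is.finite(s)) return(NA_real_)
    sum(minima <= s) / length(minima)
  }, 0)
  !is.na(p_fwe) & p_fwe <= alpha
}

#' Burden fraction
#'
#' Fraction of masked elements called significantly thin; the reference for
#' the ratio is the cortical mask.
#'
#' @param rejections logical vector of significance calls.
#' @param mask logical vector / [cortical_mask()] of the same length.
#' @return ratio in `[0, 1]`.
#' @export
burden_fraction <- function(rejections, mask) {
  m <- as.logical(unclass(mask))
  .assert(length(rejections) == length(m),
          "rejections and mask must have the same length")
  .assert(sum(m) > 0, "empty mask")
  sum(rejections & m, na.rm = TRUE) / sum(m)
}

#' Standard-approach burden for one subject
#'
#' The baseline pipeline at vertex level: optional smoothing, the
#' singleton-versus-group test, multiplicity correction (BH-FDR on the
#' one-sided p-map, or max-statistic FWE over the exhaustive
#' leave-one-as-singleton relabelings of the pooled set), and the burden
#' fraction over the cortical mask.
#'
#' @inheritParams singleton_vs_group
#' @param mesh mesh for smoothing (required when `sigma > 0`).
#' @param sigma smoothing kernel SD in mm (0 = none).
#' @param correction `"fdr"` or `"maxstat"`.
#' @param alpha significance level; default 0.05.
#' @return list with `t`, `p`, `rejected`, `burden_fraction`, `df`,
#'   `sigma`, `correction`.
#' @export
run_baseline_subject <- function(patient, controls, mesh = NULL, sigma = 0,
                                 covariates = NULL, mask = NULL,
                                 correction = c("fdr", "maxstat"),
                                 alpha = 0.05) {
  correction <- match.arg(correction)
  if (sigma > 0) {
    .assert(!is.null(mesh), "smoothing requires a mesh")
    patient <- smooth_on_mesh(patient, mesh, sigma, mask)
    controls <- lapply(controls, smooth_on_mesh, mesh = mesh, sigma = sigma,
                       mask = mask)
  }
  res <- singleton_vs_group(patient, controls, covariates, mask)
  m <- .as_mask(mask, patient$vertex_count)
  if (correction == "fdr") {
    rejected <- fdr_bh(res$p, alpha)
  } else {
    n <- length(controls)
    pooled <- c(list(patient), controls)
    # covariate rows in pooled order (patient first, then controls)
    pooled_cov <- if (is.null(covariates)) NULL else
      covariates[c(n + 1, seq_len(n)), , drop = FALSE]
    null_t <- matrix(NA_real_, n + 1, patient$vertex_count)
    for (i in seq_len(n + 1)) {
      cov_i <- if (is.null(pooled_cov)) NULL else
        pooled_cov[c(setdiff(seq_len(n + 1), i), i), , drop = FALSE]
      null_t[i, ] <- singleton_vs_group(pooled[[i]], pooled[-i],
                                        covariates = cov_i, mask = mask)$t
    }
    rejected <- maxstat_fwe(res$t, null_t, alpha)
  }
  list(t = res$t, p = res$p, df = res$df, rejected = rejected,
       burden_fraction = burden_fraction(rejected, m),
       sigma = sigma, correction = correction)
}
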