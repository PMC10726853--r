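# synthetic: meshes, balanced parcellations and simulated cohorts with
# injected patch-level atrophy and clinical variables coupled to the true
# atrophy burden. Everything is seeded and bit-reproducible; per-subject
# substreams are derived from (seed, subject index) so individual subjects
# are stable when cohort sizes change.

#' Build a deterministic mesh
#'
#' `"grid"` is a 4-connected rectangular lattice (the first V cells of a
#' near-square grid), `"ring"` a single cycle, `"path"` an open chain.
#'
#' @param V number of vertices (>= 3).
#' @param topology `"grid"`, `"ring"` or `"path"`.
#' @param edge_length nominal edge length in mm (default 1).
#' @return object of class `mosaic_mesh` with `vertex_count`, `adjacency`
#'   (neighbor index lists) and `edge_length`.
#' @export
make_mesh <- function(V, topology = c("grid", "ring", "path"),
                      edge_length = 1) {
  topology <- match.arg(topology)
  .assert(is.numeric(V) && length(V) == 1 && V >= 3, "V must be >= 3")
  V <- as.integer(V)
  adjacency <- if (topology == "ring") {
    lapply(seq_len(V), function(i)
      c(if (i == 1) V else i - 1L, if (i == V) 1L else i + 1L))
  } else if (topology == "path") {
    lapply(seq_len(V), function(i)
      c(if (i > 1) i - 1L, if (i < V) i + 1L))
  } else {
    nc <- ceiling(sqrt(V))
    lapply(seq_len(V), function(i) {
      r <- (i - 1L) %/% nc
      c0 <- (i - 1L) %% nc
      nb <- integer(0)
      if (c0 > 0L) nb <- c(nb, i - 1L)
      if (c0 < nc - 1L && i + 1L <= V && (i %% nc != 0L)) nb <- c(nb, i + 1L)
      if (r > 0L) nb <- c(nb, i - nc)
      if (i + nc <= V) nb <- c(nb, i + nc)
      nb
    })
  }
  structure(list(vertex_count = V, adjacency = adjacency,
                 edge_length = edge_length, topology = topology),
            class = "mosaic_mesh")
}

#' @export
print.mosaic_mesh <- function(x, ...) {
  cat(sprintf("<mosaic_mesh> %s, %d vertices, edge %.3g mm\n",
              x$topology, x$vertex_count, x$edge_length))
  invisible(x)
}

#' Balanced contiguous parcellation
#'
#' Splits `V` vertices into `N` contiguous blocks of near-equal size
#' (sizes differ by at most 1), mimicking roughly equally sized atlas
#' regions. Deterministic; `seed` is accepted for interface symmetry and
#' ignored.
#'
#' @param V number of vertices.
#' @param N number of patches (`N <= V`).
#' @param seed ignored (the construction is deterministic).
#' @return a [parcellation()].
#' @export
make_parcellation <- function(V, N, seed = NULL) {
  .assert(is.numeric(V) && is.numeric(N) && N >= 1, "V and N must be positive")
  .assert(N <= V, "N must not exceed V")
  V <- as.integer(V); N <- as.integer(N)
  sizes <- rep(V %/% N, N)
  r <- V %% N
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  parcellation(rep.int(seq_len(N), sizes))
}

#' Simulation configuration
#'
#' Defaults mirror the study conditions the generator emulates: an 89-
#' subject healthy reference cohort and 465 patients; whole-brain cortical
#' thickness 2.41 mm with 0.11 mm between-subject SD in controls; lesion
#' volume lognormal with mean 5.39 mL and SD 8.41 mL; EDSS on the 0-10
#' half-point grid with median near 1.5; lesion volume coupled to the true
#' atrophy burden more strongly than EDSS.
#'
#' @param seed master RNG seed.
#' @param n_controls,n_patients cohort sizes.
#' @param V vertices; N patches.
#' @param base_mean population mean thickness, mm.
#' @param base_sd_between between-subject SD of whole-map thickness, mm.
#' @param patch_offset_sd SD of fixed regional (per-patch) mean offsets, mm.
#' @param patch_sd_within SD of subject-by-patch deviations, mm.
#' @param vertex_noise_sd vertex-level measurement noise SD, mm.
#' @param atrophy_patch_fraction mean fraction of atrophic patches across
#'   patients. Each patient draws an individual atrophy propensity from a
#'   Beta distribution with this mean (see `atrophy_heterogeneity`), then
#'   each patch is atrophic independently with that propensity -- disease
#'   burden is strongly heterogeneous across patients, as in relapsing-
#'   remitting cohorts.
#' @param atrophy_heterogeneity Beta shape1 of the per-patient propensity
#'   (shape2 is set to match the configured mean); larger values give a
#'   more homogeneous cohort. Default 2.
#' @param atrophy_effect atrophy depth in units of the empirical reference
#'   patch SD.
#' @param clinical_coupling target Pearson correlation between true burden
#'   and lesion volume, in [0, 1].
#' @param edss_coupling target (weaker) coupling for EDSS.
#' @param lv_mean,lv_sd lognormal calibration for lesion volume, mL.
#' @param atrophy_unit `"patch"` (default) or `"vertex"` (independent
#'   vertex-level injection, for baseline comparisons).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_controls = 89, n_patients = 465,
                              V = 10000, N = 1000,
                              base_mean = 2.41, base_sd_between = 0.11,
                              patch_offset_sd = 0.15,
                              patch_sd_within = 0.05,
                              vertex_noise_sd = 0.25,
                              atrophy_patch_fraction = 0.1,
                              atrophy_heterogeneity = 2,
                              atrophy_effect = 6,
                              clinical_coupling = 0.6,
                              edss_coupling = 0.35,
                              lv_mean = 5.39, lv_sd = 8.41,
                              atrophy_unit = c("patch", "vertex")) {
  atrophy_unit <- match.arg(atrophy_unit)
  .assert(n_controls >= 2, "n_controls must be >= 2")
  .assert(n_patients >= 1, "n_patients must be >= 1")
  .assert(atrophy_patch_fraction >= 0 && atrophy_patch_fraction <= 1,
          "atrophy_patch_fraction must lie in [0, 1]")
  .assert(clinical_coupling >= 0 && clinical_coupling <= 1 &&
            edss_coupling >= 0 && edss_coupling <= 1,
          "couplings must lie in [0, 1]")
  structure(as.list(environment()), class = "simulation_config")
}

#' Latent-normal correlation needed for a Pearson target on a lognormal
#' margin: corr(exp(s W), W) = s / sqrt(exp(s^2) - 1).
#' @noRd
.lognormal_attenuation <- function(sdlog) sdlog / sqrt(exp(sdlog^2) - 1)

#' Simulate a cohort of thickness maps with injected atrophy
#'
#' Controls: per subject, a global thickness shift (between-subject SD),
#' fixed regional patch offsets, subject-by-patch deviations and vertex
#' noise. Patients: same generative model, then each patch (or vertex) is
#' independently atrophic with probability `atrophy_patch_fraction`;
#' atrophic locations are lowered by `atrophy_effect` empirical reference
#' SDs. Lesion volume is lognormal (calibrated to the configured mean/SD)
#' and coupled to the realized burden at the target Pearson correlation via
#' a Gaussian copula whose latent correlation is inflated by the closed-
#' form lognormal attenuation factor; EDSS is generated the same way on the
#' 0-10 half-point grid with the weaker coupling. Identical seeds give
#' bit-identical cohorts.
#'
#' @param config a [simulation_config()].
#' @return object of class `simulated_cohort`: `maps` (named list of
#'   [vertex_map()]s), `cohort` (a `cohort_table`), `scheme`, `mask`,
#'   `mesh`, `ground_truth` (per-patient atrophic patch sets and true
#'   burden) and `config`.
#' @export
simulate_cohort <- function(config) {
  .assert(inherits(config, "simulation_config"),
          "config must come from simulation_config()")
  cf <- config
  n_tot <- cf$n_controls + cf$n_patients
  scheme <- make_parcellation(cf$V, cf$N)
  mask <- cortical_mask(rep(TRUE, cf$V))
  mesh <- make_mesh(cf$V, "grid")

  sdlog_lv <- sqrt(log(1 + (cf$lv_sd / cf$lv_mean)^2))
  meanlog_lv <- log(cf$lv_mean) - sdlog_lv^2 / 2
  att_lv <- .lognormal_attenuation(sdlog_lv)
  .assert(cf$clinical_coupling <= att_lv,
          sprintf("infeasible clinical_coupling %.3f: the lognormal margin caps the attainable Pearson correlation at %.3f",
                  cf$clinical_coupling, att_lv))
  c_lv <- cf$clinical_coupling / att_lv
  sdlog_edss <- 0.9
  att_edss <- .lognormal_attenuation(sdlog_edss)
  .assert(cf$edss_coupling <= att_edss,
          sprintf("infeasible edss_coupling %.3f (cap %.3f)",
                  cf$edss_coupling, att_edss))
  c_edss <- cf$edss_coupling / att_edss

  set.seed(cf$seed %% 2147483647)
  patch_offset <- stats::rnorm(cf$N, 0, cf$patch_offset_sd)

  per_patch <- cf$atrophy_unit == "patch"
  n_units <- if (per_patch) cf$N else cf$V
  gen_subject <- function(idx, is_patient) {
    set.seed(.substream_seed(cf$seed, idx))
    b <- stats::rnorm(1, 0, cf$base_sd_between)
    pdev <- stats::rnorm(cf$N, 0, cf$patch_sd_within)
    f <- cf$atrophy_patch_fraction
    propensity <- if (f > 0 && f < 1)
      stats::rbeta(1, cf$atrophy_heterogeneity,
                   cf$atrophy_heterogeneity * (1 - f) / f) else f
    atroph <- stats::runif(n_units) < propensity
    noise <- stats::rnorm(cf$V, 0, cf$vertex_noise_sd)
    mu <- cf$base_mean + b + patch_offset + pdev
    values <- mu[scheme$labels] + noise
    eps <- stats::rnorm(2)
    age <- if (is_patient) stats::rnorm(1, 40.14, 9.94) else
      stats::rnorm(1, 37.36, 15.06)
    age <- min(max(age, 18), 85)
    sex <- if (stats::runif(1) < 0.66) "F" else "M"
    duration <- max(stats::rnorm(1, 8.65, 5.16), 0.1)
    list(values = values, atroph = atroph, eps = eps,
         age = age, sex = sex, duration = duration)
  }

  ctl <- lapply(seq_len(cf$n_controls), gen_subject, is_patient = FALSE)
  pat <- lapply(cf$n_controls + seq_len(cf$n_patients), gen_subject,
                is_patient = TRUE)

  ctl_ids <- sprintf("hc%03d", seq_len(cf$n_controls))
  pat_ids <- sprintf("ms%03d", seq_len(cf$n_patients))

  ctl_maps <- lapply(seq_along(ctl), function(i)
    vertex_map(pmax(ctl[[i]]$values, 0.05), ctl_ids[i]))

  # empirical reference spread, the unit for the injected atrophy depth
  ref <- fit_reference(lapply(ctl_maps, patch_means, scheme = scheme,
                              mask = mask))
  unit_sd <- if (per_patch) ref$patch_sd_ref else {
    Yc <- do.call(rbind, lapply(ctl_maps, `[[`, "values"))
    .col_mean_sd(Yc)$sd
  }

  atrophic <- vector("list", cf$n_patients)
  pat_maps <- vector("list", cf$n_patients)
  for (i in seq_len(cf$n_patients)) {
    vals <- pat[[i]]$values
    idx <- which(pat[[i]]$atroph)
    if (length(idx) > 0) {
      if (per_patch) {
        hit <- scheme$labels %in% idx
        vals[hit] <- vals[hit] - cf$atrophy_effect * unit_sd[scheme$labels[hit]]
      } else {
        vals[idx] <- vals[idx] - cf$atrophy_effect * unit_sd[idx]
      }
    }
    atrophic[[i]] <- idx
    pat_maps[[i]] <- vertex_map(pmax(vals, 0.05), pat_ids[i])
  }
  burden <- lengths(atrophic) / n_units

  # clinical variables, coupled to realized burden through a Gaussian copula
  zb <- if (cf$n_patients >= 2 && stats::sd(burden) > 0)
    as.vector(scale(burden)) else rep(0, cf$n_patients)
  eps1 <- vapply(pat, function(s) s$eps[1], 0)
  eps2 <- vapply(pat, function(s) s$eps[2], 0)
  z_lv <- c_lv * zb + sqrt(1 - c_lv^2) * eps1
  lv <- stats::qlnorm(stats::pnorm(z_lv), meanlog_lv, sdlog_lv)
  z_ed <- c_edss * zb + sqrt(1 - c_edss^2) * eps2
  edss_raw <- stats::qlnorm(stats::pnorm(z_ed), log(1.5), sdlog_edss)
  edss <- pmin(pmax(round(edss_raw * 2) / 2, 0), 10)

  cohort <- as_cohort_table(data.frame(
    subject_id = c(pat_ids, ctl_ids),
    group = rep(c("patient", "control"), c(cf$n_patients, cf$n_controls)),
    age = c(vapply(pat, `[[`, 0, "age"), vapply(ctl, `[[`, 0, "age")),
    sex = c(vapply(pat, `[[`, "", "sex"), vapply(ctl, `[[`, "", "sex")),
    lesion_volume = c(lv, rep(NA_real_, cf$n_controls)),
    edss = c(edss, rep(NA_real_, cf$n_controls)),
    disease_duration = c(vapply(pat, `[[`, 0, "duration"),
                         rep(NA_real_, cf$n_controls)),
    stringsAsFactors = FALSE))

  maps <- c(pat_maps, ctl_maps)
  names(maps) <- c(pat_ids, ctl_ids)
  structure(list(maps = maps, cohort = cohort, scheme = scheme, mask = mask,
                 mesh = mesh,
                 ground_truth = list(atrophic = stats::setNames(atrophic,
                                                                pat_ids),
                                     burden = stats::setNames(burden,
                                                              pat_ids),
                                     unit = cf$atrophy_unit),
                 config = cf),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cf <- x$config
  cat(sprintf(paste0("<simulated_cohort> %d patients + %d controls, V = %d, ",
                     "N = %d, atrophy effect %.3g SD at fraction %.3g (%s level)\n"),
              cf$n_patients, cf$n_controls, cf$V, cf$N, cf$atrophy_effect,
              cf$atrophy_patch_fraction, cf$atrophy_unit))
  invisible(x)
}

#' True (generating) atrophy burden of a simulated patient
#'
#' The realized fraction of atrophic units (patches or vertices) injected
#' into that patient -- the realized draw, not its expectation.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param subject patient subject id (e.g. `"ms001"`).
#' @return ratio in `[0, 1]`.
#' @export
true_burden <- function(cohort, subject) {
  .assert(inherits(cohort, "simulated_cohort"),
          "cohort must come from simulate_cohort()")
  if (!subject %in% names(cohort$ground_truth$burden)) {
    grp <- cohort$cohort$group[match(subject, cohort$cohort$subject_id)]
    if (identical(grp, "control"))
      stop("subject '", subject, "' is a control; true burden is only ",
           "defined for patients", call. = FALSE)
    stop("unknown subject: ", subject, call. = FALSE)
  }
  unname(cohort$ground_truth$burden[subject])
}

#' Patient / control vertex maps of a simulated cohort
#' @param cohort a [simulate_cohort()] result.
#' @return named list of [vertex_map()]s.
#' @export
patient_maps <- function(cohort) {
  ids <- cohort$cohort$subject_id[cohort$cohort$group == "patient"]
  cohort$maps[ids]
}

#' @rdname patient_maps
#' @export
control_maps <- function(cohort) {
  ids <- cohort$cohort$subject_id[cohort$cohort$group == "control"]
  cohort$maps[ids]
}
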