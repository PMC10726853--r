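# parcellate: reduce vertexwise thickness to patch means.

#' Patch-averaged thickness profile
#'
#' Averages all masked vertices of each patch (unweighted arithmetic mean).
#' Vertices labeled 0 or outside the mask never contribute. Patches left
#' without any contributing vertex get `NA` mean and size 0 and are treated
#' as not evaluable downstream.
#'
#' @param map a [vertex_map()].
#' @param scheme a [parcellation()] on the same vertex set.
#' @param mask optional [cortical_mask()] (default: all vertices included).
#' @return object of class `patch_profile` with `subject_id`,
#'   `patch_means` (length N, mm) and `patch_sizes` (contributing vertex
#'   counts).
#' @export
patch_means <- function(map, scheme, mask = NULL) {
  .assert(inherits(map, "vertex_map"), "map must be a vertex_map")
  .assert(inherits(scheme, "parcellation"), "scheme must be a parcellation")
  v <- map$vertex_count
  if (length(scheme$labels) != v)
    stop(sprintf("parcellation has %d vertices but map has %d",
                 length(scheme$labels), v), call. = FALSE)
  m <- .as_mask(mask, v)
  use <- m & scheme$labels > 0L
  n <- scheme$n_patches
  sizes <- tabulate(scheme$labels[use], nbins = n)
  sums <- rep(0, n)
  if (any(use)) {
    agg <- rowsum(map$values[use], group = scheme$labels[use])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  means <- ifelse(sizes > 0L, sums / sizes, NA_real_)
  structure(list(subject_id = map$subject_id,
                 patch_means = means,
                 patch_sizes = sizes),
            class = "patch_profile")
}

#' Construct a patch profile from precomputed patch means
#'
#' For data already aggregated at parcel level (the usual product of
#' [patch_means()]); `NA` means are allowed only where the size is 0.
#'
#' @param means numeric vector of per-patch mean thickness, mm.
#' @param sizes contributing vertex counts (default 1 per patch).
#' @param subject_id subject identifier.
#' @return a `patch_profile`.
#' @export
patch_profile <- function(means, sizes = rep(1L, length(means)),
                          subject_id = "subject") {
  .assert(length(means) == length(sizes),
          "means and sizes must have the same length")
  .assert(all(is.finite(means[sizes > 0])),
          "patch means must be finite wherever sizes > 0")
  structure(list(subject_id = as.character(subject_id),
                 patch_means = as.double(means),
                 patch_sizes = as.integer(sizes)),
            class = "patch_profile")
}

#' @export
print.patch_profile <- function(x, ...) {
  cat(sprintf("<patch_profile> subject '%s': %d patches (%d evaluable), mean %.3f mm\n",
              x$subject_id, length(x$patch_means), sum(x$patch_sizes > 0),
              mean(x$patch_means, na.rm = TRUE)))
  invisible(x)
}

#' Identity parcellation (each masked vertex is its own patch)
#'
#' Masked vertices receive consecutive labels 1..M in vertex order;
#' unmasked vertices get label 0.
#'
#' @param mask a [cortical_mask()] or logical vector.
#' @return a [parcellation()].
#' @export
identity_parcellation <- function(mask) {
  m <- as.logical(unclass(mask))
  .assert(length(m) > 0 && !anyNA(m), "mask must be a logical vector")
  .assert(any(m), "identity_parcellation: mask is empty")
  labels <- integer(length(m))
  labels[m] <- seq_len(sum(m))
  parcellation(labels)
}
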