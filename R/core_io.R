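# core_io: domain containers and file formats (GIFTI shape/label, CSV).

# Constructors ---------------------------------------------------------------

#' Per-vertex cortical thickness map
#'
#' One subject's cortical thickness (mm) on a fixed vertex set, both
#' hemispheres concatenated (left then right).
#'
#' @param values numeric vector of thickness values in mm, one per vertex.
#' @param subject_id subject identifier.
#' @return object of class `vertex_map` with fields `subject_id`, `values`,
#'   and `vertex_count`.
#' @export
vertex_map <- function(values, subject_id = "subject") {
  values <- as.double(values)
  .assert(length(values) > 0, "vertex_map: values must be non-empty")
  bad <- which(!is.finite(values))
  if (length(bad) > 0)
    stop("vertex_map: non-finite thickness values at vertex indices ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ..." else "", call. = FALSE)
  .assert(all(values >= 0), "vertex_map: thickness values must be >= 0")
  structure(list(subject_id = as.character(subject_id),
                 values = values,
                 vertex_count = length(values)),
            class = "vertex_map")
}

#' @export
print.vertex_map <- function(x, ...) {
  cat(sprintf("<vertex_map> subject '%s': %d vertices, mean %.3f mm (SD %.3f)\n",
              x$subject_id, x$vertex_count, mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Cortical parcellation scheme
#'
#' Integer patch label per vertex; label 0 marks unassigned vertices
#' (medial wall) and is excluded from every statistic.
#'
#' @param labels integer vector, one label in `0..n_patches` per vertex.
#' @param patch_names optional character vector of patch names, length
#'   `n_patches`.
#' @return object of class `parcellation` with fields `labels`, `n_patches`,
#'   `patch_sizes` (vertex census per patch), `empty_patches` and optional
#'   `patch_names`.
#' @export
parcellation <- function(labels, patch_names = NULL) {
  labels <- as.integer(labels)
  .assert(length(labels) > 0, "parcellation: labels must be non-empty")
  .assert(!anyNA(labels), "parcellation: labels must not contain NA")
  if (any(labels < 0))
    stop("parcellation: negative labels at vertex indices ",
         paste(utils::head(which(labels < 0), 10), collapse = ", "),
         call. = FALSE)
  n <- max(labels, 0L)
  sizes <- tabulate(labels, nbins = n)
  if (!is.null(patch_names))
    .assert(length(patch_names) == n,
            "parcellation: patch_names must have length n_patches")
  structure(list(labels = labels, n_patches = n,
                 patch_sizes = sizes,
                 empty_patches = which(sizes == 0L),
                 patch_names = patch_names),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> N = %d patches over %d vertices (%d unassigned, %d empty patches)\n",
              x$n_patches, length(x$labels), sum(x$labels == 0L),
              length(x$empty_patches)))
  invisible(x)
}

#' Cortical mask
#'
#' Logical inclusion vector over vertices; excluded vertices take no part
#' in any statistic.
#'
#' @param include logical vector, TRUE for vertices inside the mask.
#' @return object of class `cortical_mask` (a logical vector).
#' @export
cortical_mask <- function(include) {
  include <- as.logical(include)
  .assert(!anyNA(include), "cortical_mask: NA not allowed")
  .assert(any(include), "cortical_mask: at least one vertex must be included")
  structure(include, class = "cortical_mask")
}

#' @noRd
.as_mask <- function(mask, v) {
  if (is.null(mask)) return(rep(TRUE, v))
  m <- as.logical(unclass(mask))
  .assert(length(m) == v,
          sprintf("mask length (%d) does not match vertex count (%d)",
                  length(m), v))
  m
}

# Readers --------------------------------------------------------------------

#' @noRd
.guess_format <- function(path, kinds) {
  if (grepl("\\.gii$", path, ignore.case = TRUE)) kinds[1] else "csv"
}

#' Read a per-vertex thickness map
#'
#' @param path file path: a GIFTI `.shape.gii` (or any `.gii` holding a
#'   single scalar array) or a CSV with one numeric column.
#' @param format `"auto"` (by extension), `"gifti-shape"` or `"csv"`.
#' @param subject_id subject identifier; defaults to the file basename.
#' @return a [vertex_map()].
#' @export
read_vertex_map <- function(path, format = c("auto", "gifti-shape", "csv"),
                            subject_id = NULL) {
  format <- match.arg(format)
  .assert(file.exists(path), paste0("file not found: ", path))
  if (format == "auto") format <- .guess_format(path, "gifti-shape")
  if (is.null(subject_id))
    subject_id <- sub("\\.(shape\\.)?gii$|\\.csv$", "",
                      basename(path), ignore.case = TRUE)
  vals <- if (format == "gifti-shape") {
    .read_gifti_array(path)$values
  } else {
    df <- utils::read.csv(path, header = TRUE)
    .assert(ncol(df) >= 1, paste0("empty CSV: ", path))
    col <- if ("thickness" %in% names(df)) df[["thickness"]] else df[[1]]
    suppressWarnings(as.double(col))
  }
  bad <- which(!is.finite(vals))
  if (length(bad) > 0)
    stop("non-finite thickness values in ", path, " at row(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  vertex_map(vals, subject_id)
}

#' Write a per-vertex thickness map
#'
#' @param map a [vertex_map()].
#' @param path destination (`.gii` or `.csv`).
#' @param format `"auto"`, `"gifti-shape"` or `"csv"`.
#' @return the path, invisibly.
#' @export
write_vertex_map <- function(map, path,
                             format = c("auto", "gifti-shape", "csv")) {
  format <- match.arg(format)
  .assert(inherits(map, "vertex_map"), "map must be a vertex_map")
  if (format == "auto") format <- .guess_format(path, "gifti-shape")
  if (format == "gifti-shape") {
    .write_gifti_array(map$values, path, intent = "NIFTI_INTENT_SHAPE",
                       dtype = "NIFTI_TYPE_FLOAT64")
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(c("thickness", sprintf("%.17g", map$values)), con)
  }
  invisible(path)
}

#' Read a parcellation label file
#'
#' Patch count is the maximum label; vertices labeled 0 are recorded as
#' unassigned and patches with no vertices are flagged empty.
#'
#' @param path GIFTI `.label.gii` or CSV with one integer column.
#' @param format `"auto"`, `"gifti-label"` or `"csv"`.
#' @param vertex_map optional companion [vertex_map()]; a vertex-count
#'   mismatch raises a consistency error.
#' @return a [parcellation()].
#' @export
read_parcellation <- function(path, format = c("auto", "gifti-label", "csv"),
                              vertex_map = NULL) {
  format <- match.arg(format)
  .assert(file.exists(path), paste0("file not found: ", path))
  if (format == "auto") format <- .guess_format(path, "gifti-label")
  patch_names <- NULL
  if (format == "gifti-label") {
    arr <- .read_gifti_array(path)
    labels <- arr$values
    if (!is.null(arr$label_table)) {
      lt <- arr$label_table[arr$label_table$key > 0, , drop = FALSE]
      if (nrow(lt) > 0 && max(lt$key) == max(labels, 0)) {
        patch_names <- rep(NA_character_, max(labels, 0))
        patch_names[lt$key] <- lt$name
      }
    }
  } else {
    df <- utils::read.csv(path, header = TRUE)
    labels <- suppressWarnings(as.integer(df[[1]]))
    .assert(!anyNA(labels), paste0("non-integer labels in ", path))
  }
  if (!is.null(vertex_map) &&
      length(labels) != vertex_map$vertex_count)
    stop(sprintf("parcellation has %d vertices but vertex map has %d",
                 length(labels), vertex_map$vertex_count), call. = FALSE)
  parcellation(labels, patch_names)
}

#' Write a parcellation label file
#'
#' @param scheme a [parcellation()].
#' @param path destination (`.gii` or `.csv`).
#' @param format `"auto"`, `"gifti-label"` or `"csv"`.
#' @return the path, invisibly.
#' @export
write_parcellation <- function(scheme, path,
                               format = c("auto", "gifti-label", "csv")) {
  format <- match.arg(format)
  .assert(inherits(scheme, "parcellation"), "scheme must be a parcellation")
  if (format == "auto") format <- .guess_format(path, "gifti-label")
  if (format == "gifti-label") {
    nm <- scheme$patch_names
    if (is.null(nm)) nm <- sprintf("patch_%d", seq_len(scheme$n_patches))
    lt <- data.frame(key = c(0L, seq_len(scheme$n_patches)),
                     name = c("unassigned", nm))
    .write_gifti_array(scheme$labels, path, intent = "NIFTI_INTENT_LABEL",
                       dtype = "NIFTI_TYPE_INT32", label_table = lt)
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(c("label", format(scheme$labels, scientific = FALSE)), con)
  }
  invisible(path)
}

# Cohort table ---------------------------------------------------------------

#' Read a cohort table
#'
#' CSV with mandatory columns `subject_id`, `group`, `age`, `sex` and
#' optional clinical columns `lesion_volume` (mL), `edss` (0-10 in 0.5
#' steps) and `disease_duration` (years). Group values are normalized
#' case-insensitively to `"patient"`/`"control"`.
#'
#' @param path CSV file path.
#' @return a `data.frame` of class `cohort_table`.
#' @export
read_cohort <- function(path) {
  .assert(file.exists(path), paste0("file not found: ", path))
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       group = "character",
                                       sex = "character"))
  as_cohort_table(df)
}

#' Validate a data frame as a cohort table
#'
#' @param df data.frame with the columns described in [read_cohort()].
#' @return a `data.frame` of class `cohort_table`.
#' @export
as_cohort_table <- function(df) {
  req <- c("subject_id", "group", "age", "sex")
  missing_cols <- setdiff(req, names(df))
  .assert(length(missing_cols) == 0,
          paste0("cohort table missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup) > 0)
    stop("duplicate subject_id in cohort table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  grp <- tolower(trimws(df$group))
  ok <- grp %in% c("patient", "control")
  .assert(all(ok), paste0("unrecognized group value(s): ",
                          paste(unique(df$group[!ok]), collapse = ", "),
                          " (expected patient/control)"))
  df$group <- grp
  df$sex <- toupper(trimws(df$sex))
  .assert(all(df$sex %in% c("F", "M")), "sex must be F or M")
  df$age <- as.double(df$age)
  if ("edss" %in% names(df)) {
    e <- df$edss[!is.na(df$edss)]
    if (any(e < 0 | e > 10))
      stop("EDSS outside [0, 10] in cohort table", call. = FALSE)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects (%d patients, %d controls)\n",
              nrow(x), sum(x$group == "patient"), sum(x$group == "control")))
  NextMethod()
}

# Result table ---------------------------------------------------------------

#' Write a per-patch atrophy result table
#'
#' One row per patch (`patch_id`, `n_vertices`, `z`, `p`, `thin`), with the
#' run metadata (N, alpha, reference size, thin-patch fraction) in `#`
#' comment lines before the header. Numbers are written at full double
#' precision so the file rereads to an equal structure.
#'
#' @param result an `atrophy_result` from [run_map_subject()].
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
write_result_table <- function(result, path) {
  .assert(inherits(result, "atrophy_result"), "result must be an atrophy_result")
  n <- length(result$z)
  if (n == 0) warning("writing an empty result table (header only)")
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject_id,%s", result$subject_id),
    sprintf("# n_patches,%d", n),
    sprintf("# alpha,%.17g", result$alpha),
    sprintf("# n_reference,%d", result$n_permutations - 1L),
    sprintf("# correction,%s", result$correction),
    sprintf("# thin_patch_fraction,%.17g", result$thin_patch_fraction),
    "patch_id,n_vertices,z,p,thin"), con)
  if (n > 0) {
    fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
    writeLines(sprintf("%d,%d,%s,%s,%d",
                       seq_len(n), result$patch_sizes,
                       fmt(result$z), fmt(result$p),
                       as.integer(result$thin)), con)
  }
  invisible(path)
}

#' Read a per-patch atrophy result table written by [write_result_table()]
#'
#' @param path CSV path.
#' @return data.frame with columns `patch_id`, `n_vertices`, `z`, `p`,
#'   `thin`; run metadata in attribute `"meta"`.
#' @export
read_result_table <- function(path) {
  .assert(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#\\s*", "", meta_lines), ",", fixed = TRUE)
  meta <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)],
                                     collapse = "\n"))
  df$thin <- as.logical(df$thin)
  attr(df, "meta") <- meta
  df
}
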