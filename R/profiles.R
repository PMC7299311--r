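#' Align raw values with the direction of disease progression
#'
#' Multiplies each continuous variable by its severity direction `d_v`, so
#' that higher transformed values always mean greater severity
#' (`Y[i,v,t] = d_v * X[i,v,t]`). Binary and genotype variables pass through
#' unchanged. Applying the transform to an already-directed array with
#' `d_v = +1` is the identity; with `d_v = -1` twice it is the identity.
#'
#' @param cohort A [longitudinal_cohort()].
#' @return A cohort with the same shape and metadata, values directed.
#' @export
apply_direction <- function(cohort) {
  vals <- cohort$values
  for (v in cohort$variables) {
    if (v$kind != "continuous") next
    if (is.null(v$direction)) stop("missing direction for '", v$name, "'")
    vals[, v$name, ] <- v$direction * vals[, v$name, ]
  }
  longitudinal_cohort(vals, cohort$patient_ids, cohort$timepoints,
                      cohort$variables)
}

#' Baseline-median severity thresholds from training data
#'
#' For each continuous variable, the threshold `theta_v` is the median of the
#' direction-aligned baseline values over the training patients (even-sized
#' samples use the mean of the two central order statistics). Thresholds are
#' computed from training data only and reused verbatim for test patients.
#'
#' @param train A direction-aligned training [longitudinal_cohort()].
#' @return An object of class `threshold_set`: named numeric `theta` over the
#'   continuous variables and `source_n`, the training size used.
#' @export
compute_thresholds <- function(train) {
  n <- length(train$patient_ids)
  if (n == 0L) stop("empty training set")
  cont <- names(train$variables)[vapply(train$variables,
                                        function(v) v$kind == "continuous",
                                        logical(1))]
  theta <- vapply(cont, function(v) {
    x <- train$values[, v, 1]
    if (anyNA(x)) stop("missing baseline value for '", v, "'")
    stats::median(x)
  }, numeric(1))
  if (any(!is.finite(theta))) stop("non-finite threshold computed")
  structure(list(theta = theta, source_n = n), class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> %d baseline medians from n=%d training patients\n",
              length(x$theta), x$source_n))
  invisible(x)
}

#' Profile column layout for a variable set
#'
#' Trajectory profiles have one binary column per continuous or binary
#' variable and one per genotype class of each genotype locus (one-hot
#' encoding, so a biallelic SNP contributes three columns).
#'
#' @param variables List of [variable_spec()] objects.
#' @return A data.frame with one row per profile column: `column` (label),
#'   `variable`, `kind`, `class` (genotype class or `NA`), `static`,
#'   `domain_group`.
#' @export
profile_columns <- function(variables) {
  rows <- lapply(variables, function(v) {
    if (v$kind == "genotype") {
      data.frame(column = paste0(v$name, "=", v$genotype_classes),
                 variable = v$name, kind = v$kind,
                 class = v$genotype_classes, static = v$static,
                 domain_group = v$domain_group, stringsAsFactors = FALSE)
    } else {
      data.frame(column = v$name, variable = v$name, kind = v$kind,
                 class = NA_character_, static = v$static,
                 domain_group = v$domain_group, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Build binary trajectory profiles
#'
#' Converts a direction-aligned cohort into per-patient binary profile
#' matrices `T^i` (columns x timepoints): a continuous entry is 1 iff the
#' value strictly exceeds the training baseline-median threshold (values
#' exactly at the median score 0), a binary entry is copied, and a genotype
#' value becomes a one-hot indicator over its classes, replicated across all
#' timepoints. Static columns are therefore constant in time and are counted
#' once per timepoint by the downstream similarity score.
#'
#' @param cohort A direction-aligned [longitudinal_cohort()] (train or test).
#' @param thresholds A [compute_thresholds()] result fit on training data.
#' @return An object of class `trajectory_profiles`: binary array
#'   N x V' x M with attributes `columns` (the [profile_columns()] table) and
#'   the cohort's timepoints.
#' @export
build_trajectory_profiles <- function(cohort, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  cols <- profile_columns(cohort$variables)
  n <- length(cohort$patient_ids)
  m <- length(cohort$timepoints)
  T_arr <- array(NA_real_, c(n, nrow(cols), m),
                 dimnames = list(cohort$patient_ids, cols$column,
                                 cohort$timepoints))
  for (k in seq_len(nrow(cols))) {
    v <- cohort$variables[[cols$variable[k]]]
    x <- cohort$values[, v$name, , drop = FALSE]
    dim(x) <- c(n, m)
    T_arr[, k, ] <- switch(
      v$kind,
      continuous = {
        th <- thresholds$theta[[v$name]]
        if (is.null(th)) stop("no threshold for continuous variable '", v$name, "'")
        (x > th) + 0
      },
      binary = x,
      genotype = (x == match(cols$class[k], v$genotype_classes)) + 0
    )
  }
  if (anyNA(T_arr)) stop("missing values in profile input; run complete_case_filter()")
  structure(T_arr, class = "trajectory_profiles", columns = cols,
            timepoints = cohort$timepoints)
}

#' @export
print.trajectory_profiles <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<trajectory_profiles> %d patients x %d columns x %d timepoints\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Extract one patient's trajectory profile matrix
#'
#' @param profiles A [build_trajectory_profiles()] result.
#' @param patient Patient id or index.
#' @return A V' x M binary matrix (columns x timepoints).
#' @export
trajectory_profile <- function(profiles, patient) {
  if (is.character(patient)) patient <- match(patient, dimnames(profiles)[[1]])
  if (is.na(patient)) stop("unknown patient")
  out <- profiles[patient, , ]
  dim(out) <- dim(profiles)[2:3]
  dimnames(out) <- dimnames(profiles)[2:3]
  out
}
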