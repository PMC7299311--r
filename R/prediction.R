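#' Assign a patient to the nearest subtype at one timepoint
#'
#' Computes, for each retained subtype, the squared Euclidean distance
#' between the patient's binary profile column vector at timepoint `t` and
#' the subtype's profile at `t`:
#' `d_t(i, l) = sum over v of (T[v,t] - S_l[v,t])^2`. No square root is
#' taken; the argmin is unaffected. By default the normalized subtype
#' profile `S` is used (entries may exceed 1); `profile = "affected_fraction"`
#' compares against the unnormalized fraction instead. Columns whose
#' normalizer `U_v0` is zero are excluded from the sum for every subtype
#' symmetrically. Ties go to the lowest community id and are flagged.
#'
#' @param profile_matrix A single patient's V' x M binary profile
#'   (see [trajectory_profile()]).
#' @param t Timepoint index (1 = baseline) or timepoint label.
#' @param subtypes A [subtype_profiles()] list (retained communities only).
#' @param profile Which subtype matrix to compare against: `"normalized"`
#'   (default) or `"affected_fraction"`.
#' @return An object of class `subtype_assignment`: `distances` (named by
#'   community id), `assigned`, `tie_flag`, `timepoint`.
#' @export
assign_at_time <- function(profile_matrix, t, subtypes,
                           profile = c("normalized", "affected_fraction")) {
  profile <- match.arg(profile)
  if (length(subtypes) == 0L) stop("no retained subtypes to assign to")
  if (is.character(t)) t <- match(t, colnames(profile_matrix))
  if (is.na(t) || t < 1L || t > ncol(profile_matrix)) stop("invalid timepoint")
  # columns with undefined S are dropped for all subtypes symmetrically
  drop_cols <- unique(unlist(lapply(subtypes, `[[`, "undefined_columns")))
  keep <- !(rownames(profile_matrix) %in% drop_cols)
  x <- profile_matrix[keep, t]
  d <- vapply(subtypes, function(sp) {
    ref <- switch(profile, normalized = sp$S, affected_fraction = sp$affected_fraction)
    sum((x - ref[keep, t])^2)
  }, numeric(1))
  ids <- vapply(subtypes, function(sp) as.integer(sp$community_id), integer(1))
  names(d) <- ids
  best <- d == min(d)
  assigned <- min(ids[best])
  structure(
    list(distances = d, assigned = assigned, tie_flag = sum(best) > 1L,
         timepoint = t),
    class = "subtype_assignment"
  )
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("<subtype_assignment> t=%d -> subtype %d (d = %.4g%s)\n",
              x$timepoint, x$assigned, x$distances[as.character(x$assigned)],
              if (x$tie_flag) ", tie" else ""))
  invisible(x)
}

#' Assign every patient in a profile array at one timepoint
#'
#' @param profiles A `trajectory_profiles` array (e.g. test patients profiled
#'   with training thresholds).
#' @inheritParams assign_at_time
#' @return Named list of [assign_at_time()] results, one per patient.
#' @export
assign_cohort_at_time <- function(profiles, t, subtypes,
                                  profile = c("normalized", "affected_fraction")) {
  profile <- match.arg(profile)
  ids <- dimnames(profiles)[[1]]
  stats::setNames(
    lapply(ids, function(p) {
      assign_at_time(trajectory_profile(profiles, p), t, subtypes, profile)
    }),
    ids
  )
}

#' Baseline-to-final subtype prediction accuracy
#'
#' A held-out patient's prediction is successful when the subtype nearest to
#' their baseline profile equals the subtype nearest to their profile at the
#' final timepoint; accuracy is the fraction of successful test patients.
#'
#' @param baseline,final Named lists of [assign_at_time()] results for the
#'   same patients (e.g. from [assign_cohort_at_time()]).
#' @return An object of class `prediction_report`: `table` (per-patient
#'   predicted/final subtype, concordance, baseline distance) and `accuracy`.
#' @export
prediction_accuracy <- function(baseline, final) {
  if (!setequal(names(baseline), names(final))) {
    stop("baseline and final assignments cover different patients")
  }
  final <- final[names(baseline)]
  tab <- data.frame(
    patient_id = names(baseline),
    predicted_subtype = vapply(baseline, `[[`, integer(1), "assigned"),
    final_subtype = vapply(final, `[[`, integer(1), "assigned"),
    baseline_distance = vapply(baseline, function(a) {
      unname(a$distances[as.character(a$assigned)])
    }, numeric(1)),
    tie_flag = vapply(baseline, `[[`, logical(1), "tie_flag"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$concordant <- tab$predicted_subtype == tab$final_subtype
  structure(list(table = tab, accuracy = mean(tab$concordant)),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %d test patients, accuracy %.1f%%\n",
              nrow(x$table), 100 * x$accuracy))
  invisible(x)
}

#' Order assignments by prediction confidence
#'
#' Stable ascending sort by the distance to the assigned subtype, so the most
#' confident predictions (smallest baseline distance) come first — the
#' left-to-right patient ordering used in per-year distance panels.
#'
#' @param assignments Named list of [assign_at_time()] results.
#' @return The list reordered; ties keep their original relative order.
#' @export
rank_by_confidence <- function(assignments) {
  d <- vapply(assignments, function(a) {
    unname(a$distances[as.character(a$assigned)])
  }, numeric(1))
  assignments[order(d)]  # order() is stable
}
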