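#' Keep or drop cohort variables
#'
#' Convenience for e.g. a clinical-only analysis that excludes genotype loci.
#'
#' @param cohort A [longitudinal_cohort()].
#' @param keep Character vector of variable names to keep.
#' @return The restricted cohort.
#' @export
select_variables <- function(cohort, keep) {
  missing_v <- setdiff(keep, names(cohort$variables))
  if (length(missing_v)) {
    stop("unknown variable(s): ", paste(missing_v, collapse = ", "))
  }
  longitudinal_cohort(cohort$values[, keep, , drop = FALSE],
                      cohort$patient_ids, cohort$timepoints,
                      cohort$variables[keep])
}

#' Fit a trajectory-profile clustering model
#'
#' Runs the full training pipeline: complete-case filtering, direction
#' alignment, baseline-median thresholds, binary trajectory profiles, the
#' patient-patient agreement network, Louvain subtype detection, the
#' small-community filter, and normalized subtype profiles. Everything a
#' prediction on new patients needs is captured in the returned model.
#'
#' @param cohort Training [longitudinal_cohort()] (raw values).
#' @param seed Integer seed for the Louvain sweep order.
#' @param min_size Minimum community size retained for reporting/prediction
#'   (default 10).
#' @param weights Optional [weight_scheme()] matrix; default unit weights.
#' @param static_count_once When no explicit weights are given, build a
#'   scheme in which static columns count only at baseline.
#' @param distance_profile Default subtype matrix used by prediction
#'   distances: `"normalized"` (the S profile) or `"affected_fraction"`.
#' @param quiet Suppress progress messages.
#' @return An object of class `tpc_model`.
#' @export
fit_tpc <- function(cohort, seed = 1L, min_size = 10L, weights = NULL,
                    static_count_once = FALSE,
                    distance_profile = c("normalized", "affected_fraction"),
                    quiet = FALSE) {
  distance_profile <- match.arg(distance_profile)
  cohort <- complete_case_filter(cohort, quiet = quiet)
  directed <- apply_direction(cohort)
  thresholds <- compute_thresholds(directed)
  profiles <- build_trajectory_profiles(directed, thresholds)
  if (is.null(weights)) {
    weights <- weight_scheme(profiles, static_count_once = static_count_once)
  }
  network <- build_similarity_matrix(profiles, weights)
  partition <- filter_small(louvain_partition(network, seed = seed),
                            min_size = min_size)
  U <- baseline_normalizers(profiles)
  stp <- subtype_profiles(profiles, partition, U)
  if (!quiet) {
    message(length(partition$sizes), " communities (",
            length(partition$retained), " retained at min_size ", min_size,
            "), Q = ", round(partition$Q, 4))
  }
  structure(
    list(variables = cohort$variables, timepoints = cohort$timepoints,
         thresholds = thresholds, weights = weights, U = U,
         partition = partition, subtype_profiles = stp,
         population_profile = apply(unclass(profiles), c(2, 3), mean),
         config = list(min_size = as.integer(min_size),
                       static_count_once = isTRUE(static_count_once),
                       distance_profile = distance_profile,
                       seed = as.integer(seed)),
         version = as.character(utils::packageVersion("trajpc"))),
    class = "tpc_model"
  )
}

#' @export
print.tpc_model <- function(x, ...) {
  cat(sprintf("<tpc_model> %d subtypes retained (Q = %.4f), %d profile columns x %d timepoints\n",
              length(x$subtype_profiles), x$partition$Q,
              nrow(x$population_profile), ncol(x$population_profile)))
  invisible(x)
}

# profile a (raw) cohort with a fitted model's metadata and thresholds
profile_with_model <- function(model, cohort) {
  if (!identical(names(cohort$variables), names(model$variables))) {
    stop("cohort variables do not match the fitted model")
  }
  if (!identical(cohort$timepoints, model$timepoints)) {
    stop("cohort timepoints do not match the fitted model")
  }
  build_trajectory_profiles(apply_direction(cohort), model$thresholds)
}

#' Predict subtypes of held-out patients from baseline data
#'
#' Profiles the test patients with the *training* thresholds stored in the
#' model, assigns each to the nearest retained subtype from the baseline
#' profile, re-assigns at `final_timepoint`, and scores the fraction of
#' patients whose baseline and final assignments agree.
#'
#' @param model A [fit_tpc()] model.
#' @param cohort Test [longitudinal_cohort()] (raw values; complete cases).
#' @param final_timepoint Label or index of the later timepoint (default:
#'   the last one).
#' @param profile Override of the model's `distance_profile` setting.
#' @return A `prediction_report` (see [prediction_accuracy()]) with two
#'   extra fields: `distances`, a per-timepoint patient x subtype distance
#'   table (the per-year panel layout), and `confidence_order`, patient ids
#'   from the most to the least confident baseline assignment.
#' @export
predict_tpc <- function(model, cohort, final_timepoint = NULL,
                        profile = NULL) {
  if (length(cohort$patient_ids) == 0L) stop("empty test cohort")
  profile <- profile %||% model$config$distance_profile
  profiles <- profile_with_model(model, cohort)
  m <- length(model$timepoints)
  final_timepoint <- final_timepoint %||% m
  if (is.character(final_timepoint)) {
    final_timepoint <- match(final_timepoint, model$timepoints)
  }
  stopifnot(!is.na(final_timepoint), final_timepoint >= 1, final_timepoint <= m)

  per_t <- lapply(seq_len(m), function(t) {
    assign_cohort_at_time(profiles, t, model$subtype_profiles, profile)
  })
  report <- prediction_accuracy(per_t[[1]], per_t[[final_timepoint]])
  dist_rows <- do.call(rbind, lapply(seq_len(m), function(t) {
    do.call(rbind, lapply(names(per_t[[t]]), function(p) {
      a <- per_t[[t]][[p]]
      data.frame(patient_id = p, timepoint = model$timepoints[t],
                 subtype = as.integer(names(a$distances)),
                 distance = unname(a$distances), stringsAsFactors = FALSE)
    }))
  }))
  report$distances <- dist_rows
  report$confidence_order <- names(rank_by_confidence(per_t[[1]]))
  report$final_timepoint <- model$timepoints[final_timepoint]
  report
}

mat_to_json <- function(m) {
  list(rows = rownames(m), cols = colnames(m), values = as.numeric(m))
}

mat_from_json <- function(x) {
  matrix(unlist(x$values), nrow = length(x$rows),
         dimnames = list(unlist(x$rows), unlist(x$cols)))
}

#' Serialize a fitted model to a JSON artifact
#'
#' The artifact is self-contained and human-auditable: variable metadata,
#' thresholds, weights, normalizers, partition (labels, Q, seed), subtype
#' profiles and the population profile, at full floating-point precision.
#' [read_model_json()] restores a model whose predictions are bit-identical
#' to the in-memory original.
#'
#' @param model A [fit_tpc()] model.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  part <- model$partition
  obj <- list(
    format = "trajpc-model",
    version = model$version,
    timepoints = model$timepoints,
    variables = lapply(unname(model$variables), function(v) {
      m <- list(name = v$name, domain_group = v$domain_group, kind = v$kind,
                static = v$static)
      if (!is.null(v$direction)) m$direction <- v$direction
      if (!is.null(v$genotype_classes)) m$genotype_classes <- v$genotype_classes
      m
    }),
    thresholds = list(theta = as.list(model$thresholds$theta),
                      source_n = model$thresholds$source_n),
    weights = mat_to_json(model$weights),
    U = as.list(model$U),
    partition = list(labels = as.list(part$labels), Q = part$Q,
                     sizes = as.list(part$sizes), retained = part$retained,
                     min_size = part$min_size, seed = part$seed,
                     flagged = as.list(part$flagged %||% logical(0))),
    subtype_profiles = lapply(unname(model$subtype_profiles), function(sp) {
      list(community_id = sp$community_id, N_l = sp$N_l,
           S = mat_to_json(sp$S),
           affected_fraction = mat_to_json(sp$affected_fraction),
           undefined_columns = sp$undefined_columns)
    }),
    population_profile = mat_to_json(model$population_profile),
    config = model$config
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Restore a fitted model from a JSON artifact
#'
#' @param path Path written by [write_model_json()].
#' @return A `tpc_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "trajpc-model")) stop("not a trajpc model artifact")
  variables <- lapply(obj$variables, function(m) {
    variable_spec(m$name, m$domain_group, m$kind, direction = m$direction,
                  static = isTRUE(m$static),
                  genotype_classes = unlist(m$genotype_classes))
  })
  names(variables) <- vapply(variables, `[[`, character(1), "name")
  U <- unlist(obj$U)
  labels <- vapply(obj$partition$labels, as.integer, integer(1))
  sizes <- vapply(obj$partition$sizes, as.integer, integer(1))
  part <- structure(
    list(labels = labels,
         Q = obj$partition$Q,
         sizes = sizes,
         retained = as.integer(unlist(obj$partition$retained)),
         min_size = as.integer(obj$partition$min_size),
         seed = as.integer(obj$partition$seed),
         flagged = vapply(obj$partition$flagged, isTRUE, logical(1))),
    class = "subtype_partition"
  )
  stp <- lapply(obj$subtype_profiles, function(sp) {
    S <- mat_from_json(sp$S)
    structure(
      list(community_id = as.integer(sp$community_id),
           S = S, affected_fraction = mat_from_json(sp$affected_fraction),
           N_l = as.integer(sp$N_l), U = U[rownames(S)],
           undefined_columns = as.character(unlist(sp$undefined_columns))),
      class = "subtype_profile")
  })
  names(stp) <- vapply(stp, function(sp) as.character(sp$community_id),
                       character(1))
  w <- mat_from_json(obj$weights)
  structure(
    list(variables = variables,
         timepoints = as.character(unlist(obj$timepoints)),
         thresholds = structure(list(theta = unlist(obj$thresholds$theta),
                                     source_n = as.integer(obj$thresholds$source_n)),
                                class = "threshold_set"),
         weights = structure(w, class = c("weight_scheme", "matrix", "array")),
         U = U,
         partition = part,
         subtype_profiles = stp,
         population_profile = mat_from_json(obj$population_profile),
         config = obj$config,
         version = obj$version),
    class = "tpc_model"
  )
}

#' Subtype heatmap panels and affected-fraction tables
#'
#' Builds one grayscale heatmap per retained subtype (profile columns on the
#' x axis, timepoints on the y axis, darker = larger affected fraction, i.e.
#' a larger share of the subtype above the population baseline median in the
#' direction of disease progression) plus a total-population panel, whose
#' baseline row sits near 0.5 by construction of the median thresholds.
#'
#' @param model A [fit_tpc()] model.
#' @param out_dir Optional directory; when given, per-panel CSVs and a
#'   combined PNG are written there.
#' @return Invisibly, a list: `panels` (named list of affected-fraction
#'   matrices, including `"population"`), `plot` (a ggplot object), and any
#'   written `files`.
#' @export
report_tpc <- function(model, out_dir = NULL) {
  panels <- lapply(model$subtype_profiles, function(sp) sp$affected_fraction)
  names(panels) <- sprintf("subtype_%s_n%d",
                           names(model$subtype_profiles),
                           vapply(model$subtype_profiles, `[[`, integer(1), "N_l"))
  panels$population <- model$population_profile
  if (length(panels) == 1L) {
    message("no retained subtypes; reporting the population panel only")
  }

  long <- do.call(rbind, lapply(names(panels), function(nm) {
    m <- panels[[nm]]
    data.frame(panel = nm,
               column = factor(rep(rownames(m), ncol(m)), levels = rownames(m)),
               timepoint = factor(rep(colnames(m), each = nrow(m)),
                                  levels = rev(colnames(m))),
               affected_fraction = as.numeric(m), stringsAsFactors = FALSE)
  }))
  long$panel <- factor(long$panel, levels = names(panels))
  plt <- ggplot2::ggplot(long, ggplot2::aes(x = column, y = timepoint,
                                            fill = affected_fraction)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1), name = "affected\nfraction") +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(panels)) {
      f <- file.path(out_dir, paste0("affected_fraction_", nm, ".csv"))
      utils::write.csv(panels[[nm]], f)
      files <- c(files, f)
    }
    png_path <- file.path(out_dir, "subtype_profiles.png")
    ggplot2::ggsave(png_path, plt, width = 8,
                    height = 1.6 * length(panels) + 1, dpi = 150)
    files <- c(files, png_path)
  }
  invisible(list(panels = panels, plot = plt, files = files))
}
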