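#' Variable specification
#'
#' Describes one cohort variable: a clinical scale (continuous), a binary
#' indicator (e.g. gender coded 1 = male), or a genotype locus with a small
#' set of diploid classes (e.g. CC/CT/TT for a biallelic SNP).
#'
#' For continuous variables `direction` gives the severity sign convention
#' `d_v`: `+1` when higher raw values mean greater disease severity, `-1` when
#' higher values mean better health (e.g. cognitive scales where a high score
#' is good). Binary and genotype variables carry no direction.
#'
#' @param name Variable name, unique within a cohort.
#' @param domain_group Free-text domain label (e.g. "Cognition", "Sleep",
#'   "Demographic", "Genetic"); used to group variables in reports and to
#'   identify demographics in [compare_subtypes()].
#' @param kind One of `"continuous"`, `"binary"`, `"genotype"`.
#' @param direction `+1` or `-1`; required iff `kind = "continuous"`.
#' @param static Logical; `TRUE` when the value is constant over time
#'   (gender, genotype, and by default age).
#' @param genotype_classes Character vector of >= 2 class labels; required iff
#'   `kind = "genotype"`.
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(name, domain_group = "General",
                          kind = c("continuous", "binary", "genotype"),
                          direction = NULL, static = FALSE,
                          genotype_classes = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "continuous") {
    if (is.null(direction) || !direction %in% c(-1, 1)) {
      stop("continuous variable '", name, "' needs direction +1 or -1")
    }
  } else if (!is.null(direction)) {
    stop("direction is only defined for continuous variables ('", name, "')")
  }
  if (kind == "genotype") {
    if (is.null(genotype_classes) || length(genotype_classes) < 2L) {
      stop("genotype variable '", name, "' needs >= 2 genotype_classes")
    }
    if (anyDuplicated(genotype_classes)) {
      stop("duplicate genotype classes for '", name, "'")
    }
    static <- TRUE
  } else if (!is.null(genotype_classes)) {
    stop("genotype_classes only apply to genotype variables ('", name, "')")
  }
  structure(
    list(name = name, domain_group = domain_group, kind = kind,
         direction = if (kind == "continuous") as.integer(direction) else NULL,
         static = isTRUE(static),
         genotype_classes = if (kind == "genotype") as.character(genotype_classes) else NULL),
    class = "variable_spec"
  )
}

#' @export
print.variable_spec <- function(x, ...) {
  extra <- switch(x$kind,
    continuous = paste0("d=", sprintf("%+d", x$direction)),
    binary = "0/1",
    genotype = paste(x$genotype_classes, collapse = "/"))
  cat(sprintf("<variable_spec> %s [%s, %s%s]\n", x$name, x$kind, extra,
              if (x$static) ", static" else ""))
  invisible(x)
}

#' Longitudinal cohort
#'
#' An N-patient x V-variable x M-timepoint array of raw values `X[i, v, t]`
#' plus variable metadata. Continuous values are stored as-is, binary values
#' as 0/1, and genotype values as the integer index of the patient's class in
#' the variable's `genotype_classes`. `NA` marks a missing observation.
#'
#' @param values Numeric N x V x M array (see above for the encoding).
#' @param patient_ids Character vector of N unique patient identifiers.
#' @param timepoints Character vector of M ordered timepoint labels; the first
#'   is the baseline.
#' @param variables List of [variable_spec()] objects, one per array column.
#' @return An object of class `longitudinal_cohort`.
#' @export
longitudinal_cohort <- function(values, patient_ids, timepoints, variables) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  patient_ids <- as.character(patient_ids)
  timepoints <- as.character(timepoints)
  vnames <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(patient_ids)) stop("duplicate patient ids")
  if (anyDuplicated(timepoints)) stop("duplicate timepoint labels")
  if (anyDuplicated(vnames)) stop("duplicate variable names")
  if (length(timepoints) < 1L) stop("at least one timepoint required")
  d <- dim(values)
  if (d[1] != length(patient_ids) || d[2] != length(vnames) ||
      d[3] != length(timepoints)) {
    stop("values array dimensions do not match ids/variables/timepoints")
  }
  dimnames(values) <- list(patient_ids, vnames, timepoints)
  names(variables) <- vnames
  cohort <- structure(
    list(values = values, patient_ids = patient_ids,
         timepoints = timepoints, variables = variables),
    class = "longitudinal_cohort"
  )
  check_static_consistency(cohort)
  cohort
}

check_static_consistency <- function(cohort) {
  for (v in cohort$variables) {
    if (!v$static || length(cohort$timepoints) < 2L) next
    x <- cohort$values[, v$name, , drop = FALSE]
    rng <- apply(x, 1, function(r) {
      r <- r[!is.na(r)]
      length(unique(r)) > 1L
    })
    if (any(rng)) {
      stop("static variable '", v$name, "' varies over time for patient(s) ",
           paste(cohort$patient_ids[which(rng)], collapse = ", "))
    }
  }
  invisible(cohort)
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cat(sprintf("<longitudinal_cohort> %d patients x %d variables x %d timepoints\n",
              length(x$patient_ids), length(x$variables), length(x$timepoints)))
  cat("  timepoints:", paste(x$timepoints, collapse = ", "), "\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat("  missing cells:", nmiss, "\n")
  invisible(x)
}

#' @export
#' @rdname longitudinal_cohort
#' @param x A `longitudinal_cohort`.
#' @param i Patient index (integer, logical, or character ids).
#' @param ... Unused.
`[.longitudinal_cohort` <- function(x, i, ...) {
  idx <- seq_along(x$patient_ids)
  names(idx) <- x$patient_ids
  i <- idx[i]
  longitudinal_cohort(x$values[i, , , drop = FALSE], x$patient_ids[i],
                      x$timepoints, x$variables)
}

#' Read a cohort from a long-format CSV plus variable metadata JSON
#'
#' The CSV must have columns `patient_id, timepoint, variable, value` (one row
#' per observed cell). The metadata JSON declares the ordered timepoint labels
#' and every variable with its [variable_spec()] fields; rows whose variable
#' is not declared are rejected. Cells absent from the CSV are recorded as
#' missing. See `inst/extdata/cohort-schema.md` for the schema.
#'
#' @param table_path Path to the long-format CSV.
#' @param metadata_path Path to the metadata JSON.
#' @return A [longitudinal_cohort()].
#' @export
read_cohort <- function(table_path, metadata_path) {
  meta <- jsonlite::fromJSON(metadata_path, simplifyDataFrame = FALSE)
  if (is.null(meta$timepoints) || is.null(meta$variables)) {
    stop("metadata must declare 'timepoints' and 'variables'")
  }
  variables <- lapply(meta$variables, function(m) {
    variable_spec(name = m$name,
                  domain_group = m$domain_group %||% "General",
                  kind = m$kind,
                  direction = m$direction,
                  static = isTRUE(m$static),
                  genotype_classes = unlist(m$genotype_classes))
  })
  vnames <- vapply(variables, function(v) v$name, character(1))
  timepoints <- as.character(unlist(meta$timepoints))

  tab <- utils::read.csv(table_path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", "variable", "value")
  if (!all(need %in% names(tab))) {
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  }
  unknown <- setdiff(unique(tab$variable), vnames)
  if (length(unknown)) {
    stop("variable(s) not in metadata: ", paste(unknown, collapse = ", "))
  }
  badt <- setdiff(unique(tab$timepoint), timepoints)
  if (length(badt)) {
    stop("timepoint(s) not in metadata: ", paste(badt, collapse = ", "))
  }
  key <- paste(tab$patient_id, tab$timepoint, tab$variable, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (patient, timepoint, variable) row: ",
         gsub("\r", " / ", dup, fixed = TRUE))
  }

  patient_ids <- unique(tab$patient_id)
  vals <- array(NA_real_, c(length(patient_ids), length(vnames), length(timepoints)))
  ii <- match(tab$patient_id, patient_ids)
  vi <- match(tab$variable, vnames)
  ti <- match(tab$timepoint, timepoints)
  num <- rep(NA_real_, nrow(tab))
  for (k in seq_along(variables)) {
    sel <- vi == k
    if (!any(sel)) next
    v <- variables[[k]]
    if (v$kind == "genotype") {
      cls <- match(tab$value[sel], v$genotype_classes)
      if (anyNA(cls)) {
        stop("genotype value not in classes of '", v$name, "': ",
             paste(unique(tab$value[sel][is.na(cls)]), collapse = ", "))
      }
      num[sel] <- cls
    } else {
      x <- suppressWarnings(as.numeric(tab$value[sel]))
      if (anyNA(x) && any(!is.na(tab$value[sel]) & is.na(x))) {
        stop("non-numeric value for ", v$kind, " variable '", v$name, "'")
      }
      if (v$kind == "binary" && !all(x %in% c(0, 1, NA))) {
        stop("binary variable '", v$name, "' has values outside {0,1}")
      }
      num[sel] <- x
    }
  }
  vals[cbind(ii, vi, ti)] <- num
  longitudinal_cohort(vals, patient_ids, timepoints, variables)
}

#' Write a cohort to the long-format CSV plus metadata JSON
#'
#' Inverse of [read_cohort()]: continuous/binary values are written as
#' numbers at full precision, genotype values as their class labels; missing
#' cells are omitted.
#'
#' @param cohort A [longitudinal_cohort()].
#' @param table_path,metadata_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, table_path, metadata_path) {
  long <- expand.grid(patient_id = cohort$patient_ids,
                      timepoint = cohort$timepoints,
                      variable = names(cohort$variables),
                      stringsAsFactors = FALSE)
  ii <- match(long$patient_id, cohort$patient_ids)
  vi <- match(long$variable, names(cohort$variables))
  ti <- match(long$timepoint, cohort$timepoints)
  x <- cohort$values[cbind(ii, vi, ti)]
  keep <- !is.na(x)
  long <- long[keep, ]
  x <- x[keep]
  vi <- vi[keep]
  value <- character(length(x))
  for (k in seq_along(cohort$variables)) {
    sel <- vi == k
    if (!any(sel)) next
    v <- cohort$variables[[k]]
    value[sel] <- if (v$kind == "genotype") {
      v$genotype_classes[x[sel]]
    } else {
      format(x[sel], digits = 17, trim = TRUE, scientific = FALSE)
    }
  }
  long$value <- value
  long <- long[, c("patient_id", "timepoint", "variable", "value")]
  utils::write.csv(long, table_path, row.names = FALSE, quote = FALSE)

  meta <- list(
    timepoints = cohort$timepoints,
    variables = lapply(unname(cohort$variables), function(v) {
      m <- list(name = v$name, domain_group = v$domain_group, kind = v$kind,
                static = v$static)
      if (!is.null(v$direction)) m$direction <- v$direction
      if (!is.null(v$genotype_classes)) m$genotype_classes <- v$genotype_classes
      m
    })
  )
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(table_path, metadata_path))
}

#' Restrict a cohort to complete cases
#'
#' Drops every patient with one or more missing cells, mirroring a
#' complete-case longitudinal analysis. No imputation is performed.
#'
#' @param cohort A [longitudinal_cohort()].
#' @param quiet Suppress the message reporting how many patients were removed.
#' @return The filtered cohort.
#' @export
complete_case_filter <- function(cohort, quiet = FALSE) {
  miss <- apply(is.na(cohort$values), 1, any)
  if (all(miss)) stop("complete-case filter removed every patient")
  if (!quiet && any(miss)) {
    message(sum(miss), " of ", length(miss),
            " patients removed (incomplete data); ", sum(!miss), " retained")
  }
  if (!any(miss)) return(cohort)
  cohort[!miss]
}

#' Split a cohort into training and held-out test sets
#'
#' Samples `round_half_up(test_fraction * N)` patients uniformly without
#' replacement as the test set; the rest form the training set. Half-up
#' rounding makes a 20% split of 194 patients give exactly 39 test / 155
#' training patients.
#'
#' @param cohort A [longitudinal_cohort()].
#' @param test_fraction Fraction of patients held out, in (0, 1).
#' @param seed Integer seed; the split is reproducible for a fixed seed.
#' @return A list with class `train_test_split`: `train`, `test` (cohorts),
#'   `test_ids`, and `seed`.
#' @export
split_cohort <- function(cohort, test_fraction, seed = 1L) {
  n <- length(cohort$patient_ids)
  stopifnot(n >= 2L, test_fraction > 0, test_fraction < 1)
  n_test <- floor(test_fraction * n + 0.5)  # round half up
  if (n_test < 1L || n_test >= n) {
    stop("test_fraction ", test_fraction, " leaves an empty train or test set")
  }
  test_idx <- with_seed(seed, sort(sample.int(n, n_test)))
  structure(
    list(train = cohort[-test_idx], test = cohort[test_idx],
         test_ids = cohort$patient_ids[test_idx], seed = as.integer(seed)),
    class = "train_test_split"
  )
}

#' @export
print.train_test_split <- function(x, ...) {
  cat(sprintf("<train_test_split> train n=%d, test n=%d (seed %d)\n",
              length(x$train$patient_ids), length(x$test$patient_ids), x$seed))
  invisible(x)
}
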