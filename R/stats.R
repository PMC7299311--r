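#' Two-sided Mann-Whitney U test between two subtypes
#'
#' Rank-sum comparison of a variable's raw values between two patient groups,
#' chosen because clinical scale values routinely violate normality. For
#' small samples (combined n <= `exact_max`, no ties) the exact two-sided
#' p-value is used; otherwise the normal approximation with tie and
#' continuity correction. The method actually applied is recorded.
#'
#' @param group_a,group_b Non-empty numeric vectors of raw values.
#' @param exact_max Combined sample size up to which the exact distribution
#'   is used (default 20).
#' @return List: `p_value`, `U` (statistic for `group_a`), `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
pairwise_mwu <- function(group_a, group_b, exact_max = 20L) {
  if (length(group_a) == 0L || length(group_b) == 0L) stop("empty group")
  n <- length(group_a) + length(group_b)
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  use_exact <- n <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  p <- ht$p.value
  if (is.nan(p)) p <- 1  # zero rank variance (all values tied): no separation
  list(p_value = min(p, 1),
       U = unname(ht$statistic),
       method = if (use_exact) "exact" else "normal_approx")
}

#' Two-sided Fisher exact test for a binary variable
#'
#' Exact test on a 2x2 count table (e.g. gender by subtype pair), summing
#' hypergeometric probabilities no larger than that of the observed table.
#'
#' @param table A 2x2 matrix of nonnegative integer counts.
#' @return List: `p_value`, `odds_ratio` (conditional MLE).
#' @export
fisher_gender <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be nonnegative integers")
  }
  ht <- stats::fisher.test(table, alternative = "two.sided")
  list(p_value = ht$p.value, odds_ratio = unname(ht$estimate))
}

#' Bonferroni comparison budget for subtype contrasts
#'
#' Pairwise subtype comparisons cover each demographic variable once and
#' each evolving clinical variable at two timepoints (baseline and final),
#' giving `n_c = n_p * (V_d + 2 * V_e)` comparisons and an adjusted
#' significance level `alpha / n_c`. With 3 subtype pairs, 2 demographics and
#' 16 evolving variables this is 102 comparisons at about 5e-4.
#'
#' @param n_p Number of subtype pairs (> 0).
#' @param V_d Number of demographic variables (>= 0, not both V zero).
#' @param V_e Number of evolving clinical variables (>= 0).
#' @param alpha Overall significance level (default 0.05).
#' @return An object of class `comparison_budget` with fields `n_p`, `V_d`,
#'   `V_e`, `n_c`, `alpha`, `alpha_adjusted`.
#' @export
bonferroni_budget <- function(n_p, V_d, V_e, alpha = 0.05) {
  if (n_p <= 0 || V_d < 0 || V_e < 0 || (V_d + V_e) <= 0 ||
      alpha <= 0 || alpha >= 1) {
    stop("invalid budget inputs")
  }
  n_c <- n_p * (V_d + 2 * V_e)
  structure(
    list(n_p = as.integer(n_p), V_d = as.integer(V_d), V_e = as.integer(V_e),
         n_c = as.integer(n_c), alpha = alpha, alpha_adjusted = alpha / n_c),
    class = "comparison_budget"
  )
}

#' @export
print.comparison_budget <- function(x, ...) {
  cat(sprintf("<comparison_budget> n_c = %d comparisons, alpha_adjusted = %.3g\n",
              x$n_c, x$alpha_adjusted))
  invisible(x)
}

#' Pairwise statistical comparison of retained subtypes
#'
#' For every pair of retained subtypes: each evolving (non-static continuous,
#' non-demographic) variable is compared by Mann-Whitney U at the baseline
#' and at the final timepoint; demographic variables are compared once —
#' continuous demographics (age) by Mann-Whitney U, binary demographics
#' (gender) by Fisher's exact test. Medians and tests use the raw
#' (untransformed, undirected) values; each variable's direction is reported
#' alongside. Unadjusted p-values are returned and flagged for significance
#' against the Bonferroni-adjusted level from [bonferroni_budget()].
#'
#' @param cohort The raw (undirected) training [longitudinal_cohort()].
#' @param partition A [louvain_partition()] after [filter_small()]; needs
#'   >= 2 retained subtypes, each with >= 2 members.
#' @param alpha Overall significance level for the Bonferroni budget.
#' @param final_timepoint Label or index of the later timepoint (default:
#'   last).
#' @return List of class `subtype_comparison`: `table` (one row per
#'   comparison: block A/B/C, variable, timepoint, pair, per-subtype medians
#'   or male fractions, direction, p_value, method, significant) and
#'   `budget`.
#' @export
compare_subtypes <- function(cohort, partition, alpha = 0.05,
                             final_timepoint = NULL) {
  labs <- partition$labels[cohort$patient_ids]
  if (anyNA(labs)) stop("partition does not cover the cohort")
  retained <- partition$retained
  if (length(retained) < 2L) stop("need >= 2 retained subtypes")
  small <- vapply(retained, function(cid) sum(labs == cid) < 2L, logical(1))
  if (any(small)) {
    stop("retained subtype(s) with < 2 members: ",
         paste(retained[small], collapse = ", "))
  }
  m <- length(cohort$timepoints)
  final_timepoint <- final_timepoint %||% m
  if (is.character(final_timepoint)) {
    final_timepoint <- match(final_timepoint, cohort$timepoints)
  }
  stopifnot(!is.na(final_timepoint), final_timepoint >= 1, final_timepoint <= m)

  is_demo <- vapply(cohort$variables, function(v) {
    identical(v$domain_group, "Demographic")
  }, logical(1))
  kinds <- vapply(cohort$variables, `[[`, character(1), "kind")
  evolving <- names(cohort$variables)[kinds == "continuous" & !is_demo &
    !vapply(cohort$variables, `[[`, logical(1), "static")]
  demo_cont <- names(cohort$variables)[is_demo & kinds == "continuous"]
  demo_bin <- names(cohort$variables)[is_demo & kinds == "binary"]

  pairs <- utils::combn(retained, 2L)
  budget <- bonferroni_budget(n_p = ncol(pairs),
                              V_d = length(demo_cont) + length(demo_bin),
                              V_e = length(evolving), alpha = alpha)

  rows <- list()
  add_row <- function(block, variable, timepoint, a, b, stat_a, stat_b, dirn,
                      p, method) {
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, variable = variable, timepoint = timepoint,
      subtype_a = a, subtype_b = b, stat_a = stat_a, stat_b = stat_b,
      direction = dirn, p_value = p, method = method,
      stringsAsFactors = FALSE)
  }
  mwu_row <- function(block, vname, t_idx, a, b) {
    v <- cohort$variables[[vname]]
    xa <- cohort$values[labs == a, vname, t_idx]
    xb <- cohort$values[labs == b, vname, t_idx]
    res <- pairwise_mwu(xa, xb)
    add_row(block, vname, cohort$timepoints[t_idx], a, b,
            stats::median(xa), stats::median(xb),
            v$direction %||% NA_integer_, res$p_value, res$method)
  }
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    for (vname in evolving) mwu_row("A", vname, 1L, a, b)
    for (vname in evolving) mwu_row("B", vname, final_timepoint, a, b)
    for (vname in demo_cont) mwu_row("C", vname, 1L, a, b)
    for (vname in demo_bin) {
      xa <- cohort$values[labs == a, vname, 1L]
      xb <- cohort$values[labs == b, vname, 1L]
      tab <- rbind(c(sum(xa == 1), sum(xa == 0)),
                   c(sum(xb == 1), sum(xb == 0)))
      res <- fisher_gender(tab)
      add_row("C", vname, cohort$timepoints[1L], a, b,
              mean(xa), mean(xb), NA_integer_, res$p_value, "fisher_exact")
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < budget$alpha_adjusted
  structure(list(table = out, budget = budget), class = "subtype_comparison")
}

#' @export
print.subtype_comparison <- function(x, ...) {
  cat(sprintf("<subtype_comparison> %d comparisons, %d significant at alpha_adjusted = %.3g\n",
              nrow(x$table), sum(x$table$significant), x$budget$alpha_adjusted))
  invisible(x)
}
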