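#' Specification of one planted subtype
#'
#' A planted subtype is defined on the probability scale the pipeline itself
#' reports: `severity_curves[[v]][t]` is the target probability that a member
#' exceeds the population baseline threshold for variable `v` at timepoint
#' `t` (the subtype's expected "affected fraction"). Static binary variables
#' get a per-subtype success probability and genotype loci a per-subtype
#' class distribution.
#'
#' @param id Subtype identifier (integer).
#' @param mixing_proportion Probability that a patient belongs to this
#'   subtype; proportions must sum to 1 over all subtypes.
#' @param severity_curves Named list: continuous variable -> numeric vector
#'   of length M (or length 1 for static variables) with entries in (0, 1).
#' @param binary_probs Named list: binary variable -> success probability.
#' @param genotype_frequencies Named list: genotype locus -> named numeric
#'   distribution over its classes (sums to 1).
#' @return An object of class `subtype_sim_spec`.
#' @export
subtype_sim_spec <- function(id, mixing_proportion, severity_curves,
                             binary_probs = list(),
                             genotype_frequencies = list()) {
  stopifnot(mixing_proportion > 0, mixing_proportion <= 1)
  ok <- vapply(severity_curves, function(p) all(p > 0 & p < 1), logical(1))
  if (!all(ok)) stop("severity curve probabilities must lie in (0, 1)")
  structure(
    list(id = as.integer(id), mixing_proportion = mixing_proportion,
         severity_curves = severity_curves, binary_probs = binary_probs,
         genotype_frequencies = genotype_frequencies),
    class = "subtype_sim_spec"
  )
}

#' Specification of a synthetic longitudinal cohort
#'
#' Bundles the variable metadata, cohort dimensions, noise scale and planted
#' subtypes used by [generate_cohort()].
#'
#' The generative model for a continuous variable is a probit-spaced latent
#' Gaussian: a member of subtype `k` gets
#' `X[i,v,t] = d_v * (qnorm(p[k,v,t]) + sigma * eps)`, `eps ~ N(0, 1)`, so
#' that with the population threshold at 0 the probability of exceeding it
#' (after direction alignment) is `pnorm(qnorm(p) / sigma)` — exactly the
#' target `p` at the reference noise `sigma = 1`, shrinking toward 0.5 as
#' `sigma` grows. Static variables draw once at baseline and replicate.
#'
#' @param variables List of [variable_spec()] objects.
#' @param timepoints Character vector of M >= 2 timepoint labels.
#' @param N Number of patients (>= number of subtypes).
#' @param subtypes List of [subtype_sim_spec()]; mixing proportions sum to 1.
#' @param sigma Continuous noise scale (> 0, default 1).
#' @param seed Default RNG seed used by [generate_cohort()].
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(variables, timepoints, N, subtypes, sigma = 1,
                            seed = 1L) {
  m <- length(timepoints)
  stopifnot(m >= 2L, N >= length(subtypes), sigma > 0, length(subtypes) >= 1L)
  mix <- vapply(subtypes, `[[`, numeric(1), "mixing_proportion")
  if (abs(sum(mix) - 1) > 1e-8) stop("mixing proportions must sum to 1")
  names(variables) <- vapply(variables, `[[`, character(1), "name")
  for (v in variables) {
    for (st in subtypes) {
      if (v$kind == "continuous") {
        p <- st$severity_curves[[v$name]]
        if (is.null(p)) stop("no severity curve for '", v$name, "' in subtype ", st$id)
        if (!length(p) %in% c(1L, m)) {
          stop("severity curve for '", v$name, "' must have length 1 or M")
        }
        if (v$static && length(p) == m && length(unique(p)) > 1L) {
          stop("static variable '", v$name, "' has a time-varying curve")
        }
      } else if (v$kind == "binary") {
        if (is.null(st$binary_probs[[v$name]])) {
          stop("no probability for binary '", v$name, "' in subtype ", st$id)
        }
      } else {
        f <- st$genotype_frequencies[[v$name]]
        if (is.null(f) || !setequal(names(f), v$genotype_classes) ||
            abs(sum(f) - 1) > 1e-8) {
          stop("invalid genotype frequencies for '", v$name, "' in subtype ", st$id)
        }
      }
    }
  }
  structure(
    list(variables = variables, timepoints = as.character(timepoints),
         N = as.integer(N), subtypes = subtypes, sigma = sigma,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("<simulation_spec> N=%d, M=%d, %d variables, %d subtypes, sigma=%g\n",
              x$N, length(x$timepoints), length(x$variables),
              length(x$subtypes), x$sigma))
  invisible(x)
}

#' Generate a synthetic cohort with planted subtypes
#'
#' Draws subtype membership from the mixing proportions, then values per the
#' latent-Gaussian model described in [simulation_spec()]. All randomness
#' flows from one seeded generator with a fixed draw order, so a fixed seed
#' gives a bit-identical cohort; the caller's RNG state is untouched.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed (defaults to the spec's).
#' @return A list: `cohort` (a [longitudinal_cohort()]) and `labels`
#'   (named integer vector of true subtype ids).
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  seed <- seed %||% spec$seed
  n <- spec$N
  m <- length(spec$timepoints)
  vnames <- names(spec$variables)
  ids <- sprintf("P%04d", seq_len(n))
  mix <- vapply(spec$subtypes, `[[`, numeric(1), "mixing_proportion")
  sub_ids <- vapply(spec$subtypes, `[[`, integer(1), "id")

  out <- with_seed(seed, {
    z <- sample.int(length(spec$subtypes), n, replace = TRUE, prob = mix)
    vals <- array(NA_real_, c(n, length(vnames), m))
    for (vi in seq_along(spec$variables)) {
      v <- spec$variables[[vi]]
      for (k in seq_along(spec$subtypes)) {
        st <- spec$subtypes[[k]]
        rows <- which(z == k)
        nk <- length(rows)
        if (nk == 0L) next
        if (v$kind == "continuous") {
          p <- st$severity_curves[[v$name]]
          if (length(p) == 1L) p <- rep(p, m)
          if (v$static) {
            x <- v$direction * (stats::qnorm(p[1]) + spec$sigma * stats::rnorm(nk))
            vals[rows, vi, ] <- x
          } else {
            eps <- matrix(stats::rnorm(nk * m), nk, m)
            mu <- matrix(stats::qnorm(p), nk, m, byrow = TRUE)
            vals[rows, vi, ] <- v$direction * (mu + spec$sigma * eps)
          }
        } else if (v$kind == "binary") {
          x <- stats::rbinom(nk, 1L, st$binary_probs[[v$name]])
          if (v$static) vals[rows, vi, ] <- x
          else vals[rows, vi, ] <- matrix(stats::rbinom(nk * m, 1L,
                                          st$binary_probs[[v$name]]), nk, m)
        } else {
          f <- st$genotype_frequencies[[v$name]][v$genotype_classes]
          x <- sample.int(length(f), nk, replace = TRUE, prob = f)
          vals[rows, vi, ] <- x
        }
      }
    }
    list(z = z, vals = vals)
  })

  cohort <- longitudinal_cohort(out$vals, ids, spec$timepoints, spec$variables)
  labels <- stats::setNames(sub_ids[out$z], ids)
  list(cohort = cohort, labels = labels)
}

#' Reference synthetic cohort spec with three planted subtypes
#'
#' A packaged fixture emulating a multi-domain Parkinson's progression
#' cohort: 194 patients over 5 yearly visits (baseline + years 1-4), 17
#' evolving clinical scales across six domains (with their conventional
#' severity directions, e.g. cognitive scales scored higher-is-better),
#' static age, gender, and four biallelic SNP loci (CC/CT/TT), for 23
#' variables before one-hot genotype expansion. Three planted subtypes:
#'
#' * mild (40%): below-average affected fractions in every domain,
#'   demographics near the population average;
#' * mixed (35%): high and rising motor, autonomic, sleep and mental-health
#'   severity but good cognition; younger and predominantly female;
#' * severe (25%): above-average severity in all domains, worst in
#'   cognition; older and predominantly male.
#'
#' @param N Number of patients (default 194).
#' @param sigma Continuous noise scale (default 1, the reference
#'   calibration at which planted affected fractions are attained exactly).
#' @param seed Default seed stored in the spec.
#' @return A [simulation_spec()].
#' @export
ppmi_like_spec <- function(N = 194L, sigma = 1, seed = 1L) {
  doms <- list(
    `General PD Severity` = c("UPDRS1", "UPDRS2", "UPDRS3", "TUPDRS"),
    Disability = "SEADL",
    Cognition = c("MoCA", "HVLT", "JOLO", "SFT", "LNS", "SDM"),
    `Autonomic Function` = "SCOPA",
    Sleep = c("ESS", "RBDQ"),
    `Mental Health` = c("GDS", "STAI", "QUIP")
  )
  neg <- c("HVLT", "JOLO", "SFT", "LNS", "SDM", "MoCA", "SEADL")
  variables <- list()
  for (d in names(doms)) {
    for (v in doms[[d]]) {
      variables[[v]] <- variable_spec(v, domain_group = d, kind = "continuous",
                                      direction = if (v %in% neg) -1 else 1)
    }
  }
  variables$age <- variable_spec("age", "Demographic", "continuous",
                                 direction = 1, static = TRUE)
  variables$gender <- variable_spec("gender", "Demographic", "binary",
                                    static = TRUE)
  for (g in paste0("G", 1:4)) {
    variables[[g]] <- variable_spec(g, "Genetic", "genotype",
                                    genotype_classes = c("CC", "CT", "TT"))
  }

  m <- 5L
  evolving <- setdiff(names(variables)[vapply(variables, `[[`, character(1),
                                              "kind") == "continuous"], "age")
  cognition <- doms$Cognition
  motor <- c(doms$`General PD Severity`, doms$Disability)
  nonmotor <- c(doms$`Autonomic Function`, doms$Sleep, doms$`Mental Health`)
  ramp <- function(from, to) seq(from, to, length.out = m)
  set_levels <- function(default, ...) {
    lv <- stats::setNames(rep(list(default), length(evolving)), evolving)
    overrides <- list(...)
    for (grp in names(overrides)) {
      vars <- switch(grp, cognition = cognition, motor = motor,
                     nonmotor = nonmotor)
      lv[vars] <- list(overrides[[grp]])
    }
    lv
  }
  curves <- function(levels, age_p) c(levels, list(age = age_p))
  # mild: below-average everywhere; mixed: high motor + non-motor but good
  # cognition; severe: worst motor and cognition, non-motor impairment
  # milder than the mixed subtype (near the population average)
  mild_curves <- curves(set_levels(ramp(0.35, 0.25)), age_p = 0.5)
  mixed_curves <- curves(set_levels(ramp(0.70, 0.85),
                                    nonmotor = ramp(0.75, 0.90),
                                    cognition = rep(0.25, m)),
                         age_p = 0.30)
  severe_curves <- curves(set_levels(ramp(0.70, 0.90),
                                     nonmotor = ramp(0.45, 0.55),
                                     cognition = ramp(0.70, 0.90)),
                          age_p = 0.75)

  gt <- function(cc, ct, tt) c(CC = cc, CT = ct, TT = tt)
  subtypes <- list(
    subtype_sim_spec(1L, 0.40, mild_curves,
                     binary_probs = list(gender = 0.62),
                     genotype_frequencies = list(
                       G1 = gt(0.36, 0.48, 0.16), G2 = gt(0.30, 0.50, 0.20),
                       G3 = gt(0.36, 0.48, 0.16), G4 = gt(0.40, 0.45, 0.15))),
    subtype_sim_spec(2L, 0.35, mixed_curves,
                     binary_probs = list(gender = 0.38),
                     genotype_frequencies = list(
                       G1 = gt(0.45, 0.45, 0.10), G2 = gt(0.50, 0.40, 0.10),
                       G3 = gt(0.30, 0.50, 0.20), G4 = gt(0.25, 0.55, 0.20))),
    subtype_sim_spec(3L, 0.25, severe_curves,
                     binary_probs = list(gender = 0.80),
                     genotype_frequencies = list(
                       G1 = gt(0.25, 0.50, 0.25), G2 = gt(0.35, 0.45, 0.20),
                       G3 = gt(0.45, 0.40, 0.15), G4 = gt(0.50, 0.35, 0.15)))
  )
  simulation_spec(variables, c("bl", "y1", "y2", "y3", "y4"), N = N,
                  subtypes = subtypes, sigma = sigma, seed = seed)
}
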