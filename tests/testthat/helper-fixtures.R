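# Shared fixtures and independent oracles, built in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- tiny cohort builders ----------------------------------------------------

tiny_variables <- function() {
  list(
    variable_spec("sev", "General", "continuous", direction = 1),
    variable_spec("cog", "Cognition", "continuous", direction = -1),
    variable_spec("gender", "Demographic", "binary", static = TRUE),
    variable_spec("G1", "Genetic", "genotype",
                  genotype_classes = c("CC", "CT", "TT"))
  )
}

# cohort with n patients, m timepoints over tiny_variables(); continuous
# values drawn N(0,1), gender Bernoulli(0.5), genotype uniform over classes
tiny_cohort <- function(n = 6, m = 3, seed = 42) {
  vars <- tiny_variables()
  withr::with_seed(seed, {
    vals <- array(NA_real_, c(n, 4, m))
    vals[, 1, ] <- rnorm(n * m)
    vals[, 2, ] <- rnorm(n * m)
    vals[, 3, ] <- rbinom(n, 1, 0.5)
    vals[, 4, ] <- sample(1:3, n, replace = TRUE)
    longitudinal_cohort(vals, sprintf("p%02d", seq_len(n)),
                        paste0("t", seq_len(m) - 1L), vars)
  })
}

# continuous-only cohort from an n x v x m array of severity values (d = +1)
cont_cohort <- function(vals, static = FALSE) {
  d <- dim(vals)
  vars <- lapply(seq_len(d[2]), function(j) {
    variable_spec(paste0("v", j), "General", "continuous", direction = 1,
                  static = static)
  })
  longitudinal_cohort(vals, sprintf("p%02d", seq_len(d[1])),
                      paste0("t", seq_len(d[3]) - 1L), vars)
}

# stack two N x V x M arrays along the patient axis
abind_rows <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[2:3] == db[2:3]))
  out <- array(NA_real_, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

# --- profile / network builders ---------------------------------------------

# wrap an N x V x M binary array as a trajectory_profiles object
as_profiles <- function(arr, static = rep(FALSE, dim(arr)[2])) {
  d <- dim(arr)
  cols <- data.frame(column = paste0("c", seq_len(d[2])),
                     variable = paste0("c", seq_len(d[2])),
                     kind = "binary", class = NA_character_,
                     static = static, domain_group = "General",
                     stringsAsFactors = FALSE)
  dimnames(arr) <- list(sprintf("p%02d", seq_len(d[1])), cols$column,
                        paste0("t", seq_len(d[3]) - 1L))
  structure(arr, class = "trajectory_profiles", columns = cols,
            timepoints = dimnames(arr)[[3]])
}

random_profiles <- function(n, v, m) {
  as_profiles(array(rbinom(n * v * m, 1, 0.5), c(n, v, m)))
}

# wrap a symmetric zero-diagonal weight matrix as a patient_network
as_network <- function(A, ids = sprintf("n%02d", seq_len(nrow(A)))) {
  dimnames(A) <- list(ids, ids)
  structure(list(patient_ids = ids, P = A, total_weight = max(A)),
            class = "patient_network")
}

# block-structured network: strong within-block weights, weak between
block_network <- function(sizes, w_in = 5, w_out = 1) {
  lab <- rep(seq_along(sizes), sizes)
  n <- length(lab)
  A <- ifelse(outer(lab, lab, `==`), w_in, w_out)
  diag(A) <- 0
  list(network = as_network(A), labels = lab)
}

# subtype_partition stub for functions that only need labels + retained
fake_partition <- function(labels, retained = sort(unique(labels)),
                           ids = names(labels)) {
  if (is.null(ids)) ids <- sprintf("p%02d", seq_along(labels))
  labels <- stats::setNames(as.integer(labels), ids)
  sizes <- table(labels)
  structure(
    list(labels = labels, Q = NA_real_,
         sizes = stats::setNames(as.integer(sizes), names(sizes)),
         retained = as.integer(retained), min_size = 1L, seed = NA_integer_),
    class = "subtype_partition")
}

# --- independent oracles ------------------------------------------------------

# agreement by explicit nested loops (oracle for build_similarity_matrix)
agreement_loop <- function(profiles, w = NULL) {
  d <- dim(profiles)
  if (is.null(w)) w <- matrix(1, d[2], d[3])
  P <- matrix(0, d[1], d[1])
  for (i in seq_len(d[1])) for (j in seq_len(d[1])) {
    if (i == j) next
    acc <- 0
    for (v in seq_len(d[2])) for (t in seq_len(d[3])) {
      if (profiles[i, v, t] == profiles[j, v, t]) acc <- acc + w[v, t]
    }
    P[i, j] <- acc
  }
  dimnames(P) <- list(dimnames(profiles)[[1]], dimnames(profiles)[[1]])
  P
}

# pairwise-sum modularity (oracle route, distinct from the per-community form)
modularity_pairsum <- function(A, labels) {
  s <- rowSums(A)
  W2 <- sum(A)  # 2W
  delta <- outer(labels, labels, `==`)
  sum((A - outer(s, s) / W2) * delta) / W2
}

# all set partitions of n elements as label vectors (restricted growth strings)
set_partitions <- function(n) {
  res <- vector("list", 0)
  rgs <- integer(n)
  rec <- function(i, maxv) {
    if (i > n) {
      res[[length(res) + 1L]] <<- rgs
      return(invisible(NULL))
    }
    for (v in seq_len(maxv + 1L)) {
      rgs[i] <<- v
      rec(i + 1L, max(maxv, v))
    }
  }
  rec(1L, 0L)
  res
}

# maximum modularity over all partitions (exhaustive oracle, n <= 8)
max_modularity_exhaustive <- function(A) {
  parts <- set_partitions(nrow(A))
  best <- -Inf
  for (p in parts) best <- max(best, modularity_pairsum(A, p))
  best
}

# exact two-sided Mann-Whitney p by enumeration over all group assignments
mwu_enum_p <- function(a, b) {
  x <- c(a, b)
  n <- length(x); na <- length(a)
  r <- rank(x)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# two-sided Fisher p by hypergeometric enumeration over tables with the
# observed margins (tables at most as probable as the observed one)
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }, numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random weighted graph adjacency (symmetric, zero diagonal, connected enough)
random_graph <- function(n, p_edge = 0.6, wmax = 4) {
  A <- matrix(0, n, n)
  ut <- which(upper.tri(A))
  on <- runif(length(ut)) < p_edge
  A[ut[on]] <- sample.int(wmax, sum(on), replace = TRUE)
  A <- A + t(A)
  if (sum(A) == 0) A[1, 2] <- A[2, 1] <- 1
  A
}
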