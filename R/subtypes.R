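#' Newman-Girvan modularity of a patient partition
#'
#' Weighted modularity on the off-diagonal similarity graph:
#' `Q = sum over communities c of [ W_c / W - (s_c / (2 W))^2 ]`, where `W` is
#' the total edge weight, `W_c` the weight of edges inside community `c`, and
#' `s_c` the summed node strength of `c`. The all-in-one-community partition
#' has Q = 0 by construction; Q is bounded by [-1, 1].
#'
#' @param network A [build_similarity_matrix()] result (no self-loops).
#' @param labels Community labels, one per patient (any atomic type), in
#'   `patient_ids` order or named by patient id.
#' @return The modularity Q.
#' @export
newman_girvan_modularity <- function(network, labels) {
  P <- network$P
  n <- nrow(P)
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), network$patient_ids)) {
      stop("label names do not match the network's patients")
    }
    labels <- labels[network$patient_ids]
  }
  if (length(labels) != n || anyNA(labels)) {
    stop("need one non-missing label per patient")
  }
  W <- sum(P) / 2
  if (W <= 0) stop("graph has zero total weight")
  s <- rowSums(P)
  Q <- 0
  for (c in unique(labels)) {
    idx <- labels == c
    Wc <- sum(P[idx, idx]) / 2
    sc <- sum(s[idx])
    Q <- Q + Wc / W - (sc / (2 * W))^2
  }
  Q
}

#' Detect subtypes by Louvain modularity maximization
#'
#' Runs Louvain community detection on the weighted patient network; the
#' number of communities is not set a priori but emerges from maximizing
#' Newman-Girvan modularity. The node sweep order is randomized under `seed`,
#' so repeated runs with the same seed give identical partitions. Communities
#' are relabeled 1..K by decreasing size (ties by first member).
#'
#' @param network A [build_similarity_matrix()] result with >= 2 patients.
#' @param seed Integer seed controlling the Louvain sweep order.
#' @return An object of class `subtype_partition`: `labels` (named integer
#'   vector), `Q` (modularity of the partition, computed by
#'   [newman_girvan_modularity()]), `sizes`, `retained` (all communities until
#'   [filter_small()] is applied), `min_size`, and `seed`.
#' @export
louvain_partition <- function(network, seed = 1L) {
  if (length(network$patient_ids) < 2L) stop("need at least 2 patients")
  if (sum(network$P) <= 0) stop("graph has zero total weight")
  g <- network_graph(network)
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = 1))
  raw <- igraph::membership(comm)
  # stable relabel: 1..K by decreasing size, ties by first-encountered member
  raw <- as.character(raw)
  tab <- table(raw)
  first_seen <- vapply(names(tab), function(cm) which(raw == cm)[1L], integer(1))
  ord <- order(-as.integer(tab), first_seen)
  relab <- match(raw, names(tab)[ord])
  labels <- stats::setNames(as.integer(relab), network$patient_ids)
  new_subtype_partition(labels, network, seed = as.integer(seed))
}

new_subtype_partition <- function(labels, network, seed = NA_integer_,
                                  min_size = 1L) {
  sizes <- table(labels)
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  structure(
    list(labels = labels,
         Q = newman_girvan_modularity(network, labels),
         sizes = sizes,
         retained = sort(as.integer(names(sizes)[sizes >= min_size])),
         min_size = as.integer(min_size),
         seed = seed),
    class = "subtype_partition"
  )
}

#' @export
print.subtype_partition <- function(x, ...) {
  cat(sprintf("<subtype_partition> %d communities (Q = %.4f, seed %s)\n",
              length(x$sizes), x$Q, x$seed))
  cat("  sizes:", paste(sprintf("%s:%d", names(x$sizes), x$sizes),
                        collapse = ", "), "\n")
  if (length(x$retained) < length(x$sizes)) {
    cat("  retained (>=", x$min_size, "patients):",
        paste(x$retained, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Mark small communities as unretained for reporting and prediction
#'
#' Communities with fewer than `min_size` members keep their labels but are
#' excluded from subtype profiles and from the prediction reference set;
#' their members are flagged as unassigned-for-reporting.
#'
#' @param partition A [louvain_partition()] result.
#' @param min_size Minimum community size to retain (default 10).
#' @return The partition with updated `retained`, `min_size`, and a logical
#'   `flagged` vector marking members of unretained communities.
#' @export
filter_small <- function(partition, min_size = 10L) {
  stopifnot(inherits(partition, "subtype_partition"), min_size >= 1L)
  partition$min_size <- as.integer(min_size)
  partition$retained <- sort(as.integer(
    names(partition$sizes)[partition$sizes >= min_size]))
  partition$flagged <- !(partition$labels %in% partition$retained)
  if (length(partition$retained) == 0L) {
    warning("no community reaches min_size = ", min_size,
            "; retained set is empty")
  }
  partition
}

#' Population baseline normalizers
#'
#' `U_v0`, the mean baseline profile value of each column over the full
#' training population. Computed once on the training set and frozen; subtype
#' profiles never recompute it on their own members.
#'
#' @param profiles The training [build_trajectory_profiles()] array.
#' @return Named numeric vector over profile columns, values in [0, 1].
#' @export
baseline_normalizers <- function(profiles) {
  u <- colMeans(profiles[, , 1, drop = FALSE])
  stats::setNames(as.numeric(u), dimnames(profiles)[[2]])
}

#' Aggregate profile of one subtype
#'
#' The normalized average trajectory profile of a community:
#' `S[v,t] = sum of member T[v,t] / (N_l * U_v0)`, where `N_l` is the
#' community size and `U_v0` the population baseline normalizer. Values above
#' 1 mean the community exceeds the population-average baseline prevalence
#' for that cell. The unnormalized mean (`affected_fraction`, in [0, 1]) is
#' the quantity rendered as the grayscale in subtype heatmap panels. Columns
#' with `U_v0 = 0` have undefined S; they are flagged and excluded from
#' prediction distances.
#'
#' @param member_profiles A `trajectory_profiles` array restricted to the
#'   community's members (or the full array plus `members` indices).
#' @param U Named baseline normalizers from [baseline_normalizers()].
#' @param members Optional patient index/id vector selecting the community.
#' @param community_id Identifier stored in the result.
#' @return An object of class `subtype_profile`: `S`, `affected_fraction`
#'   (both V' x M), `N_l`, `U`, `undefined_columns`, `community_id`.
#' @export
subtype_profile <- function(member_profiles, U, members = NULL,
                            community_id = NA_integer_) {
  if (!is.null(members)) {
    if (is.character(members)) {
      members <- match(members, dimnames(member_profiles)[[1]])
    }
    member_profiles <- member_profiles[members, , , drop = FALSE]
  }
  d <- dim(member_profiles)
  if (d[1] < 1L) stop("community has no members")
  if (!identical(names(U), dimnames(member_profiles)[[2]])) {
    stop("normalizer names do not match profile columns")
  }
  af <- apply(member_profiles, c(2, 3), mean)
  S <- af / U  # recycles U down columns (rows of af are profile columns)
  S[U == 0, ] <- NA_real_
  structure(
    list(community_id = community_id, S = S, affected_fraction = af,
         N_l = d[1], U = U, undefined_columns = names(U)[U == 0]),
    class = "subtype_profile"
  )
}

#' @export
print.subtype_profile <- function(x, ...) {
  cat(sprintf("<subtype_profile> community %s, n = %d\n", x$community_id, x$N_l))
  invisible(x)
}

#' Subtype profiles for all retained communities
#'
#' @param profiles The training `trajectory_profiles` array.
#' @param partition A [louvain_partition()] (after [filter_small()]).
#' @param U Baseline normalizers; computed from `profiles` when omitted.
#' @return Named list of [subtype_profile()] objects, one per retained
#'   community.
#' @export
subtype_profiles <- function(profiles, partition, U = NULL) {
  if (is.null(U)) U <- baseline_normalizers(profiles)
  labs <- partition$labels[dimnames(profiles)[[1]]]
  if (anyNA(labs)) stop("partition does not cover all profiled patients")
  out <- lapply(partition$retained, function(cid) {
    subtype_profile(profiles, U, members = which(labs == cid),
                    community_id = cid)
  })
  stats::setNames(out, as.character(partition$retained))
}
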