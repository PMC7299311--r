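#' Column-by-timepoint weight scheme for the agreement score
#'
#' By default every (profile column, timepoint) cell carries weight 1, which
#' makes the patient-patient score a plain count of agreeing profile entries.
#' Unequal weights let callers emphasize domains or timepoints; setting
#' `static_count_once = TRUE` gives static columns (gender, genotype, static
#' age) weight only at baseline so they are not counted once per timepoint.
#'
#' @param columns A [profile_columns()] table (or a `trajectory_profiles`
#'   object, from which it is taken).
#' @param timepoints Character vector of timepoint labels.
#' @param default Baseline weight for every cell.
#' @param static_count_once Restrict static columns to the baseline timepoint.
#' @return A nonnegative V' x M weight matrix of class `weight_scheme`.
#' @export
weight_scheme <- function(columns, timepoints = NULL, default = 1,
                          static_count_once = FALSE) {
  if (inherits(columns, "trajectory_profiles")) {
    timepoints <- attr(columns, "timepoints")
    columns <- attr(columns, "columns")
  }
  stopifnot(is.data.frame(columns), !is.null(timepoints), default >= 0)
  w <- matrix(default, nrow(columns), length(timepoints),
              dimnames = list(columns$column, as.character(timepoints)))
  if (static_count_once) w[columns$static, -1] <- 0
  structure(w, class = c("weight_scheme", "matrix", "array"))
}

check_weights <- function(w, profiles) {
  d <- dim(profiles)
  if (is.null(w)) {
    w <- matrix(1, d[2], d[3], dimnames = dimnames(profiles)[2:3])
  }
  if (!is.matrix(w) || !all(dim(w) == d[2:3])) {
    stop("weight matrix must be V' x M matching the profiles")
  }
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  w
}

#' Agreement score between two trajectory profiles
#'
#' The weighted count of profile cells on which two patients agree:
#' `sum over (v, t) of w[v,t] * 1(T_a[v,t] == T_b[v,t])`. With unit weights
#' this is the number of identical entries, between 0 (bitwise complements)
#' and V'*M (identical profiles).
#'
#' @param a,b V' x M binary profile matrices with identical layout.
#' @param weights Optional V' x M weight matrix (default all 1).
#' @return A single nonnegative number.
#' @export
profile_agreement <- function(a, b, weights = NULL) {
  if (!all(dim(a) == dim(b))) stop("profile shape mismatch")
  if (!identical(dimnames(a), dimnames(b))) stop("profile label mismatch")
  d3 <- array(a, c(1, dim(a)))
  w <- check_weights(weights, structure(d3, class = "trajectory_profiles"))
  sum(w * (a == b))
}

#' Patient-patient trajectory similarity network
#'
#' Computes all pairwise [profile_agreement()] scores, giving a symmetric
#' N x N matrix `P` whose entry (i, j) is the (weighted) number of profile
#' cells on which patients i and j agree. The diagonal is set to 0: a
#' patient's self-agreement is the constant total weight and carries no
#' community information, so the clustering graph has no self-loops. The
#' dense matrix is kept unthresholded.
#'
#' @param profiles A [build_trajectory_profiles()] result (N >= 2 patients).
#' @param weights Optional [weight_scheme()] matrix.
#' @return An object of class `patient_network`: `patient_ids`, symmetric
#'   matrix `P` with zero diagonal, and `total_weight` (the maximum possible
#'   pair score, `sum(w)`).
#' @export
build_similarity_matrix <- function(profiles, weights = NULL) {
  d <- dim(profiles)
  if (d[1] < 2L) stop("need at least 2 profiles")
  w <- check_weights(weights, profiles)
  flat <- matrix(profiles, d[1], d[2] * d[3])  # N x (V'M), column-major (v, t)
  wv <- as.numeric(w)
  # agreement on binary entries: x*y + (1-x)*(1-y), weighted per cell
  bw <- sweep(flat, 2, wv, `*`)
  cw <- sweep(1 - flat, 2, wv, `*`)
  P <- tcrossprod(bw, flat) + tcrossprod(cw, 1 - flat)
  diag(P) <- 0
  dimnames(P) <- list(dimnames(profiles)[[1]], dimnames(profiles)[[1]])
  structure(
    list(patient_ids = dimnames(profiles)[[1]], P = P, total_weight = sum(w)),
    class = "patient_network"
  )
}

#' @export
print.patient_network <- function(x, ...) {
  cat(sprintf("<patient_network> %d patients, pair score range [%g, %g] of max %g\n",
              length(x$patient_ids), min(x$P[upper.tri(x$P)]),
              max(x$P[upper.tri(x$P)]), x$total_weight))
  invisible(x)
}

#' Export a patient network for external graph tools
#'
#' Writes the off-diagonal upper triangle as a TSV edge list
#' (`patient_i`, `patient_j`, `weight`) and/or a GraphML file.
#'
#' @param network A [build_similarity_matrix()] result.
#' @param edgelist_path,graphml_path Output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
export_network <- function(network, edgelist_path = NULL, graphml_path = NULL) {
  written <- character(0)
  if (!is.null(edgelist_path)) {
    ut <- which(upper.tri(network$P), arr.ind = TRUE)
    edges <- data.frame(patient_i = network$patient_ids[ut[, 1]],
                        patient_j = network$patient_ids[ut[, 2]],
                        weight = network$P[ut])
    utils::write.table(edges, edgelist_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    written <- c(written, edgelist_path)
  }
  if (!is.null(graphml_path)) {
    g <- network_graph(network)
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}

# igraph view of the patient network (undirected, weighted, no self-loops)
network_graph <- function(network) {
  igraph::graph_from_adjacency_matrix(network$P, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}
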