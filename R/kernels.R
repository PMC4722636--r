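#' Gaussian Interaction Profile (GIP) kernel
#'
#' Encodes the topology of the interaction network itself as a similarity:
#' each entity is represented by its binary interaction profile (for a drug,
#' the column of the interaction matrix; for a target, the row) and pairs
#' are compared with a Gaussian kernel,
#' \deqn{K(u, v) = \exp(-\gamma \|y_u - y_v\|^2),}
#' with bandwidth normalized by the mean squared profile norm,
#' \eqn{\gamma = m / \mathrm{mean}_u \|y_u\|^2} for multiplier \eqn{m}.
#'
#' Inside cross-validation the kernel must be computed from training
#' interactions only (pass the training-view network); an entity whose
#' training profile is all zero then receives similarity
#' \eqn{\exp(-\gamma \|y_v\|^2)} to every other entity \eqn{v}, with no
#' special-casing.
#'
#' @param net a [dti_network()].
#' @param side `"drug"` or `"target"`: which entity side to compare.
#' @param bandwidth_multiplier positive multiplier \eqn{m} on the
#'   normalized bandwidth (default 1).
#' @return a symmetric kernel matrix with unit diagonal, entries in (0, 1].
#' @export
gip_kernel <- function(net, side = c("drug", "target"),
                       bandwidth_multiplier = 1) {
  side <- match.arg(side)
  stopifnot(inherits(net, "dti_network"), bandwidth_multiplier > 0)
  P <- if (side == "drug") t(net$Y) else net$Y   # rows = profiles
  sq <- rowSums(P^2)
  if (mean(sq) == 0)
    stop("all interaction profiles are zero on the ", side,
         " side; the GIP bandwidth is undefined")
  gamma <- bandwidth_multiplier / mean(sq)
  G <- tcrossprod(P)
  d2 <- pmax(outer(sq, sq, "+") - 2 * G, 0)
  K <- exp(-gamma * d2)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}

#' Shortest hop distances on an interaction graph
#'
#' Breadth-first unweighted shortest path lengths between all pairs of a
#' fixed entity set, given an undirected edge list (e.g. a protein-protein
#' interaction network).  Entities absent from the edge list are isolated:
#' distance 0 to themselves and `Inf` to everything else.  Edge endpoints
#' that are not in `ids` are ignored with a warning giving the count.
#'
#' @param edges two-column matrix or data.frame of entity identifiers
#'   (undirected; duplicates and self-loops are collapsed).
#' @param ids character vector of entity identifiers (matrix order).
#' @return symmetric matrix of hop counts with zero diagonal and `Inf` for
#'   unreachable pairs, labeled by `ids`.
#' @export
shortest_hop_distances <- function(edges, ids) {
  ids <- as.character(ids)
  .check_ids(ids, "entity")
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L)
    stop("edges must have two columns")
  if (length(edges)) {
    storage.mode(edges) <- "character"
    known <- edges[, 1L] %in% ids & edges[, 2L] %in% ids
    if (any(!known))
      warning(sum(!known), " edge(s) reference unknown entities; ignored")
    edges <- edges[known, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  g <- igraph::simplify(g)
  D <- igraph::distances(g, v = ids, to = ids, weights = NA)
  dimnames(D) <- list(ids, ids)
  D
}

#' Shortest-path similarity for protein-protein networks
#'
#' Converts hop distances into similarities that decay exponentially with
#' network distance, \eqn{S(p, p') = A e^{-b D(p, p')}}, with \eqn{S = 0}
#' for unreachable pairs and \eqn{S = A} on the diagonal.  Defaults
#' `A = 0.9`, `b = 1` follow the published parametrization for
#' drug-target prediction from protein-interaction proximity.
#'
#' The growing-exponent form \eqn{A e^{+bD}} (which rewards distance) is
#' selectable with `decay = FALSE` but is not meaningful as a similarity;
#' the decaying form is the default.
#'
#' @param D hop-distance matrix from [shortest_hop_distances()] (or any
#'   nonnegative matrix with `Inf` for unreachable pairs).
#' @param A similarity at distance zero, in (0, 1].
#' @param b nonnegative decay rate per hop.
#' @param decay logical; `TRUE` uses the decaying exponent.
#' @return a symmetric similarity matrix bounded by (0, A].
#' @export
ppi_similarity <- function(D, A = 0.9, b = 1, decay = TRUE) {
  stopifnot(A > 0, A <= 1, b >= 0)
  D <- as.matrix(D)
  sgn <- if (decay) -1 else 1
  S <- A * exp(sgn * b * D)
  S[is.infinite(D)] <- 0
  S
}
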