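#' Weighted node connectivity
#'
#' The connectivity of node i is the sum of absolute association weights of
#' its edges to all other nodes, \eqn{\chi_i = \sum_{j \ne i} |a_{ij}|}.
#' Diagonal entries never contribute (a correlation self-weight of 1 would
#' add a constant to every node). For a 0/1 adjacency matrix this is the
#' node degree.
#'
#' @param a an \code{\link{association_matrix}} result or a square symmetric
#'   numeric matrix.
#' @return Named numeric vector of nonnegative connectivities, one per
#'   feature. For correlation measures values lie in [0, p - 1].
#' @examples
#' A <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0, 0), 3, 3)
#' node_connectivity(A)  # degrees 2, 1, 1
#' @export
node_connectivity <- function(a) {
  w <- if (inherits(a, "assoc_matrix")) a$weights else a
  if (!is.numeric(w)) stop("'a' must be numeric")
  .check_square_symmetric(w, "a")
  chi <- colSums(abs(w)) - abs(diag(w))
  names(chi) <- colnames(w) %||% paste0("V", seq_len(ncol(w)))
  chi
}

#' Differential connectivity between two groups
#'
#' Elementwise difference of node connectivities computed from the two
#' group-specific association matrices:
#' \eqn{\Delta\chi_i = \chi_i^{G1} - \chi_i^{G2}}. Antisymmetric under group
#' swap.
#'
#' @param a1,a2 association matrices (see \code{\link{association_matrix}})
#'   or square symmetric matrices over the same features, built with the
#'   same measure.
#' @return Named numeric vector of differential connectivities.
#' @export
differential_connectivity <- function(a1, a2) {
  if (inherits(a1, "assoc_matrix") && inherits(a2, "assoc_matrix")) {
    if (!identical(a1$measure, a2$measure) ||
        !identical(a1$estimator, a2$estimator)) {
      stop("association matrices use different measures")
    }
  }
  chi1 <- node_connectivity(a1)
  chi2 <- node_connectivity(a2)
  if (length(chi1) != length(chi2)) stop("feature sets differ in size")
  if (!is.null(names(chi1)) && !is.null(names(chi2)) &&
      !identical(names(chi1), names(chi2))) {
    stop("feature names do not match between the two groups")
  }
  chi1 - chi2
}
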