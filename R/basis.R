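# Cubic B-spline basis over signed TSS distance (or any covariate interval)
# and the discrete second-difference penalty of the P-spline approach.

#' Build a B-spline basis
#'
#' Constructs a degree-3 (by default) B-spline basis of \code{n_basis}
#' functions over \code{[d_min, d_max]} with uniformly spaced interior
#' knots and boundary knots repeated \code{degree + 1} times. The basis is
#' a partition of unity on the domain; evaluation outside the domain
#' returns 0 for every function.
#'
#' @param d_min,d_max Domain endpoints (bp for distance bases, or \[0, 1\]
#'   for conservation bases).
#' @param n_basis Number of basis functions P (at least \code{degree + 1}).
#' @param degree Spline degree (default 3, cubic).
#' @return A \code{spline_basis} object.
#' @export
build_basis <- function(d_min, d_max, n_basis = 20, degree = 3) {
  if (d_min >= d_max) stopf("d_min must be < d_max")
  if (n_basis < degree + 1) stopf("n_basis must be >= degree + 1 (= %d)", degree + 1)
  n_interior <- n_basis - degree - 1
  inner <- seq(d_min, d_max, length.out = n_interior + 2)
  knots <- c(rep(d_min, degree), inner, rep(d_max, degree))
  structure(list(knots = knots, degree = degree, n_basis = n_basis,
                 domain = c(d_min, d_max)),
            class = "spline_basis")
}

#' Evaluate all basis functions
#'
#' @param basis A \code{spline_basis}.
#' @param x Numeric vector of evaluation points.
#' @return A \code{length(x) x n_basis} matrix; rows for points outside the
#'   domain are all zero.
#' @export
eval_basis <- function(basis, x) {
  B <- matrix(0, nrow = length(x), ncol = basis$n_basis)
  inside <- x >= basis$domain[1] & x <= basis$domain[2]
  if (any(inside))
    B[inside, ] <- splines::splineDesign(basis$knots, x[inside],
                                         ord = basis$degree + 1, outer.ok = TRUE)
  B
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("spline_basis: degree %d, %d functions on [%s, %s]\n",
              x$degree, x$n_basis, format(x$domain[1], big.mark = ","),
              format(x$domain[2], big.mark = ",")))
  invisible(x)
}

#' Difference penalty matrix
#'
#' Returns \code{D = t(Delta) \%*\% Delta} where \code{Delta} is the
#' order-\code{order} difference operator on the coefficient sequence: the
#' standard P-spline approximation to the integrated squared
#' \code{order}-th derivative of the fitted curve. For \code{order = 2}
#' the null space contains constant and linear coefficient sequences.
#'
#' @param basis A \code{spline_basis} (or an integer number of
#'   coefficients).
#' @param order Difference order (default 2); must be < P.
#' @return A symmetric positive semidefinite P x P matrix.
#' @export
penalty_matrix <- function(basis, order = 2) {
  P <- if (inherits(basis, "spline_basis")) basis$n_basis else as.integer(basis)
  if (order >= P) stopf("penalty order (%d) must be < number of basis functions (%d)", order, P)
  Delta <- diff(diag(P), differences = order)
  crossprod(Delta)
}

#' Design features for a set of binding profiles
#'
#' For each gene, computes the feature vector
#' \code{b_k = sum_j alpha_j * B_k(x_j)} over the gene's associated sites,
#' where \code{x_j} is the entry's covariate (\code{distance} for the
#' position model, \code{conservation} for the conservation-weighted
#' model). Genes with empty profiles get an all-zero row.
#'
#' @param profiles A \code{binding_profiles} object.
#' @param basis A \code{spline_basis}.
#' @param covariate Entry column evaluated in the basis: \code{"distance"}
#'   or \code{"conservation"}.
#' @param outside Handling of covariate values outside the basis domain:
#'   \code{"error"} (default), \code{"drop"} (exclude those sites) or
#'   \code{"clip"} (move them to the nearest domain endpoint).
#' @return An \code{n_genes x n_basis} matrix with genes as rownames.
#' @export
design_features <- function(profiles, basis, covariate = c("distance", "conservation"),
                            outside = c("error", "drop", "clip")) {
  covariate <- match.arg(covariate)
  outside <- match.arg(outside)
  sizes <- profile_sizes(profiles)
  gene_idx <- rep(seq_along(profiles), sizes)
  x <- unlist(lapply(profiles, function(e) e[[covariate]]), use.names = FALSE)
  alpha <- unlist(lapply(profiles, function(e) e$alpha), use.names = FALSE)
  M <- matrix(0, nrow = length(profiles), ncol = basis$n_basis,
              dimnames = list(names(profiles), NULL))
  if (!length(x)) return(M)
  if (covariate == "conservation" && anyNA(x))
    stopf("site(s) missing conservation score; score sites before fitting the conservation model")
  out <- x < basis$domain[1] | x > basis$domain[2]
  if (any(out)) {
    if (outside == "error")
      stopf("%d site covariate value(s) outside the basis domain [%s, %s]",
            sum(out), basis$domain[1], basis$domain[2])
    if (outside == "clip") {
      x <- pmin(pmax(x, basis$domain[1]), basis$domain[2])
    } else {
      keep <- !out
      x <- x[keep]; alpha <- alpha[keep]; gene_idx <- gene_idx[keep]
      if (!length(x)) return(M)
    }
  }
  Bsite <- eval_basis(basis, x) * alpha
  agg <- rowsum(Bsite, group = gene_idx)
  M[as.integer(rownames(agg)), ] <- agg
  M
}
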