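#' P-spline basis with difference penalty
#'
#' Builds a B-spline design matrix on equally spaced knots together with the
#' difference penalty used as a random-walk prior on the spline coefficients.
#' The construction follows the standard penalised-spline recipe: the range
#' `[min(x), max(x)]` is divided into `knots` equal-width segments and the
#' knot sequence is extended `degree` segments beyond each boundary, giving
#' `knots + degree` basis functions whose rows sum to one on the data range.
#' The penalty is `t(D) %*% D` with `D` the `penalty_order`-th difference
#' operator, so its null space has dimension `penalty_order` (a second-order
#' penalty leaves linear trends unpenalised).
#'
#' @param x numeric vector with at least `degree + 1` distinct values.
#' @param knots number of equal-width segments spanning the data range
#'   (so `knots + degree` basis functions); must be `>= penalty_order + 1`.
#' @param degree spline degree (`3` = cubic).
#' @param penalty_order order of the difference penalty (`2` = RW2).
#' @return An object of class `pspline_basis`: list with `B` (n x K basis
#'   matrix), `penalty` (K x K), `knots` (full knot sequence), `degree`,
#'   `penalty_order`, `range`.
#' @export
build_pspline_basis <- function(x, knots = 20, degree = 3, penalty_order = 2) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("x contains missing values")
  if (length(unique(x)) < degree + 1) {
    stop("x needs at least degree+1 distinct values (is x constant?)")
  }
  if (degree < 1) stop("degree must be >= 1")
  if (knots < penalty_order + 1) {
    stop("knots must be >= penalty_order + 1")
  }
  a <- min(x); b <- max(x)
  h <- (b - a) / knots
  kn <- seq(a - degree * h, b + degree * h, by = h)
  # guard against fp drift at the right boundary
  if (length(kn) < knots + 2 * degree + 1) kn <- c(kn, b + degree * h)
  B <- splines::splineDesign(knots = kn, x = x, ord = degree + 1,
                             outer.ok = TRUE)
  K <- ncol(B)  # = knots + degree
  D <- diff(diag(K), differences = penalty_order)
  structure(list(B = B, penalty = crossprod(D), knots = kn, degree = degree,
                 penalty_order = penalty_order, range = c(a, b)),
            class = "pspline_basis")
}

#' Evaluate a P-spline basis at new points
#'
#' Points are clamped to the range the basis was built on (constant
#' extrapolation of the basis support).
#'
#' @param basis a `pspline_basis`.
#' @param x numeric vector.
#' @return matrix with `length(x)` rows.
#' @export
eval_pspline_basis <- function(basis, x) {
  x <- pmin(pmax(as.numeric(x), basis$range[1]), basis$range[2])
  splines::splineDesign(knots = basis$knots, x = x, ord = basis$degree + 1,
                        outer.ok = TRUE)
}

#' @export
print.pspline_basis <- function(x, ...) {
  cat("pspline_basis:", ncol(x$B), "basis functions, degree", x$degree,
      ", penalty order", x$penalty_order, "\n")
  invisible(x)
}
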