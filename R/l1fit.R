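#' Least-absolute-deviations (median regression) solver
#'
#' Minimizes the L1 objective `sum(|y - X b|)`, i.e. fits the conditional
#' median of `y` given the columns of `X` (quantile regression at tau = 0.5).
#' The solver runs iteratively reweighted least squares with a shrinking
#' smoothing parameter to get near the optimum, then polishes with a
#' basis-exchange descent: an L1 optimum interpolates `p = ncol(X)`
#' observations, and at the current interpolating vertex each of the `p`
#' edge directions (relax one interpolation condition) is searched exactly
#' by a weighted median. A vertex at which no exchange improves the
#' objective is a global minimizer of this convex piecewise-linear problem.
#'
#' @param X numeric design matrix (include a column of ones for an
#'   intercept); must have full column rank.
#' @param y numeric response vector.
#' @param max_sweeps maximum basis-exchange sweeps after the smoothed start.
#' @return A list with `coefficients`, `objective` (sum of absolute
#'   residuals), `residuals`, `basis` (row indices interpolated at the
#'   solution, when the solution is a vertex), and `nonunique` (`TRUE` when
#'   a flat segment was detected in a line search, i.e. the minimizer is not
#'   unique).
#' @export
l1_fit <- function(X, y, max_sweeps = 200L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n <= p)
    stop("need more observations (", n, ") than parameters (", p, ")",
         call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, p)]]
    if (is.null(bad)) bad <- paste0("column ", qx$pivot[seq.int(qx$rank + 1L, p)])
    stop("design matrix is rank deficient; collinear: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  b <- qr.coef(qx, y)                      # least-squares warm start
  scale_y <- max(mean(abs(y)), 1e-8)
  eps <- 0.1 * scale_y
  for (it in 1:120) {
    r <- y - drop(X %*% b)
    w <- 1 / pmax(abs(r), eps)
    bw <- tryCatch(solve(crossprod(X, X * w), crossprod(X, w * y)),
                   error = function(e) NULL)
    if (is.null(bw)) break
    step <- max(abs(bw - b)) / max(max(abs(b)), 1e-8)
    b <- drop(bw)
    if (step < 1e-10) {
      if (eps <= 1e-11 * scale_y) break
      eps <- max(eps / 10, 1e-11 * scale_y)
    }
  }

  # initial basis: p rows of smallest |residual| that are linearly independent
  r <- y - drop(X %*% b)
  ord <- order(abs(r))
  basis <- integer(0)
  for (i in ord) {
    cand <- c(basis, i)
    if (qr(X[cand, , drop = FALSE])$rank == length(cand)) basis <- cand
    if (length(basis) == p) break
  }
  if (length(basis) < p) stop("could not construct an interpolation basis",
                              call. = FALSE)
  b <- drop(solve(X[basis, , drop = FALSE], y[basis]))

  obj <- function(bb) sum(abs(y - drop(X %*% bb)))
  f_cur <- obj(b)
  tol <- 1e-12 * (1 + f_cur)
  nonunique <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (pos in seq_len(p)) {
      XB <- X[basis, , drop = FALSE]
      e <- numeric(p); e[pos] <- 1
      d <- tryCatch(drop(solve(XB, e)), error = function(err) NULL)
      if (is.null(d)) next
      g <- drop(X %*% d)
      r <- y - drop(X %*% b)
      act <- abs(g) > 1e-11 * max(abs(g))
      if (!any(act)) next
      wm <- weighted_median(r[act] / g[act], abs(g[act]))
      t_star <- wm$value
      f_new <- sum(abs(r - t_star * g))
      if (f_new < f_cur - tol) {
        b <- b + t_star * d
        if (wm$flat) nonunique <- TRUE
        # enter the row where the new residual vanishes (and g != 0)
        idx_act <- which(act)
        enter <- idx_act[which.min(abs(r[act] - t_star * g[act]))]
        basis[pos] <- enter
        f_cur <- f_new
        improved <- TRUE
      } else if (wm$flat && abs(f_new - f_cur) <= tol) {
        nonunique <- TRUE
      }
    }
    if (!improved) break
  }

  r <- y - drop(X %*% b)
  nm <- colnames(X)
  if (!is.null(nm)) names(b) <- nm
  list(coefficients = b, objective = sum(abs(r)), residuals = r,
       basis = sort(basis), nonunique = nonunique)
}

# Minimizer of sum(w * |t - x|): smallest t where the cumulative weight
# reaches half the total. A crossing that lands exactly on half the weight
# means a flat optimal segment; the midpoint of the segment is returned and
# flagged.
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  half <- cw[length(cw)] / 2
  k <- which(cw >= half - 1e-12 * half)[1]
  flat <- abs(cw[k] - half) <= 1e-9 * half && k < length(x)
  value <- if (flat) (x[k] + x[k + 1]) / 2 else x[k]
  list(value = value, flat = flat)
}
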