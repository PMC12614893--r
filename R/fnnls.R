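# Fast non-negative least squares (Bro & de Jong 1997), operating on the
# normal-equation matrices: solves min ||A x - b||^2 s.t. x >= 0 given
# M = A'A and f = A'b. Active-set method; terminates at the KKT point.
# No NNLS solver ships with the pre-installed stack's base packages, and the
# inversion needs thousands of solves, so this implements the standard
# algorithm directly; pracma::lsqnonneg serves as a cross-check in tests.
#
# `init_passive` seeds the passive (unconstrained) set, e.g. with the support
# of the solution at a neighbouring regularisation parameter; the algorithm
# first restores primal feasibility on that set, then proceeds with the
# usual optimality loop, so the result is the same KKT point but typically
# reached in far fewer iterations. Because floating-point cycling can stall
# a warm-started run on ill-conditioned systems, the result is checked
# against the KKT conditions and the solve is repeated from a cold start
# when the check fails; the iterate with the lower objective wins.
fnnls <- function(M, f, tol = NULL, init_passive = NULL) {
  n <- length(f)
  stopifnot(nrow(M) == n, ncol(M) == n)
  # dual tolerance scales with the gradient f (norm(M) over-scales it when a
  # huge regularisation weight dominates M and stalls the solve at x = 0)
  if (is.null(tol)) tol <- 100 * .Machine$double.eps * n * max(abs(f), 1e-12)
  kkt_tol <- max(tol * 100, 1e-3 * max(abs(f), 1))
  obj <- function(x) 0.5 * sum(x * (M %*% x)) - sum(f * x)
  kkt_gap <- function(x, passive) {
    w <- f - M %*% x
    if (all(passive)) 0 else max(0, max(w[!passive]))
  }
  res <- fnnls_core(M, f, n, tol, init_passive)
  if (!is.null(init_passive) && kkt_gap(res$x, res$passive) > kkt_tol) {
    res2 <- fnnls_core(M, f, n, tol, NULL)
    if (obj(res2$x) < obj(res$x)) res <- res2
  }
  structure(as.vector(res$x), passive = res$passive)
}

fnnls_core <- function(M, f, n, tol, init_passive) {
  x <- numeric(n)
  passive <- logical(n)

  solve_passive <- function(idx) {
    s <- numeric(n)
    Msub <- M[idx, idx, drop = FALSE]
    sol <- tryCatch({                      # SPD: Cholesky is fastest
      R <- chol(Msub)
      backsolve(R, forwardsolve(R, f[idx], upper.tri = TRUE, transpose = TRUE))
    }, error = function(e) NULL)
    if (is.null(sol)) {
      sol <- qr.coef(qr(Msub), f[idx])
      sol[is.na(sol)] <- 0
    }
    s[idx] <- sol
    s
  }

  # inner loop: restore x >= 0 on the current passive set
  make_feasible <- function(x, passive) {
    guard <- 0L
    repeat {
      idx <- which(passive)
      if (!length(idx)) return(list(x = numeric(n), passive = passive))
      s <- solve_passive(idx)
      if (all(s[idx] > 0)) return(list(x = s, passive = passive))
      guard <- guard + 1L
      if (guard > n) {             # numerically stuck: keep feasible iterate
        x[x < 0] <- 0
        return(list(x = x, passive = x > 0))
      }
      neg <- idx[s[idx] <= 0]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (s - x)
      out <- passive & x <= tol & s <= tol
      passive[out] <- FALSE
      x[!passive] <- 0
    }
  }

  if (!is.null(init_passive) && any(init_passive)) {
    fs <- make_feasible(x, as.logical(init_passive))
    x <- fs$x; passive <- fs$passive
  }

  w <- f - M %*% x
  iter <- 0L
  max_iter <- 3L * n + 100L
  last_j <- -1L
  stall <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    if (j == last_j) {             # immediate re-add: numerical cycling
      stall <- stall + 1L
      if (stall > 3L) break
      tol <- tol * 10
    } else stall <- 0L
    passive[j] <- TRUE
    fs <- make_feasible(x, passive)
    # cycling signature: the just-added index was dropped again
    last_j <- if (!fs$passive[j]) j else -1L
    x <- fs$x; passive <- fs$passive
    w <- f - M %*% x
  }
  list(x = x, passive = passive)
}
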