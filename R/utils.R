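#' @keywords internal
"_PACKAGE"

#' Run an expression with a local RNG seed
#'
#' Saves and restores \code{.Random.seed} so that seeded internals never
#' disturb the caller's RNG stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## zero-mean sample covariance, divisor T (the convention used throughout:
## filtered EEG is zero mean by construction, epochs keep their raw offset)
cov0 <- function(X) {
  X <- as.matrix(X)
  tcrossprod(X) / ncol(X)
}

#' Symmetric inverse square root of a positive-definite matrix
#' @param C symmetric positive-definite matrix.
#' @param tol relative eigenvalue tolerance below which C is declared
#'   rank-deficient.
#' @return matrix \code{C^(-1/2)} (symmetric).
#' @keywords internal
sym_inv_sqrt <- function(C, tol = 1e-12) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  bad <- e$values <= tol * max(e$values)
  if (any(bad))
    stop(sprintf("covariance is rank deficient: %d dimension(s) collapsed",
                 sum(bad)))
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

## orthonormalize the columns of M (QR with positive diagonal R)
orthonormalize <- function(M) {
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  Q * rep(d, each = nrow(Q))
}

## excess kurtosis of a vector (zero-mean convention not assumed)
excess_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2 - 3
}

## squared Frobenius norm of the off-diagonal part
offdiag_norm2 <- function(M) {
  sum(M^2) - sum(diag(M)^2)
}

## flip component signs so the largest-|.| map entry is positive
fix_map_signs <- function(A, W, activities = NULL) {
  s <- apply(A, 2, function(a) {
    v <- a[which.max(abs(a))]
    if (v < 0) -1 else 1
  })
  A <- A * rep(s, each = nrow(A))
  W <- W * s
  if (!is.null(activities)) activities <- activities * s
  list(A = A, W = W, activities = activities, signs = s)
}
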