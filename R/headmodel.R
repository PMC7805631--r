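## Three-shell spherical volume conductor.
##
## The head is modeled as three concentric spherical shells (brain, skull,
## scalp).  For a current dipole inside the innermost shell the potential is
## expanded in spherical harmonics; per harmonic degree n the radial
## coefficients in each shell follow from continuity of potential and of
## radial current at the two interfaces plus a no-flux condition at the
## scalp surface.  That 5x5 linear system is solved numerically per degree,
## which keeps the model exact (up to series truncation) without hard-coding
## the classical closed-form three-shell coefficients.

#' Construct a three-shell spherical head model
#'
#' @param radii radii of brain, skull and scalp shells in meters
#'   (increasing).
#' @param conductivities conductivities of the three shells in S/m.
#' @return object of class \code{head_model}.
#' @examples
#' hm <- head_model()
#' hm$radii
#' @export
head_model <- function(radii = c(0.087, 0.092, 0.100),
                       conductivities = c(0.33, 0.0042, 0.33)) {
  stopifnot(length(radii) == 3, length(conductivities) == 3,
            all(diff(radii) > 0), all(conductivities > 0))
  structure(list(radii = radii, conductivities = conductivities),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("Three-shell spherical head model\n")
  cat("  radii (m):         ", paste(x$radii, collapse = " / "), "\n")
  cat("  conductivity (S/m):", paste(x$conductivities, collapse = " / "), "\n")
  invisible(x)
}

## Per-degree surface gain G_n: the scalp-surface potential produced by a
## unit source coefficient r'^-(n+1) in the innermost shell, radii scaled so
## the scalp radius is 1.  Solves for (A1, A2, B2, A3, B3).
.shell_gains <- function(n_terms, radii, cond) {
  R <- radii[3]
  r1 <- radii[1] / R
  r2 <- radii[2] / R
  s1 <- cond[1]; s2 <- cond[2]; s3 <- cond[3]
  G <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    ## unknowns u = (A1, A2, B2, A3, B3)
    M <- matrix(0, 5, 5)
    b <- numeric(5)
    ## potential continuity at r1: A1 r1^n - A2 r1^n - B2 r1^-(n+1) = -r1^-(n+1)
    M[1, ] <- c(r1^n, -r1^n, -r1^(-(n + 1)), 0, 0)
    b[1] <- -r1^(-(n + 1))
    ## radial current continuity at r1
    M[2, ] <- c(s1 * n * r1^(n - 1),
                -s2 * n * r1^(n - 1),
                s2 * (n + 1) * r1^(-(n + 2)), 0, 0)
    b[2] <- s1 * (n + 1) * r1^(-(n + 2))
    ## potential continuity at r2
    M[3, ] <- c(0, r2^n, r2^(-(n + 1)), -r2^n, -r2^(-(n + 1)))
    ## radial current continuity at r2
    M[4, ] <- c(0, s2 * n * r2^(n - 1), -s2 * (n + 1) * r2^(-(n + 2)),
                -s3 * n * r2^(n - 1), s3 * (n + 1) * r2^(-(n + 2)))
    ## no radial current through the scalp surface (r = 1)
    M[5, ] <- c(0, 0, 0, n, -(n + 1))
    u <- solve(M, b)
    G[n] <- u[4] + u[5]
  }
  G
}

## cache of per-model gain vectors (gains depend only on model geometry)
.gain_cache <- new.env(parent = emptyenv())

.get_gains <- function(model, n_terms) {
  key <- paste(c(model$radii, model$conductivities, n_terms), collapse = "|")
  g <- .gain_cache[[key]]
  if (is.null(g)) {
    g <- .shell_gains(n_terms, model$radii, model$conductivities)
    .gain_cache[[key]] <- g
  }
  g
}

#' Scalp potential map of a current dipole
#'
#' Computes the average-referenced potential at the given electrodes
#' produced by a single current dipole inside the innermost shell of a
#' three-shell spherical head model.
#'
#' @param position dipole position, 3-vector in meters; must lie strictly
#'   inside the innermost shell.
#' @param moment dipole moment, 3-vector (A m); need not be unit norm.
#' @param electrodes matrix (channels x 3) of scalp electrode positions in
#'   meters, e.g. from [montage_1010()].
#' @param model a [head_model()].
#' @param tol series truncation tolerance.
#' @return numeric vector of length \code{nrow(electrodes)} summing to zero
#'   (average reference).
#' @examples
#' el <- montage_1010()
#' v <- forward_map(c(0, 0, 0.05), c(0, 0, 1e-8), el)
#' names(which.max(v))  # radial dipole under the vertex peaks at Cz
#' @export
forward_map <- function(position, moment, electrodes,
                        model = head_model(), tol = 1e-9) {
  position <- as.numeric(position)
  moment <- as.numeric(moment)
  stopifnot(length(position) == 3, length(moment) == 3)
  R <- model$radii[3]
  b <- sqrt(sum(position^2))
  if (b >= model$radii[1])
    stop("dipole position lies outside the innermost shell (|r| = ",
         signif(b, 4), " m, limit ", model$radii[1], " m)")
  if (all(moment == 0)) stop("dipole moment must be nonzero")
  electrodes <- as.matrix(electrodes)

  bq <- b / R
  if (bq < 1e-9) {
    rhat <- moment / sqrt(sum(moment^2))
    bq <- 0
  } else rhat <- position / b
  q_r <- sum(moment * rhat)
  q_tvec <- moment - q_r * rhat
  q_t <- sqrt(sum(q_tvec^2))
  that <- if (q_t > 1e-15 * sqrt(sum(moment^2))) q_tvec / q_t else c(0, 0, 0)

  ## electrode geometry in the dipole frame
  enorm <- sqrt(rowSums(electrodes^2))
  eu <- electrodes / enorm
  x <- pmin(1, pmax(-1, as.numeric(eu %*% rhat)))  # cos(gamma)
  eperp <- eu - outer(x, rhat)
  s <- sqrt(pmax(0, 1 - x^2))                    # sin(gamma)
  cphi <- as.numeric(eperp %*% that)
  cphi <- ifelse(s > 1e-12, cphi / pmax(s, 1e-12), 0)

  n_terms <- if (bq > 0)
    max(20L, min(300L, ceiling(log(tol) / log(bq)))) else 20L
  G <- .get_gains(model, n_terms)

  ## Legendre recurrences over degrees, vectorized over electrodes
  V <- numeric(nrow(electrodes))
  Pnm1 <- rep(1, length(x))  # P_0
  Pn <- x                    # P_1
  bpow <- 1                  # (b/R)^(n-1)
  for (n in seq_len(n_terms)) {
    ## P_n^1(x) = n (P_{n-1} - x P_n) / sin(gamma)  (no Condon-Shortley phase)
    Pn1 <- ifelse(s > 1e-12, n * (Pnm1 - x * Pn) / pmax(s, 1e-12), 0)
    V <- V + G[n] * bpow * (n * q_r * Pn + q_t * Pn1 * cphi)
    Pnext <- ((2 * n + 1) * x * Pn - n * Pnm1) / (n + 1)
    Pnm1 <- Pn
    Pn <- Pnext
    bpow <- bpow * bq
    if (bq == 0 && n >= 1) break  # central dipole: only n = 1 contributes
  }
  V <- V / (4 * pi * model$conductivities[1] * R^2)
  V <- V - mean(V)
  names(V) <- rownames(electrodes)
  V
}

#' Dipole lead field at one position
#'
#' Stacks the forward maps of the three unit Cartesian moments into a
#' (channels x 3) matrix, so that the map of an arbitrary moment q is
#' \code{L \%*\% q}.
#'
#' @inheritParams forward_map
#' @return matrix (channels x 3).
#' @export
leadfield <- function(position, electrodes, model = head_model(),
                      tol = 1e-9) {
  position <- as.numeric(position)
  R <- model$radii[3]
  b <- sqrt(sum(position^2))
  if (b >= model$radii[1])
    stop("dipole position lies outside the innermost shell")
  electrodes <- as.matrix(electrodes)
  if (b < 1e-9 * R) {
    ## central dipole: fall back to the single-moment path per axis
    return(cbind(forward_map(position, c(1, 0, 0), electrodes, model, tol),
                 forward_map(position, c(0, 1, 0), electrodes, model, tol),
                 forward_map(position, c(0, 0, 1), electrodes, model, tol)))
  }
  rhat <- position / b
  bq <- b / R
  enorm <- sqrt(rowSums(electrodes^2))
  eu <- electrodes / enorm
  x <- pmin(1, pmax(-1, as.numeric(eu %*% rhat)))
  eperp <- eu - outer(x, rhat)
  s <- sqrt(pmax(0, 1 - x^2))
  ## tangential geometric factor: eperp (I - rhat rhat') / s
  Tg <- (eperp - outer(as.numeric(eperp %*% rhat), rhat)) /
    pmax(s, 1e-12)
  Tg[s <= 1e-12, ] <- 0
  n_terms <- max(20L, min(300L, ceiling(log(tol) / log(bq))))
  G <- .get_gains(model, n_terms)
  B <- matrix(0, nrow(electrodes), 3)
  Pnm1 <- rep(1, length(x)); Pn <- x; bpow <- 1
  for (n in seq_len(n_terms)) {
    Pn1 <- ifelse(s > 1e-12, n * (Pnm1 - x * Pn) / pmax(s, 1e-12), 0)
    B <- B + (G[n] * bpow) * (outer(n * Pn, rhat) + Pn1 * Tg)
    Pnext <- ((2 * n + 1) * x * Pn - n * Pnm1) / (n + 1)
    Pnm1 <- Pn; Pn <- Pnext
    bpow <- bpow * bq
  }
  B <- B / (4 * pi * model$conductivities[1] * R^2)
  sweep(B, 2, colMeans(B))  # average reference per moment column
}
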