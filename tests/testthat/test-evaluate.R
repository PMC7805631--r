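test_that("entropy estimator matches closed forms and the scaling law", {
  set.seed(1)
  x <- rnorm(1e6)
  h_gauss <- 0.5 * log2(2 * pi * exp(1))
  expect_equal(estimate_entropy(x), h_gauss, tolerance = 0.02)
  u <- runif(1e6)
  expect_equal(estimate_entropy(u), 0, tolerance = 0.02)
  ## doubling the scale adds exactly one bit
  expect_equal(estimate_entropy(2 * x) - estimate_entropy(x), 1,
               tolerance = 0.01)
  expect_warning(h <- estimate_entropy(rep(1, 2000)), "constant")
  expect_identical(h, -Inf)
})

test_that("MIR vanishes for permutations and matches the Gaussian closed form", {
  set.seed(2)
  X <- matrix(rnorm(2 * 2e5), 2)
  ## signed permutation decomposition: no information change
  P <- matrix(c(0, -1, 1, 0), 2)
  dec <- structure(list(A = P, W = solve(P), activities = solve(P) %*% X),
                   class = "eeg_decomposition")
  expect_equal(mutual_info_reduction(X, dec)$per_sample, 0,
               tolerance = 0.02)
  ## correlated Gaussian pair, rho = 0.9, decorrelated by PCA:
  ## MIR = -0.5 log2(1 - 0.81) = 1.198 bits/sample
  z <- rnorm(2e5)
  Xc <- rbind(z, 0.9 * z + sqrt(1 - 0.81) * rnorm(2e5))
  d <- pca_decompose(Xc)
  expect_equal(mutual_info_reduction(Xc, d)$per_sample,
               -0.5 * log2(1 - 0.81), tolerance = 0.05)
  ## rate normalization: per_sample * fs / channels
  mir <- mutual_info_reduction(Xc, d, fs = 128)
  expect_equal(mir$rate, mir$per_sample * 128 / 2)
})

test_that("ICA reduces mutual information at least as much as PCA", {
  wins <- 0
  for (s in 1:5) {
    S <- bursty_sources(3, 1e4, seed = s)
    set.seed(s)
    A0 <- matrix(rnorm(9), 3)
    X <- A0 %*% S
    wh <- whiten(X)
    m_ica <- mutual_info_reduction(X, fastica(wh, "tanh", X,
                                              seed = s))$per_sample
    m_pca <- mutual_info_reduction(X, pca_decompose(X))$per_sample
    wins <- wins + (m_ica >= m_pca)
  }
  expect_gte(wins, 4)
})

test_that("dipole fitting is self-consistent and scale invariant", {
  el <- montage_1010()
  pos0 <- c(-0.045, -0.01, 0.060)
  mom0 <- c(-0.4, 0.2, 1); mom0 <- mom0 / sqrt(sum(mom0^2))
  map <- forward_map(pos0, mom0, el)
  f <- fit_dipole(map, el)
  expect_lt(f$residual_variance, 1e-6)
  expect_lt(sqrt(sum((f$position - pos0)^2)), 0.002)
  ## scaling the map does not change the fit
  f10 <- fit_dipole(10 * map, el)
  expect_equal(f10$position, f$position, tolerance = 1e-6)
  expect_equal(f10$residual_variance, f$residual_variance,
               tolerance = 1e-10)
  expect_error(fit_dipole(rep(0, 32), el), "nonzero")
})

test_that("the dipolarity decision is inclusive at the threshold", {
  expect_true(is_dipolar(0.05))
  expect_true(is_dipolar(0.10))
  expect_false(is_dipolar(0.101))
})

test_that("component matching requires both thresholds and is one-to-one", {
  set.seed(5)
  n <- 4; T_ <- 3000
  A <- matrix(rnorm(n * n), n)
  act <- matrix(rnorm(n * T_), n)
  d1 <- structure(list(A = A, W = solve(A), activities = act),
                  class = "eeg_decomposition")
  ## permuted and sign-flipped copy: everything matches
  p <- c(3, 1, 4, 2); s <- c(1, -1, -1, 1)
  d2 <- structure(list(A = A[, p] %*% diag(s), W = diag(s) %*% solve(A)[p, ],
                       activities = act[p, ] * s),
                  class = "eeg_decomposition")
  mt <- match_components(d1, d2)
  expect_equal(nrow(mt), 4)
  expect_equal(mt$j[order(mt$i)], order(p))
  ## orthogonal maps, independent activities: no matches
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  d3 <- structure(list(A = Q[, 1:2], W = t(Q[, 1:2]),
                       activities = matrix(rnorm(2 * T_), 2)),
                  class = "eeg_decomposition")
  d4 <- structure(list(A = Q[, 3:4], W = t(Q[, 3:4]),
                       activities = matrix(rnorm(2 * T_), 2)),
                  class = "eeg_decomposition")
  expect_equal(nrow(match_components(d3, d4)), 0)
  ## conjunction: high map similarity but sub-threshold activity correlation
  a1 <- rnorm(T_)
  a2 <- 0.75 * a1 + sqrt(1 - 0.75^2) * rnorm(T_)
  stopifnot(abs(cor(a1, a2)) < 0.8)     # below the activity threshold
  v <- rnorm(8); v <- v / sqrt(sum(v^2))
  w <- v + 0.05 * rnorm(8); w <- w / sqrt(sum(w^2))
  stopifnot(abs(sum(v * w)) >= 0.9)     # above the map threshold
  e1 <- structure(list(A = cbind(v), W = rbind(v),
                       activities = rbind(a1)),
                  class = "eeg_decomposition")
  e2 <- structure(list(A = cbind(w), W = rbind(w),
                       activities = rbind(a2)),
                  class = "eeg_decomposition")
  expect_equal(nrow(match_components(e1, e2)), 0)
  expect_equal(nrow(match_components(e1, e2, act_thresh = 0.7)), 1)
})

test_that("method similarity matches the shared-component formula", {
  set.seed(6)
  n <- 4; T_ <- 2000
  A <- matrix(rnorm(16), 4)
  act <- matrix(rnorm(n * T_), n)
  d <- structure(list(A = A, W = solve(A), activities = act),
                 class = "eeg_decomposition")
  ## identical decompositions: similarity 1
  S <- method_similarity(list(m1 = d, m2 = d))
  expect_equal(S["m1", "m2"], 1)
  ## disjoint: 0
  Q <- qr.Q(qr(matrix(rnorm(64), 8)))
  mk <- function(cols, seed) {
    set.seed(seed)
    structure(list(A = Q[, cols], W = t(Q[, cols]),
                   activities = matrix(rnorm(4 * T_), 4)),
              class = "eeg_decomposition")
  }
  S0 <- method_similarity(list(a = mk(1:4, 1), b = mk(5:8, 2)))
  expect_equal(S0["a", "b"], 0)
  ## arithmetic: n_s = 1, n_i = n_j = 4 -> 1/7
  dA <- mk(1:4, 3)
  dB <- mk(c(1, 5, 6, 7), 4)
  dB$activities[1, ] <- dA$activities[1, ]
  SB <- method_similarity(list(a = dA, b = dB))
  expect_equal(SB["a", "b"], 1 / 7)
})

test_that("component rank uses transitive closure over matches", {
  ## chain: method a comp 1 ~ b comp 1 ~ c comp 1 without a direct a ~ c
  ## match is impossible to construct with exact duplicates, so use three
  ## slightly rotated map copies where consecutive pairs pass the map
  ## threshold but the extremes do not
  T_ <- 3000
  set.seed(7)
  act <- rnorm(T_)
  base <- c(1, rep(0, 7))
  rot <- function(theta) {
    v <- c(cos(theta), sin(theta), rep(0, 6)); v
  }
  mkd <- function(v, a) structure(
    list(A = cbind(v), W = rbind(v), activities = rbind(a)),
    class = "eeg_decomposition")
  ## cos(0.3) = 0.955 > 0.9 between neighbors, cos(0.6) = 0.825 < 0.9
  decs <- list(a = mkd(rot(0), act), b = mkd(rot(0.3), act),
               c = mkd(rot(0.6), act))
  expect_equal(nrow(match_components(decs$a, decs$c)), 0)
  rk <- component_rank(decs)
  expect_equal(rk$rank, rep(2L, 3))
  ## a component found by one method only has rank 0
  d_only <- list(a = mkd(rot(0), act),
                 b = mkd(c(0, 0, 1, rep(0, 5)), rnorm(T_)))
  rk2 <- component_rank(d_only)
  expect_equal(rk2$rank, c(0L, 0L))
})

test_that("greedy selection finds the informative component", {
  ## one component whose variance depends on the task, others stationary
  set.seed(8)
  n_blocks <- 10; len <- 400; n <- 4
  epochs <- list(); act <- NULL
  ev <- NULL
  onset <- 1L
  rows <- list()
  for (b in seq_len(n_blocks)) for (task in c("relax", "left_MI",
                                              "right_MI", "relax")) {
    rows[[length(rows) + 1]] <- data.frame(onset = onset, task = task,
                                           block = b)
    onset <- onset + len
  }
  ev <- do.call(rbind, rows)
  ev$task <- factor(ev$task, levels = TASKS)
  T_ <- onset - 1L
  act <- matrix(rnorm(n * T_), n)
  sdmap <- c(relax = 1, left_MI = 3, right_MI = 0.3)
  for (k in seq_len(nrow(ev))) {
    i0 <- ev$onset[k]
    act[1, i0:(i0 + len - 1)] <- rnorm(len) * sdmap[as.character(ev$task[k])]
  }
  rec <- structure(list(data = act, fs = len / 10, events = ev),
                   class = "eeg_recording")
  dec <- structure(list(A = diag(n), W = diag(n), activities = act),
                   class = "eeg_decomposition")
  dip <- rep(TRUE, n)
  sel <- greedy_select(dec, rec, dip, task_duration_s = 10)
  expect_true(1 %in% sel$selected)
  expect_equal(sel$kappa, max(sel$trace))
  expect_gt(sel$kappa, 0.3)
  ## without any task-modulated component kappa stays near zero
  act0 <- matrix(rnorm(n * T_), n)
  rec0 <- structure(list(data = act0, fs = len / 10, events = ev),
                    class = "eeg_recording")
  dec0 <- structure(list(A = diag(n), W = diag(n), activities = act0),
                    class = "eeg_decomposition")
  ## the greedy maximum over candidate sets inflates the null slightly
  sel0 <- greedy_select(dec0, rec0, dip, task_duration_s = 10)
  expect_lte(abs(sel0$kappa), 0.2)
  ## no dipolar candidates: empty result
  selE <- greedy_select(dec, rec, rep(FALSE, n))
  expect_length(selE$selected, 0)
  expect_true(is.na(selE$kappa))
})

test_that("classical MDS embeds method similarity faithfully", {
  ## equal pairwise similarity: equilateral triangle
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  rownames(S) <- colnames(S) <- c("a", "b", "c")
  xy <- mds_embed(structure(S, class = c("method_similarity", "matrix")))
  d <- as.matrix(dist(xy))
  off <- d[upper.tri(d)]
  expect_equal(off, rep(off[1], 3), tolerance = 1e-6)
  ## an outlier method sits farthest from the centroid
  S2 <- matrix(0.8, 4, 4); diag(S2) <- 1
  S2[4, 1:3] <- S2[1:3, 4] <- 0.05
  rownames(S2) <- colnames(S2) <- c("a", "b", "c", "out")
  xy2 <- mds_embed(structure(S2, class = c("method_similarity", "matrix")))
  cd <- sqrt(rowSums(xy2^2))
  expect_equal(names(which.max(cd)), "out")
  ## identical methods collapse to coincident points
  S3 <- matrix(1, 3, 3)
  rownames(S3) <- colnames(S3) <- c("a", "b", "c")
  xy3 <- mds_embed(structure(S3, class = c("method_similarity", "matrix")))
  expect_true(isTRUE(attr(xy3, "degenerate")))
  expect_equal(unname(xy3), matrix(0, 3, 2), ignore_attr = TRUE)
})

test_that("pairwise Wilcoxon tests with BH correction behave as expected", {
  ## identical vectors tie everywhere: p = 1, nothing rejected
  V <- cbind(a = 1:10 + 0.5, b = 1:10 + 0.5, c = 1:10 + 0.5)
  expect_warning(pairwise_method_tests(V[, 1:2]), "tie")
  r <- suppressWarnings(pairwise_method_tests(V))
  expect_true(all(r$p[upper.tri(r$p)] == 1))
  expect_false(any(r$significant, na.rm = TRUE))
  ## a clearly shifted method is detected after correction
  set.seed(9)
  base <- rnorm(30)
  V2 <- cbind(a = base + rnorm(30, 0, 0.2),
              b = base + rnorm(30, 0, 0.2),
              c = base + 2 + rnorm(30, 0, 0.2))
  r2 <- pairwise_method_tests(V2)
  expect_true(r2$significant["a", "c"])
  expect_true(r2$significant["b", "c"])
  expect_false(r2$significant["a", "b"])
  expect_error(pairwise_method_tests(V2[1:4, ]), ">= 6")
})
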