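## small epoch-set builder: zero-mean Gaussian epochs with per-class
## covariance, organized in blocks
gauss_epochs <- function(Cs, n_blocks = 10, per_block = 2, len = 200,
                         seed = 1) {
  set.seed(seed)
  out <- list()
  for (b in seq_len(n_blocks)) for (cl in names(Cs)) {
    for (r in seq_len(per_block)) {
      L <- chol(Cs[[cl]])
      X <- t(L) %*% matrix(rnorm(nrow(L) * len), nrow(L))
      out[[length(out) + 1]] <- list(X = X, task = cl, block = b)
    }
  }
  structure(out, class = "epoch_set")
}

test_that("fitted class covariances converge to the truth", {
  Cs <- list(relax = diag(2), left_MI = 4 * diag(2))
  ep <- gauss_epochs(Cs, n_blocks = 10, per_block = 5, len = 500)
  m <- fit_bayes(ep)
  expect_equal(m$C$relax, diag(2), tolerance = 0.05)
  expect_equal(m$C$left_MI, 4 * diag(2), tolerance = 0.05)
  ## priors proportional to total cue time (equal here)
  expect_equal(unname(m$priors), c(0.5, 0.5))
  ## single epoch per class fits with a warning on quality
  ep1 <- gauss_epochs(Cs, n_blocks = 1, per_block = 1, len = 100)
  expect_warning(fit_bayes(ep1), "single epoch")
  ## empty class errors
  expect_error(fit_bayes(structure(list(), class = "epoch_set")),
               "no labeled")
})

test_that("window classification evaluates the covariance score exactly", {
  ## 1-D hand case: C1 = 1, C2 = 4, equal priors, window covariance 1
  m <- structure(list(C = list(relax = matrix(1), left_MI = matrix(4)),
                      priors = c(relax = 0.5, left_MI = 0.5),
                      classes = c("relax", "left_MI")),
                 class = "bayes_model")
  Cx <- matrix(1); attr(Cx, "is_cov") <- TRUE
  r <- classify_window(Cx, m)
  expect_equal(unname(r$scores),
               c(log(0.5) - 1, log(0.5) - 0.25 - log(4)),
               tolerance = 1e-12)
  expect_equal(r$class, "relax")
  ## window covariance equal to C2: class 2 wins
  C2 <- matrix(4); attr(C2, "is_cov") <- TRUE
  expect_equal(classify_window(C2, m)$class, "left_MI")
  ## exact tie breaks to the first class
  mt <- m; mt$C$left_MI <- matrix(1)
  expect_equal(classify_window(Cx, mt)$class, "relax")
  expect_error(classify_window(matrix(rnorm(4), 2), m), "dimension")
})

test_that("sliding windows replay the online decision stream", {
  m <- structure(list(C = list(relax = matrix(1), left_MI = matrix(4)),
                      priors = c(relax = 0.5, left_MI = 0.5),
                      classes = c("relax", "left_MI")),
                 class = "bayes_model")
  ## 10 s at 128 Hz with 1 s window and 100 ms shift -> 91 decisions
  set.seed(2)
  x <- matrix(rnorm(1280), 1)
  dec <- sliding_window_classify(x, m, fs = 128)
  expect_equal(nrow(dec), 91)
  ## stationary class-2 signal is labeled class 2 almost everywhere
  x2 <- matrix(2 * rnorm(1280), 1)
  dec2 <- sliding_window_classify(x2, m, fs = 128)
  expect_gt(mean(dec2$label == "left_MI"), 0.9)
  ## window = shift = whole epoch: a single decision
  dec3 <- sliding_window_classify(x, m, fs = 128, window_s = 10,
                                  shift_s = 10)
  expect_equal(nrow(dec3), 1)
  expect_error(sliding_window_classify(x[, 1:100, drop = FALSE], m,
                                       fs = 128), "shorter")
})

test_that("block-wise cross-validation iterates all 120 splits", {
  Cs <- list(relax = diag(2), left_MI = diag(c(6, 0.5)),
             right_MI = diag(c(0.5, 6)))
  ep <- gauss_epochs(Cs, n_blocks = 10, per_block = 2, len = 300)
  cm <- cross_validate(ep)
  expect_equal(attr(cm, "n_folds"), 120)
  ## well-separated classes give a (near) diagonal confusion matrix
  expect_gt(sum(diag(cm)) / sum(cm), 0.98)
  expect_gt(cohen_kappa(cm), 0.95)
  ## shuffled labels: kappa collapses to chance
  set.seed(3)
  shuf <- ep
  labs <- sample(vapply(ep, `[[`, "", "task"))
  for (k in seq_along(shuf)) shuf[[k]]$task <- labs[k]
  km <- cohen_kappa(cross_validate(shuf))
  expect_lt(abs(km), 0.15)
})

test_that("Cohen's kappa matches its closed forms", {
  expect_equal(cohen_kappa(diag(c(10, 10, 10))), 1)
  expect_equal(cohen_kappa(matrix(5, 3, 3)), 0)
  ## direct arithmetic: (20*16 - 200) / (400 - 200) = 0.6
  expect_equal(cohen_kappa(matrix(c(8, 2, 2, 8), 2)), 0.6)
  ## invariance under count rescaling
  G <- matrix(c(7, 1, 2, 9), 2)
  expect_equal(cohen_kappa(G), cohen_kappa(3 * G))
  ## all mass in one cued column: undefined
  expect_error(cohen_kappa(matrix(c(5, 5, 0, 0), 2)), "undefined")
})

test_that("classification is invariant to joint linear transforms", {
  ## congruence invariance: transform data and covariances together
  set.seed(4)
  Cs <- list(relax = diag(3), left_MI = diag(c(4, 1, 0.25)))
  L <- matrix(rnorm(9), 3)
  m1 <- structure(list(C = Cs, priors = c(relax = .5, left_MI = .5),
                       classes = names(Cs)), class = "bayes_model")
  m2 <- structure(list(C = lapply(Cs, function(C) L %*% C %*% t(L)),
                       priors = c(relax = .5, left_MI = .5),
                       classes = names(Cs)), class = "bayes_model")
  for (i in 1:5) {
    X <- matrix(rnorm(300), 3) * sample(c(0.5, 1, 2), 3, TRUE)
    s1 <- classify_window(X, m1)$scores
    s2 <- classify_window(L %*% X, m2)$scores
    ## scores shift by a common constant (log |det L|^2), argmax unchanged
    expect_equal(diff(s1), diff(s2), tolerance = 1e-8)
  }
})

test_that("online replay accumulates window decisions per block", {
  Cs <- list(relax = diag(2), left_MI = diag(c(6, 0.5)),
             right_MI = diag(c(0.5, 6)))
  ep <- gauss_epochs(Cs, n_blocks = 5, per_block = 2, len = 256)
  cm <- online_replay(ep, fs = 128)
  expect_true(all(dim(cm) == 3))
  expect_gt(cohen_kappa(cm), 0.5)
})
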