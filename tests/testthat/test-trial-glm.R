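test_that("single-trial Welch coherence has the documented window layout", {
  fs <- 1000
  time <- seq(-0.5, 0.999, by = 1 / fs)
  r <- sin(2 * pi * 60 * time)
  v <- single_trial_coherence(r, r, fs, time, freq = 60)
  expect_equal(as.numeric(v), 1, tolerance = 1e-10)
  # (0.3 - 0.1)/0.025 + 1 = 9 windows in the 0.2-0.5 s interval
  expect_equal(attr(v, "n_windows"), 9)
  # nearest 512-point bin to 60 Hz at 1000 Hz sampling
  expect_equal(attr(v, "bin_freq"), 31 * 1000 / 512)
  expect_equal(attr(single_trial_coherence(r, r, fs, time, freq = 67),
                    "bin_freq"), 34 * 1000 / 512)
  expect_error(single_trial_coherence(r, r, fs, time, freq = 60,
                                      interval = c(0.2, 0.25)),
               "2 windows")
})

test_that("design matrix encodes roles, tot and the concatenation rule", {
  g1 <- data.frame(condition = "guided", tot = 0.4, trial_index = 3L)
  d <- build_design(g1)
  expect_equal(unname(d$X), rbind(c(1, 0, 0, 0.4), c(0, 0, 1, 0.4)))
  expect_equal(d$row_map$role, c("target", "distractor"))

  u1 <- data.frame(condition = "unguided", tot = 0.7, trial_index = 5L)
  expect_equal(unname(build_design(u1)$X),
               rbind(c(0, 1, 0, 0.7), c(0, 1, 0, 0.7)))

  mixed <- data.frame(condition = c("guided", "unguided", "guided",
                                    "unguided", "guided", "unguided"),
                      tot = seq(0, 1, length.out = 6),
                      trial_index = 0:5)
  X <- build_design(mixed)$X
  n_g <- 3; n_u <- 3
  expect_equal(unname(colSums(X[, 1:3])), c(n_g, 2 * n_u, n_g))
  expect_equal(sum(X[, "T"]) + sum(X[, "D"]), 2 * n_g)
  # indicators sum to the ones vector; an added intercept is collinear
  expect_equal(unname(rowSums(X[, 1:3])), rep(1, 12))
  expect_lt(qr(cbind(1, X))$rank, 5)
})

test_that("pseudoinverse fit recovers exact coefficients and flags zero residuals", {
  set.seed(30)
  tr <- data.frame(condition = rep(c("guided", "unguided"), 10),
                   tot = seq(0, 1, length.out = 20), trial_index = 0:19)
  X <- build_design(tr)$X
  B <- c(1.5, 1.0, 0.6, -0.3)
  y <- drop(X %*% B)
  fit <- fit_glm(y, X)
  expect_equal(drop(fit$betas), B, tolerance = 1e-10)
  expect_equal(unname(fit$sigma2), 0, tolerance = 1e-20)
  expect_true(all(fit$undefined))
  expect_true(all(is.na(fit$t)))
})

test_that("contrast t is invariant to positive rescaling of the response", {
  set.seed(31)
  tr <- data.frame(condition = rep(c("guided", "unguided"), 15),
                   tot = seq(0, 1, length.out = 30), trial_index = 0:29)
  X <- build_design(tr)$X
  y <- drop(X %*% c(1.3, 1, 0.7, -0.2)) + rnorm(60, 0, 0.3)
  f1 <- fit_glm(y, X)
  f2 <- fit_glm(5.7 * y, X)
  expect_equal(f1$t, f2$t, tolerance = 1e-10)
  expect_equal(5.7 * f1$cope, f2$cope, tolerance = 1e-10)
})

test_that("null generating model centres the contrast copes at zero", {
  set.seed(32)
  tr <- data.frame(condition = rep(c("guided", "unguided"), 12),
                   tot = seq(0, 1, length.out = 24), trial_index = 0:23)
  X <- build_design(tr)$X
  copes <- replicate(200, {
    y <- drop(X %*% c(1, 1, 1, 0)) + rnorm(48, 0, 0.5)
    fit_glm(y, X)$cope["target", 1]
  })
  se <- sd(copes) / sqrt(length(copes))
  expect_lt(abs(mean(copes)), 3 * se + 1e-12)
})

test_that("behaviour GLM detects a planted reaction-time slope", {
  set.seed(33)
  n <- 80
  tr <- data.frame(condition = "guided", tot = seq(0, 1, length.out = n),
                   rt = runif(n, 0.4, 1.5), trial_index = 0:(n - 1))
  y <- 0.3 + 0.5 * tr$rt + rnorm(n, 0, 0.1)
  fit <- fit_glm(y, cbind(const = 1, tot = tr$tot, rt = tr$rt),
                 contrasts = list(rt = c(0, 0, 1)))
  expect_gt(fit$t["rt", 1], 3)
  fit2 <- behaviour_glm(y, tr)
  expect_equal(fit$t["rt", 1], fit2$t["rt", 1])

  # no planted slope: t on rt centred at zero over replicates
  tvals <- replicate(100, {
    yy <- 0.3 + rnorm(n, 0, 0.1)
    behaviour_glm(yy, tr)$t["rt", 1]
  })
  expect_lt(abs(mean(tvals)), 3 / sqrt(length(tvals)) + 0.05)

  # constant response: non-intercept betas vanish
  f0 <- behaviour_glm(rep(2, n), tr)
  expect_equal(unname(f0$betas[2:3, 1]), c(0, 0), tolerance = 1e-10)

  expect_error(behaviour_glm(y, transform(tr, condition = "unguided")),
               "guided")
})
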