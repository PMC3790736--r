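make_traj <- function(frames, ...) trajectory(frames, ...)

test_that("superposition recovers rigid motions exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  fit0 <- superpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$positions, ref, tolerance = 1e-10)
  # random proper rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(ref %*% t(R), 2, c(3, -2, 5), "+")
  fit <- superpose(moved, ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$positions, ref, tolerance = 1e-9)
  expect_error(superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("superposition rmsd agrees with an independent implementation", {
  set.seed(3)
  ref <- matrix(rnorm(36), 12, 3)
  frame <- ref + matrix(rnorm(36, sd = 0.4), 12, 3)
  ours <- superpose(frame, ref)
  fit <- bio3d::fit.xyz(as.numeric(t(ref)), as.numeric(t(frame)),
                        fixed.inds = 1:36, mobile.inds = 1:36)
  rmsd_bio3d <- sqrt(mean(rowSums(
    (matrix(fit, ncol = 3, byrow = TRUE) - ref)^2)))
  expect_equal(ours$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("rmsd trace is zero for static trajectories and matches
           superpose per frame", {
  set.seed(2)
  ref <- matrix(rnorm(24), 8, 3)
  static <- make_traj(list(ref, ref, ref))
  expect_equal(rmsd_trace(static), rep(0, 3), tolerance = 1e-10)
  moved <- ref + matrix(rnorm(24, sd = 0.5), 8, 3)
  tr <- make_traj(list(ref, moved))
  trace <- rmsd_trace(tr, ref)
  expect_length(trace, 2)
  expect_equal(trace[2], superpose(moved, ref)$rmsd, tolerance = 1e-12)
})

test_that("rmsf reproduces closed-form two-point oscillators", {
  base <- matrix(0, 2, 3)
  a <- 0.8
  up <- base; up[1, 1] <- a
  dn <- base; dn[1, 1] <- -a
  tr <- make_traj(rep(list(up, dn), 10))
  # window = full trajectory; no superposition (atom 2 pins the frame)
  r1 <- rmsf(tr, list(osc = 1, static = 2, both = 1:2),
             window = c(0, Inf))
  expect_equal(unname(r1["osc"]), a, tolerance = 1e-12)
  expect_equal(unname(r1["static"]), 0, tolerance = 1e-12)
  expect_equal(unname(r1["both"]), a / sqrt(2), tolerance = 1e-12)
  static <- make_traj(rep(list(base), 5))
  expect_equal(unname(rmsf(static, list(all = 1:2),
                           window = c(0, Inf))), c(0),
               tolerance = 1e-12)
  expect_error(rmsf(tr, list(g = integer(0))), "empty group")
})

test_that("rmsf and the correlation matrix are invariant under a global
           rigid motion after superposition", {
  set.seed(5)
  ref <- matrix(rnorm(18, sd = 3), 6, 3)
  frames <- lapply(1:20, function(i) ref + matrix(rnorm(18, sd = 0.3),
                                                  6, 3))
  tr <- make_traj(frames)
  th <- 1.1
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  tr2 <- make_traj(lapply(frames, function(f)
    sweep(f %*% t(R), 2, c(10, 0, -4), "+")))
  groups <- list(a = 1:2, b = 3:4, c = 5:6)
  r1 <- rmsf(tr, groups, window = c(0, Inf), superpose_set = 1:6,
             reference = ref)
  r2 <- rmsf(tr2, groups, window = c(0, Inf), superpose_set = 1:6,
             reference = ref)
  expect_equal(r1, r2, tolerance = 1e-9)
  C1 <- cross_correlation(tr, groups, window = c(0, Inf),
                          superpose_set = 1:6, reference = ref)
  C2 <- cross_correlation(tr2, groups, window = c(0, Inf),
                          superpose_set = 1:6, reference = ref)
  expect_equal(C1, C2, tolerance = 1e-8)
})

test_that("cross-correlation identifies in-phase and anti-phase motion", {
  base <- rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0))
  frames <- lapply(1:40, function(i) {
    d <- sin(i) * 0.5
    base + rbind(c(d, 0, 0), c(d, 0, 0), c(-d, 0, 0))
  })
  tr <- make_traj(frames)
  C <- cross_correlation(tr, list(a = 1, b = 2, c = 3),
                         window = c(0, Inf))
  expect_equal(C["a", "b"], 1, tolerance = 1e-10)
  expect_equal(C["a", "c"], -1, tolerance = 1e-10)
  expect_equal(max(abs(C - t(C))), 0, tolerance = 1e-12)
  expect_equal(unname(diag(C)), rep(1, 3))
  # zero-variance group flagged, not propagated as NaN
  frames2 <- lapply(frames, function(f) rbind(f, c(20, 0, 0)))
  C2 <- cross_correlation(make_traj(frames2),
                          list(a = 1, b = 2, frozen = 4),
                          window = c(0, Inf))
  expect_true(is.na(C2["frozen", "a"]))
  expect_identical(attr(C2, "undefined_groups"), "frozen")
  expect_equal(C2["a", "b"], 1, tolerance = 1e-10)
})

test_that("independent random displacements decorrelate like 1/sqrt(n)", {
  set.seed(11)
  base <- rbind(c(0, 0, 0), c(8, 0, 0))
  nf <- 4000
  frames <- lapply(seq_len(nf), function(i)
    base + matrix(rnorm(6, sd = 0.3), 2, 3))
  C <- cross_correlation(make_traj(frames), list(a = 1, b = 2),
                         window = c(0, Inf))
  expect_lt(abs(C["a", "b"]), 0.05)
})

test_that("mode switch gives consistent correlations for single-atom
           groups", {
  set.seed(13)
  frames <- lapply(1:30, function(i) matrix(rnorm(9), 3, 3))
  g <- list(a = 1, b = 2, c = 3)
  C1 <- cross_correlation(make_traj(frames), g, window = c(0, Inf),
                          mode = "center")
  C2 <- cross_correlation(make_traj(frames), g, window = c(0, Inf),
                          mode = "atom_pairs")
  expect_equal(C1, C2, tolerance = 1e-10)
})

test_that("Pearson agreement matches the textbook formula", {
  expect_equal(method_agreement(1:5, 1:5), 1)
  expect_equal(method_agreement(1:5, 5:1), -1)
  a <- c(1.2, 0.7, 2.5, 1.9, 0.4)
  b <- c(0.9, 1.1, 2.2, 2.0, 0.6)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(method_agreement(a, b), hand, tolerance = 1e-12)
  expect_error(method_agreement(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(method_agreement(1:2, 1:2), "length")
})

test_that("trajectory constructor enforces its invariants", {
  f <- list(matrix(0, 2, 3), matrix(0, 3, 3))
  expect_error(trajectory(f), "same particle count")
  expect_error(trajectory(list(matrix(0, 2, 3), matrix(0, 2, 3)),
                          times = c(2, 1)), "strictly increasing")
})
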