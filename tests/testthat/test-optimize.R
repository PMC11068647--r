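# Distance objective, constraint penalty and the stochastic ranking
# evolution strategy.

test_that("normalised distance objective matches direct arithmetic", {
  expect_equal(distanceObjective(c(100, 50), targetProfile(c(a = 100, b = 50))),
               0)
  expect_equal(distanceObjective(c(a = 110, b = 50),
                                 targetProfile(c(a = 100, b = 50))),
               (50 / 100) * 10^2)
  # hand-evaluated four-target case with unit offsets
  tg <- c(SBP = 160, DBP = 100, HR = 75, SV = 70)
  expect_equal(distanceObjective(tg + 1, targetProfile(tg)),
               sum(min(tg) / tg))
  # brute-force oracle on random cases
  set.seed(2)
  for (i in 1:10) {
    des <- runif(5, 10, 200); names(des) <- letters[1:5]
    x <- des * runif(5, 0.8, 1.2)
    oracle <- 0
    for (j in 1:5) oracle <- oracle + (min(des) / des[j]) * (x[j] - des[j])^2
    expect_equal(distanceObjective(x, targetProfile(des)), unname(oracle))
  }
  expect_error(targetProfile(c(a = -1)), class = "invalidArgument")
  expect_error(distanceObjective(c(b = 1), targetProfile(c(a = 1))),
               class = "invalidArgument")
})

test_that("trajectory penalty equals brute-force double summation", {
  cs <- constraintSet(c("u", "v"), lower = c(0, -1), upper = c(1, 1))
  inside <- cbind(u = runif(20), v = runif(20, -1, 1))
  expect_equal(penaltyValue(inside, cs), 0)
  one <- cbind(u = c(0.5, 3), v = c(0, 0))  # one sample 2 above its bound
  expect_equal(penaltyValue(one, cs), 4)
  set.seed(3)
  traj <- cbind(u = rnorm(50, 0.5, 1), v = rnorm(50, 0, 1.5))
  oracle <- 0
  for (t in 1:50) {
    for (j in 1:2) {
      y <- traj[t, j]
      oracle <- oracle + max(0, cs$lower[j] - y)^2 + max(0, y - cs$upper[j])^2
    }
  }
  expect_equal(penaltyValue(traj, cs), oracle)
  expect_error(constraintSet("a", 2, 1), class = "invalidArgument")
})

test_that("the evolution strategy solves the sphere and an active-constraint
          problem", {
  r <- sresOptimize(function(x) sum(x^2), function(x) 0,
                    rep(-5, 10), rep(5, 10),
                    sresOptions(lambda = 100, mu = 15, generations = 150,
                                seed = 3))
  expect_lt(r$value, 1e-4)
  r2 <- sresOptimize(function(x) x^2, function(x) max(0, 1 - x)^2,
                     -5, 5,
                     sresOptions(lambda = 60, mu = 10, generations = 80,
                                 seed = 2))
  expect_equal(r2$par, 1, tolerance = 1e-2)
  expect_equal(r2$penalty, 0)
})

test_that("the optimizer is deterministic for a fixed seed and rejects
          degenerate bounds", {
  f <- function(x) sum((x - 1)^2)
  a <- sresOptimize(f, function(x) 0, rep(-5, 3), rep(5, 3),
                    sresOptions(lambda = 30, mu = 5, generations = 20,
                                seed = 7))
  b <- sresOptimize(f, function(x) 0, rep(-5, 3), rep(5, 3),
                    sresOptions(lambda = 30, mu = 5, generations = 20,
                                seed = 7))
  expect_identical(a$history, b$history)
  expect_identical(a$par, b$par)
  expect_error(sresOptimize(f, function(x) 0, c(0, 0), c(0, 1)),
               class = "invalidArgument")
})

test_that("stochastic ranking orders infeasible candidates by penalty", {
  set.seed(5)
  # objective concordant with penalty: ranking must recover penalty order
  ok <- 0
  for (rep in 1:200) {
    pen <- sample(seq(1, 6))
    idx <- raasim:::stochasticRank(obj = pen, pen = pen, Pf = 0.45)
    ok <- ok + identical(order(pen), idx)
  }
  expect_gte(ok / 200, 0.99)
  # objective anti-concordant: the sort still moves toward penalty order
  inv <- function(o, pen) sum(outer(seq_along(o), seq_along(o), "<") &
                                outer(pen[o], pen[o], ">"))
  worse <- 0
  for (rep in 1:100) {
    pen <- sample(seq(1, 8))
    obj <- -pen
    idx <- raasim:::stochasticRank(obj, pen, Pf = 0.45)
    worse <- worse + (inv(idx, pen) >= inv(rev(order(pen)), pen))
  }
  expect_lt(worse / 100, 0.2)
})

test_that("feasible candidates are always compared by objective", {
  set.seed(6)
  for (rep in 1:20) {
    obj <- sample(10)
    idx <- raasim:::stochasticRank(obj, pen = rep(0, 10), Pf = 0.45)
    expect_identical(idx, order(obj))
  }
})
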