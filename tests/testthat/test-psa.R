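test_that("strict dominance and frontier ICERs follow the textbook rules", {
  inc <- incremental_analysis(data.frame(strategy = c("A", "B"),
                                         cost = c(100, 50),
                                         qaly = c(1, 2)))
  tabA <- inc$table[inc$table$strategy == "A", ]
  expect_equal(tabA$label, "dominated")
  # published base-case means: USS strictly dominated by MMS, MMS on the
  # frontier against no screening
  inc2 <- incremental_analysis(data.frame(
    strategy = c("none", "MMS", "USS"),
    cost = c(179, 598, 824), qaly = c(14.290, 14.357, 14.297)))
  t2 <- inc2$table
  expect_equal(t2$label[t2$strategy == "USS"], "dominated")
  expect_equal(unname(inc2$dominated_by["USS"]), "MMS")
  expect_equal(t2$label[t2$strategy == "MMS"], "frontier")
  expect_equal(t2$icer[t2$strategy == "MMS"], (598 - 179) / (14.357 - 14.290))
})

test_that("extended dominance removes mid-frontier kinks only", {
  # increasing ICERs: everything stays on the frontier
  keep <- incremental_analysis(data.frame(strategy = c("A", "B", "C"),
                                          cost = c(0, 100, 150),
                                          qaly = c(0, 1, 1.05)))
  expect_equal(keep$table$label, rep("frontier", 3))
  expect_equal(keep$table$icer[2:3], c(100, 1000))
  # the most effective strategy cannot be extendedly dominated even with a
  # steep final ICER (it is optimal for a high enough willingness to pay)
  steep <- incremental_analysis(data.frame(strategy = c("A", "B", "C"),
                                           cost = c(0, 100, 150),
                                           qaly = c(0, 1, 1.01)))
  expect_equal(steep$table$label, rep("frontier", 3))
  # a genuine kink: B pricier per QALY than the step to C
  kink <- incremental_analysis(data.frame(strategy = c("A", "B", "C"),
                                          cost = c(0, 100, 150),
                                          qaly = c(0, 0.5, 1.01)))
  expect_equal(kink$table$label[kink$table$strategy == "B"],
               "extendedly dominated")
})

test_that("the frontier agrees with brute force on random instances", {
  set.seed(61)
  for (i in 1:1000) {
    n <- 4
    cost <- round(runif(n, 0, 1000))
    qaly <- round(runif(n, 0, 2), 3)
    mine <- incremental_analysis(data.frame(strategy = letters[1:n],
                                            cost = cost, qaly = qaly))
    oracle <- frontier_oracle(cost, qaly)
    ord <- match(mine$table$strategy, letters[1:n])
    expect_equal(mine$table$label, oracle[ord],
                 info = paste("instance", i))
  }
})

test_that("CEAC probabilities are proper and tie-splitting works", {
  psa <- structure(list(
    cost = cbind(none = c(0, 0, 0), MMS = c(10, 10, 10),
                 USS = c(20, 5, 20)),
    qaly = cbind(none = c(1, 1, 1), MMS = c(1.1, 0.9, 1.2),
                 USS = c(1, 1.05, 0.8)),
    strategies = c("none", "MMS", "USS")), class = "ova_psa")
  cc <- ceac(psa, wtp = c(0, 100, 1e5))
  m <- as.matrix(cc[, -1])
  expect_true(all(abs(rowSums(m) - 1) < 1e-12))
  expect_true(all(m >= 0 & m <= 1))
  # at zero willingness to pay the cheapest strategy wins each draw
  expect_equal(unname(m[1, "none"]), 1)
  # degenerate draws: probabilities in {0, 1}
  psa2 <- structure(list(cost = cbind(a = rep(1, 4), b = rep(2, 4)),
                         qaly = cbind(a = rep(1, 4), b = rep(2, 4)),
                         strategies = c("a", "b")), class = "ova_psa")
  cc2 <- ceac(psa2, wtp = c(0, 10))
  expect_true(all(as.matrix(cc2[, -1]) %in% c(0, 1)))
  expect_error(ceac(psa2, wtp = numeric()), "non-empty")
})

test_that("a single-draw PSA reports that draw as its mean", {
  inp <- small_inputs()
  psa <- run_psa(inp, n_draws = 1, seed = 71)
  s <- summary(psa)
  tab <- s$table
  expect_equal(tab$mean, tab$ci_low)
  expect_equal(tab$mean, tab$ci_high)
})

test_that("degenerate distributions give identical draws and zero-width CIs", {
  inp <- small_inputs()
  tab <- parameter_table()
  tab$ci_low <- tab$mean; tab$ci_high <- tab$mean
  dists <- fit_all_distributions(tab)
  psa <- run_psa(inp, n_draws = 5, seed = 72, dists = dists,
                 effectiveness_uncertainty = FALSE)
  expect_equal(apply(psa$cost, 2, sd), c(none = 0, MMS = 0, USS = 0))
  expect_equal(apply(psa$qaly, 2, sd), c(none = 0, MMS = 0, USS = 0))
})

test_that("PSA runs are deterministic under a fixed seed", {
  inp <- small_inputs()
  a <- run_psa(inp, n_draws = 5, seed = 73)
  b <- run_psa(inp, n_draws = 5, seed = 73)
  expect_identical(a$cost, b$cost)
  expect_identical(a$qaly, b$qaly)
  expect_identical(a$params, b$params)
})

test_that("percentile estimates converge at the root-n rate", {
  # MC error of the 97.5th percentile estimator from PSA-sized draw sets
  set.seed(74)
  draws <- rlnorm(200000, 5, 0.4)
  est <- function(n, reps = 200) {
    vapply(seq_len(reps), function(i) {
      stats::quantile(sample(draws, n), 0.975, names = FALSE)
    }, 0)
  }
  sd_small <- sd(est(500))
  sd_large <- sd(est(8000))
  ratio <- sd_small / sd_large
  expect_gt(ratio, 2.5) # expected 4, allow MC slack
  expect_lt(ratio, 6.5)
})
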