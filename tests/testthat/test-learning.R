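two_node_template <- function() {
  build_network(
    list(bbn_node("p", c("y", "n")), bbn_node("c", c("y", "n"))),
    list(bbn_cpt("p", prob = c(0.5, 0.5)),
         bbn_cpt("c", "p", matrix(0.5, 2, 2))))
}

test_that("ml_estimate matches closed-form smoothed frequencies", {
  net <- two_node_template()
  # child seen in state y 2 of 4 times under p = y
  data <- data.frame(p = c("y", "y", "y", "y", "n", "n"),
                     c = c("y", "y", "n", "n", "y", "n"),
                     stringsAsFactors = FALSE)
  fit0 <- ml_estimate(net, data, prior_count = 0)
  expect_equal(unname(fit0$cpts$c$prob["y", "y"]), 0.5)
  expect_equal(unname(fit0$cpts$p$prob[1, ]), c(4, 2) / 6)

  # 0 of 2 observations in a binary cell, prior 1 -> (0+1)/(2+2)
  d2 <- data.frame(p = c("y", "y"), c = c("n", "n"), stringsAsFactors = FALSE)
  fit1 <- ml_estimate(net, d2, prior_count = 1)
  expect_equal(unname(fit1$cpts$c$prob["y", "y"]), 0.25)
  # unvisited row with positive prior becomes uniform
  expect_equal(unname(fit1$cpts$c$prob["n", ]), c(0.5, 0.5))

  expect_error(ml_estimate(net, data.frame(p = c("y", NA), c = c("y", "n"))),
               class = "sibbn_missing_data")
})

test_that("locked deterministic tables survive any fit unchanged", {
  net <- build_model("1A")
  sim <- simulate_survey("1A", n = 200, poc_missing = 30, seed = 4)
  before_env <- net$cpts$chance_contamination_environment
  before_sto <- net$cpts$chance_contamination_storage
  fit <- em_fit(net, sim$table, max_iter = 10)
  expect_identical(fit$network$cpts$chance_contamination_environment$prob,
                   before_env$prob)
  expect_identical(fit$network$cpts$chance_contamination_storage$prob,
                   before_sto$prob)
  mlfit <- ml_estimate(build_model("1A"), sim$complete)
  expect_identical(mlfit$cpts$chance_contamination_storage$prob,
                   before_sto$prob)
})

test_that("EM log-likelihood is non-decreasing and complete data converge to ML", {
  for (seed in 1:6) {
    sim <- simulate_survey("1A", n = 150, poc_missing = 25, seed = seed)
    fit <- em_fit(build_model("1A"), sim$table, prior_count = 1)
    expect_true(all(diff(fit$loglik) >= -1e-8))
    expect_true(fit$converged)
  }
  # complete data: one EM iteration equals the closed form, any prior
  sim <- simulate_survey("1B", n = 120, poc_missing = 0, seed = 9)
  for (prior in c(0.5, 1)) {
    em <- em_fit(build_model("1B"), sim$table, prior_count = prior)
    ml <- ml_estimate(build_model("1B"), sim$table, prior_count = prior)
    for (v in names(ml$cpts))
      expect_equal(em$network$cpts[[v]]$prob, ml$cpts[[v]]$prob,
                   tolerance = 1e-12)
  }
})

test_that("a fully missing isolated node is an EM fixed point", {
  net <- build_network(
    list(bbn_node("a", c("y", "n")), bbn_node("b", c("y", "n"))),
    list(bbn_cpt("a", prob = c(0.3, 0.7)), bbn_cpt("b", prob = c(0.5, 0.5))))
  data <- data.frame(a = rep(NA_character_, 40),
                     b = sample(c("y", "n"), 40, TRUE), stringsAsFactors = FALSE)
  fit <- em_fit(net, data, prior_count = 0)
  # E-step reproduces the prior as expected counts, so the M-step returns it
  expect_equal(unname(fit$network$cpts$a$prob[1, ]), c(0.3, 0.7),
               tolerance = 1e-12)
})

test_that("EM recovers truth parameters, better with more data", {
  errs <- sapply(1:3, function(seed) {
    sapply(c(250, 1000), function(n) {
      sim <- simulate_survey("1B", n = n, poc_missing = round(0.15 * n),
                             seed = seed)
      fit <- em_fit(build_model("1B"), sim$table)
      cpt_recovery_error(sim$truth, fit$network)$overall
    })
  })
  avg <- rowMeans(errs)
  expect_lt(avg[2], avg[1])          # error shrinks with n
  expect_lt(avg[2], 0.05)
})

test_that("initialization is reproducible and well-formed", {
  net <- build_model("2B")
  u <- initialize_cpts(net, "uniform")
  expect_true(all(u$cpts$ecoli_pou$prob == 0.5))
  r1 <- initialize_cpts(net, "random", seed = 5)
  r2 <- initialize_cpts(net, "random", seed = 5)
  for (v in names(net$cpts))
    expect_identical(r1$cpts[[v]]$prob, r2$cpts[[v]]$prob)
  expect_false(identical(r1$cpts$ecoli_pou$prob,
                         initialize_cpts(net, "random", seed = 6)$cpts$ecoli_pou$prob))
  expect_equal(unname(rowSums(r1$cpts$ecoli_pou$prob)),
               rep(1, nrow(r1$cpts$ecoli_pou$prob)), tolerance = 1e-12)
  expect_true(all(r1$cpts$ecoli_pou$prob > 0))
  # locked tables are not re-initialized
  expect_identical(r1$cpts$chance_contamination_storage$prob,
                   net$cpts$chance_contamination_storage$prob)
})

test_that("an impossible record is reported by index", {
  det <- build_network(
    list(bbn_node("a", c("a1", "a2")), bbn_node("b", c("b1", "b2"))),
    list(bbn_cpt("a", prob = c(1, 0)),
         bbn_cpt("b", "a", rbind(c(1, 0), c(0, 1)))))
  data <- data.frame(a = c("a1", "a2"), b = c("b1", "b2"),
                     stringsAsFactors = FALSE)
  expect_error(em_fit(det, data, prior_count = 0, max_iter = 2),
               class = "sibbn_impossible_record", regexp = "record 2")
})
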