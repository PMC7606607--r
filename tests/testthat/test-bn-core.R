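test_that("a minimal chain builds and invalid structures are rejected", {
  a <- bbn_node("a", c("a1", "a2"))
  b <- bbn_node("b", c("b1", "b2"))
  net <- build_network(list(a, b), list(
    bbn_cpt("a", prob = c(0.4, 0.6)),
    bbn_cpt("b", "a", rbind(c(0.9, 0.1), c(0.2, 0.8)))))
  expect_s3_class(net, "bbn")
  expect_setequal(names(net$nodes), c("a", "b"))

  # cycle a -> b -> a
  expect_error(build_network(list(a, b), list(
    bbn_cpt("a", "b", rbind(c(0.5, 0.5), c(0.5, 0.5))),
    bbn_cpt("b", "a", rbind(c(0.5, 0.5), c(0.5, 0.5))))),
    class = "sibbn_cycle")

  # duplicate node name
  expect_error(build_network(list(a, bbn_node("a", c("x", "y"))), list(
    bbn_cpt("a", prob = c(0.5, 0.5)))), class = "sibbn_duplicate_node")

  # binary child of 3 binary parents needs 8 rows, not 7
  ps <- lapply(c("p1", "p2", "p3"), bbn_node, states = c("y", "n"))
  ch <- bbn_node("c", c("y", "n"))
  cpts <- c(lapply(c("p1", "p2", "p3"), bbn_cpt, prob = c(0.5, 0.5)),
            list(bbn_cpt("c", c("p1", "p2", "p3"), matrix(0.5, 7, 2))))
  expect_error(build_network(c(ps, list(ch)), cpts),
               class = "sibbn_cpt_rows",
               regexp = "7 rows supplied, 8 required")

  # row not summing to one
  expect_error(build_network(list(a), list(bbn_cpt("a", prob = c(0.5, 0.6)))),
               class = "sibbn_cpt_rowsum")

  # unknown parent
  expect_error(build_network(list(a), list(
    bbn_cpt("a", "ghost", rbind(c(0.5, 0.5), c(0.5, 0.5))))),
    class = "sibbn_unknown_parent")

  # missing CPT
  expect_error(build_network(list(a, b), list(bbn_cpt("a", prob = c(0.5, 0.5)))),
               class = "sibbn_invalid_network")
})

test_that("node and state invariants are enforced at construction", {
  expect_error(bbn_node("x", "only_one"), class = "sibbn_invalid_node")
  expect_error(bbn_node("x", c("s", "s")), class = "sibbn_invalid_node")
  expect_error(bbn_cpt("x", c("p", "p"), matrix(0.5, 4, 2)),
               class = "sibbn_invalid_cpt")
  expect_error(bbn_cpt("x", "x", matrix(0.5, 2, 2)), class = "sibbn_invalid_cpt")
})

test_that("topological order places parents first with name-order tie-break", {
  mk <- function(n, ...) bbn_node(n, c("y", "n"))
  chain <- build_network(
    list(mk("a"), mk("b"), mk("c")),
    list(bbn_cpt("a", prob = c(0.5, 0.5)),
         bbn_cpt("b", "a", matrix(0.5, 2, 2)),
         bbn_cpt("c", "b", matrix(0.5, 2, 2))))
  expect_identical(topological_order(chain), c("a", "b", "c"))

  collider <- build_network(
    list(mk("b"), mk("a"), mk("c")),   # declaration order scrambled
    list(bbn_cpt("a", prob = c(0.5, 0.5)),
         bbn_cpt("b", prob = c(0.5, 0.5)),
         bbn_cpt("c", c("a", "b"), matrix(0.5, 4, 2))))
  expect_identical(topological_order(collider), c("a", "b", "c"))

  m <- build_model("1A")
  ord <- topological_order(m)
  for (v in names(m$nodes)) {
    for (p in m$cpts[[v]]$parents)
      expect_lt(match(p, ord), match(v, ord))
  }
})

test_that("joint probability follows the chain rule and normalizes", {
  ind <- build_network(
    list(bbn_node("a", c("y", "n")), bbn_node("b", c("y", "n"))),
    list(bbn_cpt("a", prob = c(0.5, 0.5)), bbn_cpt("b", prob = c(0.5, 0.5))))
  expect_equal(joint_probability(ind, c(a = "y", b = "n")), 0.25)

  det <- chain_net()
  expect_equal(joint_probability(det, c(a = "a1", b = "b2")), 0)
  expect_error(joint_probability(det, c(a = "bogus", b = "b1")),
               class = "sibbn_unknown_state")
  expect_error(joint_probability(det, c(a = "a1")),
               class = "sibbn_bad_assignment")

  for (seed in 1:5) {
    net <- random_network(seed)
    grid <- enum_grid(net)
    expect_equal(sum(grid$.p), 1, tolerance = 1e-9)
    expect_true(all(grid$.p >= 0 & grid$.p <= 1))
  }
})

test_that("JSON round trip reproduces CPT values bit-for-bit", {
  for (net in list(random_network(11), build_model("2B"),
                   default_truth("1B", seed = 3))) {
    f <- withr::local_tempfile(fileext = ".json")
    write_network(net, f)
    back <- read_network(f)
    expect_identical(names(back$nodes), names(net$nodes))
    for (v in names(net$cpts)) {
      expect_identical(back$cpts[[v]]$prob, net$cpts[[v]]$prob)
      expect_identical(back$cpts[[v]]$locked, net$cpts[[v]]$locked)
      expect_identical(back$nodes[[v]]$states, net$nodes[[v]]$states)
    }
  }
})

test_that("cpt_rows exposes explicit parent-state tuples", {
  net <- build_model("1A")
  rows <- cpt_rows(net, "chance_contamination_storage")
  expect_equal(nrow(rows), 8)
  expect_named(rows, c("storage_covered", "storage_cracked", "place_of_storage",
                       "p_low", "p_moderate", "p_high"))
  expect_true(all(rowSums(rows[, 4:6]) == 1))
})
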