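test_that("posterior handles trivial cases exactly", {
  net <- build_network(
    list(bbn_node("r", c("s1", "s2", "s3"))),
    list(bbn_cpt("r", prob = c(0.2, 0.3, 0.5))))
  expect_equal(posterior(net, "r")$posterior,
               c(s1 = 0.2, s2 = 0.3, s3 = 0.5))

  det <- chain_net()
  expect_equal(posterior(det, "b", c(a = "a1"))$posterior, c(b1 = 1, b2 = 0))
  expect_equal(posterior(det, "a", c(b = "b2"))$posterior, c(a1 = 0, a2 = 1))
})

test_that("variable elimination matches enumeration on random networks", {
  for (seed in 1:15) {
    net <- random_network(seed)
    ev <- random_evidence(net, min(3, length(net$nodes) - 1), seed + 100)
    q <- setdiff(names(net$nodes), names(ev))[1]
    po <- posterior(net, q, ev)$posterior
    en <- enum_posterior(net, q, as.list(ev))
    expect_equal(unname(po), en, tolerance = 1e-10)
    expect_equal(evidence_probability(net, ev),
                 enum_evidence_probability(net, as.list(ev)),
                 tolerance = 1e-10)
  }
})

test_that("posterior is invariant to the elimination order", {
  net <- random_network(21, n_nodes = 7)
  ev <- random_evidence(net, 2, 22)
  q <- setdiff(names(net$nodes), names(ev))[1]
  elim <- setdiff(names(net$nodes), c(q, names(ev)))
  ref <- posterior(net, q, ev)$posterior
  set.seed(23)
  for (i in 1:3) {
    alt <- posterior(net, q, ev, elim_order = sample(elim))$posterior
    expect_equal(alt, ref, tolerance = 1e-12)
  }
  expect_error(posterior(net, q, ev, elim_order = elim[-1]),
               class = "sibbn_bad_elim_order")
})

test_that("evidence on a d-separated node leaves the posterior unchanged", {
  # a -> b, c isolated: c is d-separated from b
  net <- build_network(
    list(bbn_node("a", c("y", "n")), bbn_node("b", c("y", "n")),
         bbn_node("c", c("y", "n"))),
    list(bbn_cpt("a", prob = c(0.3, 0.7)),
         bbn_cpt("b", "a", rbind(c(0.9, 0.1), c(0.2, 0.8))),
         bbn_cpt("c", prob = c(0.6, 0.4))))
  expect_equal(posterior(net, "b", c(c = "y"))$posterior,
               posterior(net, "b")$posterior, tolerance = 1e-12)

  # collider a -> v <- b: a and b are d-separated while v is unobserved
  col <- build_network(
    list(bbn_node("a", c("y", "n")), bbn_node("b", c("y", "n")),
         bbn_node("v", c("y", "n"))),
    list(bbn_cpt("a", prob = c(0.3, 0.7)),
         bbn_cpt("b", prob = c(0.8, 0.2)),
         bbn_cpt("v", c("a", "b"),
                 rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.4, 0.6), c(0.1, 0.9)))))
  expect_equal(posterior(col, "a", c(b = "y"))$posterior,
               posterior(col, "a")$posterior, tolerance = 1e-12)
})

test_that("impossible evidence raises a classed error, not a zero vector", {
  det <- chain_net()
  expect_error(posterior(det, "a", c(b = "b1", a = "a2")),
               class = "sibbn_bad_evidence")   # query in evidence is rejected
  net <- build_network(
    list(bbn_node("a", c("a1", "a2")), bbn_node("b", c("b1", "b2")),
         bbn_node("c", c("c1", "c2"))),
    list(bbn_cpt("a", prob = c(1, 0)),
         bbn_cpt("b", "a", rbind(c(1, 0), c(0, 1))),
         bbn_cpt("c", "b", rbind(c(0.5, 0.5), c(0.5, 0.5)))))
  # a is surely a1, hence b is surely b1: b = b2 is impossible
  expect_error(posterior(net, "c", c(b = "b2")),
               class = "sibbn_impossible_evidence")
  expect_equal(evidence_probability(net, c(b = "b2")), 0)
})

test_that("evidence_probability marginalizes correctly", {
  net <- random_network(31, n_nodes = 5)
  expect_equal(evidence_probability(net), 1)
  full <- vapply(names(net$nodes), function(v) {
    set.seed(match(v, names(net$nodes)) + 500)
    sample(net$nodes[[v]]$states, 1)
  }, character(1))
  expect_equal(evidence_probability(net, full), joint_probability(net, full),
               tolerance = 1e-12)
  part <- full[1:2]
  expect_equal(evidence_probability(net, part),
               enum_evidence_probability(net, as.list(part)),
               tolerance = 1e-10)
})

test_that("predict_outcome marginalizes missing fields of a record", {
  truth <- default_truth("1A")
  rec <- c(household_water_treatment = "no", storage_covered = "yes")
  expect_equal(predict_outcome(truth, rec, "ecoli_pou"),
               enum_posterior(truth, "ecoli_pou", as.list(rec))[1],
               tolerance = 1e-9)
  # record observing nothing: the prior marginal
  none <- stats::setNames(rep(NA_character_, 2), names(rec))
  expect_equal(predict_outcome(truth, none, "ecoli_pou"),
               unname(posterior(truth, "ecoli_pou")$posterior[["detected"]]))
  # the outcome itself, if present, is excluded from the evidence
  rec2 <- c(rec, ecoli_pou = "detected")
  expect_equal(predict_outcome(truth, rec2, "ecoli_pou"),
               predict_outcome(truth, rec, "ecoli_pou"))
})

test_that("with all outcome parents observed the prediction reads the CPT row", {
  truth <- default_truth("1B")
  rec <- c(ecoli_poc = "detected", household_water_treatment = "no",
           chance_contamination_environment = "high",
           chance_contamination_storage = "moderate",
           fullness_level = "half")
  key <- paste(rec[truth$cpts$ecoli_pou$parents], collapse = "\x1f")
  expect_equal(predict_outcome(truth, rec, "ecoli_pou"),
               unname(truth$cpts$ecoli_pou$prob[key, "detected"]),
               tolerance = 1e-12)
})
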