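test_that("scoring awards 1 to the best situation in each variable", {
  expect_identical(score_variable("storage_covered", "yes"), 1L)
  expect_identical(score_variable("storage_cracked", "no"), 1L)
  expect_identical(score_variable("storage_covered", "no"), 0L)
  expect_identical(score_variable("proper_fencing", "yes"), 1L)
  expect_identical(score_variable("latrine_within_10m", "yes"), 0L)
  expect_error(score_variable("storage_covered", "maybe"),
               class = "sibbn_unknown_state")
  expect_error(score_variable("type_of_poc", "well"), class = "sibbn_not_scored")
})

test_that("cluster cut-offs map totals to categories under both semantics", {
  sto <- storage_rule()                       # contamination-risk direction
  expect_identical(cluster_index(sto, c(1, 1, 1)), "low")
  expect_identical(cluster_index(sto, c(1, 1, 0)), "moderate")
  expect_identical(cluster_index(sto, c(1, 0, 0)), "high")
  expect_identical(cluster_index(sto, c(0, 0, 0)), "high")

  lit <- storage_rule("literal")              # bands exactly as quoted
  expect_identical(cluster_index(lit, c(1, 1, 1)), "high")
  expect_identical(cluster_index(lit, c(0, 0, 0)), "low")
  expect_identical(cluster_index(lit, c(1, 1, 0)), "moderate")

  env <- environment_rule()
  expect_identical(cluster_index(env, rep(1, 6)), "low")       # total 6
  expect_identical(cluster_index(env, c(1, 1, 1, 1, 1, 0)), "low")   # 5
  expect_identical(cluster_index(env, c(1, 1, 1, 1, 0, 0)), "moderate") # 4
  expect_identical(cluster_index(env, c(1, 1, 1, 0, 0, 0)), "moderate") # 3
  expect_identical(cluster_index(env, c(1, 1, 0, 0, 0, 0)), "high")  # 2
  expect_identical(cluster_index(env, rep(0, 6)), "high")

  expect_error(cluster_index(sto, c(1, 1)), class = "sibbn_invalid_rule")
  expect_error(cluster_index(sto, c(1, 2, 0)), class = "sibbn_invalid_rule")
  expect_error(index_rule(c("a", "b"), list(low = 0, moderate = 1, high = 3)),
               class = "sibbn_invalid_rule")   # gap at 2
})

test_that("deterministic CPTs reproduce the index over every row", {
  inv <- si_variables()
  for (mk in list(storage_rule, environment_rule)) {
    for (sem in c("contamination_risk", "literal")) {
      rule <- mk(sem)
      cpt <- deterministic_cpt(rule, "chance", inv)
      expect_true(cpt$locked)
      expect_equal(nrow(cpt$prob), 2^length(rule$parents))
      expect_true(all(rowSums(cpt$prob) == 1))
      expect_true(all(apply(cpt$prob, 1, max) == 1))   # every row degenerate
      grid <- do.call(expand.grid,
                      c(lapply(inv[rule$parents], `[[`, "states"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
      for (i in seq_len(nrow(grid))) {
        scores <- mapply(function(p, s) score_variable(inv[[p]], s),
                         rule$parents, as.character(grid[i, ]))
        expect_identical(colnames(cpt$prob)[cpt$prob[i, ] == 1],
                         cluster_index(rule, scores))
      }
    }
  }
})

test_that("environment rows with exactly four best states map to moderate", {
  cpt <- deterministic_cpt(environment_rule(), "chance")
  inv <- si_variables()
  grid <- do.call(expand.grid,
                  c(lapply(inv[environment_rule()$parents], `[[`, "states"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  totals <- rowSums(mapply(function(p) grid[[p]] == inv[[p]]$best_state,
                           names(grid)))
  expect_true(all(cpt$prob[totals == 4, "moderate"] == 1))
})

test_that("E. coli counts dichotomize at zero", {
  expect_identical(discretize_ecoli(0), "not_detected")
  expect_identical(discretize_ecoli(7), "detected")
  expect_identical(discretize_ecoli(c(0, 1, 250)),
                   c("not_detected", "detected", "detected"))
  expect_error(discretize_ecoli(-1), class = "sibbn_invalid_value")
})

test_that("model variants have the published structure", {
  m1a <- build_model("1A")
  expect_equal(length(m1a$nodes), 15)
  expect_false("fullness_level" %in% names(m1a$nodes))
  expect_setequal(m1a$cpts$ecoli_pou$parents,
                  c("ecoli_poc", "household_water_treatment",
                    "chance_contamination_environment",
                    "chance_contamination_storage"))
  expect_identical(m1a$cpts$ecoli_poc$parents, "type_of_poc")

  m1b <- build_model("1B")
  expect_equal(length(m1b$nodes), 16)
  expect_true("fullness_level" %in% m1b$cpts$ecoli_pou$parents)
  expect_equal(length(m1b$cpts$ecoli_pou$parents), 5)

  m2a <- build_model("2A")
  expect_equal(length(m2a$nodes), 20)
  expect_equal(length(m2a$cpts$ecoli_poc$parents), 6)
  expect_setequal(m2a$cpts$ecoli_poc$parents,
                  c("cracked_structure", "livestock_nearby_poc", "proper_fencing",
                    "excreta_garbage_nearby", "prone_to_erosion",
                    "latrine_within_10m"))
  expect_equal(length(m2a$cpts$ecoli_pou$parents), 4)

  m2b <- build_model("2B")
  expect_equal(length(m2b$nodes), 21)
  expect_equal(length(m2b$cpts$ecoli_poc$parents), 6)
  expect_equal(length(m2b$cpts$ecoli_pou$parents), 5)
  expect_equal(nrow(m2b$cpts$ecoli_poc$prob), 64)

  for (tag in c("1A", "1B", "2A", "2B")) {
    net <- build_model(tag)                    # validation = acyclicity proof
    expect_s3_class(net, "bbn")
    expect_identical(net$variant, tag)
    locked <- vapply(net$cpts, `[[`, logical(1), "locked")
    expect_setequal(names(locked)[locked],
                    c("chance_contamination_environment",
                      "chance_contamination_storage"))
    # the six environment parents and three storage parents wire the intermediates
    expect_equal(length(net$cpts$chance_contamination_environment$parents), 6)
    expect_equal(length(net$cpts$chance_contamination_storage$parents), 3)
  }
  expect_error(model_variant("3C"), class = "sibbn_invalid_variant")
})
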