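# The study-design replica and the synthetic decision-matrix generator.

test_that("the replica design has 16 alternatives and 15 criteria with the elicited weight terms", {
  design <- uti_study_design()
  expect_length(design$alternatives, 16)
  expect_equal(nrow(design$criteria), 15)
  terms <- stats::setNames(design$criteria$weight_label, design$criteria$id)
  expect_equal(unname(terms[c("C5", "C6")]), rep("Very High", 2))
  expect_equal(unname(terms[c("C3", "C4", paste0("C", 10:15))]), rep("High", 8))
  expect_equal(unname(terms[paste0("C", 7:9)]), rep("Moderate", 3))
  expect_equal(unname(terms["C2"]), "Low")
  expect_equal(unname(terms["C1"]), "Very Low")
  # the Very Low weight of specimen volume carries the (0, 0, 0.25) fuzzy number
  c1 <- design$criteria[design$criteria$id == "C1", ]
  expect_equal(c(c1$weight_a, c1$weight_b, c1$weight_c), c(0, 0, 0.25))
})

test_that("generation is a pure, seeded function with the contracted cell ranges", {
  design <- uti_study_design()
  m1 <- simulate_decision_matrix(seed = 5)
  m2 <- simulate_decision_matrix(seed = 5)
  expect_identical(m1, m2)
  m3 <- simulate_decision_matrix(seed = 6)
  expect_false(identical(m1, m3))
  # complete and finite
  vals <- as.matrix(m1[, -1])
  expect_true(all(is.finite(vals)))
  # class-specific ranges
  crit <- design$criteria
  for (cid in crit$id[crit$class == "percentage"]) {
    expect_true(all(m1[[cid]] >= 50 & m1[[cid]] <= 100), info = cid)
  }
  for (cid in crit$id[crit$class == "binary"]) {
    expect_true(all(m1[[cid]] %in% c(0, 1)), info = cid)
  }
  for (cid in crit$id[crit$class %in% c("cost_like", "time_like")]) {
    expect_true(all(m1[[cid]] > 0), info = cid)
  }
  for (cid in crit$id[crit$class == "linguistic5"]) {
    expect_true(all(m1[[cid]] %in% defuzzify(uti_linguistic_scale())$crisp), info = cid)
  }
})

test_that("the generator leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(simulate_decision_matrix(seed = 999))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("invalid generator configs are rejected", {
  crit <- define_criteria(id = "x", direction = "maximize", weight = 1,
                          class = "gamma_ray")
  expect_error(simulate_decision_matrix(crit, c("a", "b"), seed = 1), "gamma_ray")
  expect_error(simulate_decision_matrix(alternatives = "only-one", seed = 1),
               "two alternatives")
  expect_error(simulate_decision_matrix(seed = 1, noise = 0), "positive")
})

test_that("linguistic columns can be emitted as labels and resolve back to the same values", {
  design <- uti_study_design()
  lab <- simulate_decision_matrix(seed = 12, as_labels = TRUE)
  crisp <- simulate_decision_matrix(seed = 12)
  ling <- design$criteria$id[design$criteria$class == "linguistic5"]
  expect_true(all(vapply(ling, function(cid) is.character(lab[[cid]]), logical(1))))
  resolved <- resolve_matrix(lab, design$criteria)
  expect_equal(resolved, resolve_matrix(crisp, design$criteria), tolerance = 1e-12)
})

test_that("a planted weakly dominant alternative takes the unique top rank", {
  design <- uti_study_design()
  for (seed in 1:10) {
    m <- simulate_decision_matrix(seed = seed)
    target <- design$alternatives[(seed %% 16) + 1]
    planted <- plant_dominant_alternative(m, design$criteria, target)
    r <- promethee(planted, design$criteria)$ranking
    expect_equal(r$alternative[1], target)
    expect_equal(r$rank[2], 2L) # unique: no tie at the top
  }
})

test_that("planting respects the zero-sum with two alternatives and refuses double planting", {
  crit <- define_criteria(id = c("x", "y"), direction = "maximize", weight = c(1, 2))
  m <- tibble::tibble(alternative = c("a", "b"), x = c(1, 2), y = c(5, 3))
  planted <- plant_dominant_alternative(m, crit, "a")
  fl <- promethee(planted, crit)$flows
  expect_lte(fl$phi_net[fl$alternative == "b"], 0)
  expect_error(plant_dominant_alternative(planted, crit, "b"),
               "already contains a weakly dominant")
  expect_error(plant_dominant_alternative(m, crit, "zzz"), "not found")
})
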