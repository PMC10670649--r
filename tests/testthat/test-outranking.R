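# The PROMETHEE core: preference indices, flows, partial and complete
# rankings, and the unicriterion decomposition.

toy_matrix <- function(vals, ids) {
  dplyr::bind_cols(
    tibble::tibble(alternative = paste0("A", seq_len(nrow(vals)))),
    tibble::as_tibble(as.data.frame(vals) |> stats::setNames(ids))
  )
}

test_that("preference indices match the naive triple-loop oracle", {
  # hand-sized 3 x 2 problem first
  prob <- random_problem(3, 2, seed = 101)
  pi <- preference_indices(prob$data, prob$criteria)
  expect_equal(unname(pi), oracle_pi(prob$vals, prob$directions, prob$w),
               tolerance = 1e-12)
  # a few random 6 x 4 problems (the acceptance suite runs 100)
  for (seed in 1:10) {
    prob <- random_problem(6, 4, seed = seed)
    pi <- preference_indices(prob$data, prob$criteria)
    expect_equal(unname(pi), oracle_pi(prob$vals, prob$directions, prob$w),
                 tolerance = 1e-12)
    expect_true(all(diag(pi) == 0))
    expect_true(all(pi >= 0 & pi <= 1))
  }
})

test_that("identical evaluation rows give a zero preference index", {
  crit <- define_criteria(id = c("x", "y"), direction = "maximize", weight = c(1, 1))
  m <- toy_matrix(matrix(c(1, 1, 2, 2), 2, 2), crit$id)
  expect_true(all(preference_indices(m, crit) == 0))
})

test_that("full dominance under usual-function specs gives index one", {
  crit <- define_criteria(id = c("x", "y"), direction = "maximize",
                          weight = c(1, 3), pf = "usual")
  m <- toy_matrix(matrix(c(10, 0, 10, 0), 2, 2), crit$id)
  pi <- preference_indices(m, crit)
  expect_equal(pi["A1", "A2"], 1)
  expect_equal(pi["A2", "A1"], 0)
})

test_that("outranking flows are diagonal-excluded row and column means", {
  # n = 2: single term, divisor one
  pi2 <- matrix(c(0, 0.7, 0.2, 0), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("a", "b")))
  fl <- outranking_flows(pi2)
  expect_equal(fl$phi_plus, c(0.7, 0.2))
  expect_equal(fl$phi_minus, c(0.2, 0.7))
  # constant off-diagonal entries -> constant flows
  pic <- matrix(0.3, 4, 4); diag(pic) <- 0
  flc <- outranking_flows(pic)
  expect_equal(flc$phi_plus, rep(0.3, 4))
  expect_equal(flc$phi_minus, rep(0.3, 4))
  # random 4 x 4 vs the double-loop oracle; symmetric pi -> phi+ = phi-
  set.seed(5)
  pir <- matrix(stats::runif(16), 4, 4); diag(pir) <- 0
  flr <- outranking_flows(pir)
  orc <- oracle_flows(pir)
  expect_equal(flr$phi_plus, orc$plus, tolerance = 1e-12)
  expect_equal(flr$phi_minus, orc$minus, tolerance = 1e-12)
  psym <- (pir + t(pir)) / 2; diag(psym) <- 0
  fsym <- outranking_flows(psym)
  expect_equal(fsym$phi_plus, fsym$phi_minus, tolerance = 1e-12)
  expect_error(outranking_flows(matrix(0, 1, 1)), "two alternatives")
})

test_that("net flow is the difference of leaving and entering flows", {
  expect_equal(net_flow(0.0064, 0.0001), 0.0063)
  expect_equal(net_flow(0.0029, 0.0077), -0.0048)
  expect_equal(net_flow(0.42, 0.42), 0)
})

test_that("the partial order classifies preference, indifference and incomparability", {
  fl <- tibble::tibble(
    alternative = c("a", "b"),
    phi_plus = c(0.5, 0.3), phi_minus = c(0.1, 0.2)
  )
  rel <- promethee1(fl)
  expect_equal(rel["a", "b"], "P")
  expect_equal(rel["b", "a"], "P-")
  # identical flow pairs -> indifference
  fl$phi_plus <- c(0.4, 0.4); fl$phi_minus <- c(0.2, 0.2)
  expect_equal(promethee1(fl)["a", "b"], "I")
  # crossed dominance (higher strength and higher weakness) -> incomparable
  fl$phi_plus <- c(0.5, 0.3); fl$phi_minus <- c(0.4, 0.1)
  rel <- promethee1(fl)
  expect_equal(rel["a", "b"], "R")
  expect_equal(rel["b", "a"], "R")
})

test_that("the partial order partitions all ordered pairs with the right symmetries", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    fl <- tibble::tibble(alternative = paste0("A", 1:n),
                         phi_plus = stats::runif(n), phi_minus = stats::runif(n))
    rel <- promethee1(fl)
    expect_true(all(diag(rel) == "self"))
    off <- rel[row(rel) != col(rel)]
    expect_true(all(off %in% c("P", "P-", "I", "R")))
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      expect_equal(rel[j, i], switch(rel[i, j], P = "P-", `P-` = "P",
                                     I = "I", R = "R"))
    }
  }
})

test_that("the complete ranking sorts by net flow with competition ranks for ties", {
  set.seed(9)
  fl <- tibble::tibble(alternative = paste0("A", 1:5),
                       phi_plus = stats::runif(5), phi_minus = stats::runif(5))
  fl$phi_net <- fl$phi_plus - fl$phi_minus
  r <- promethee2(fl)
  expect_equal(r$alternative, fl$alternative[order(-fl$phi_net)]) # brute-force sort oracle
  expect_equal(r$rank, 1:5)
  # ties share a rank: 1, 2, 2, 4
  flt <- tibble::tibble(alternative = c("a", "b", "c", "d"),
                        phi_plus = c(0.9, 0.5, 0.5, 0.1),
                        phi_minus = 0, phi_net = c(0.9, 0.5, 0.5, 0.1))
  expect_equal(promethee2(flt)$rank, c(1L, 2L, 2L, 4L))
})

test_that("ranking the published flow columns reproduces the published order", {
  for (which in c("main", "sensitivity")) {
    pub <- uti_reported_flows(which)
    r <- promethee2(pub)
    expect_equal(r$alternative, pub$alternative)
    if (which == "main") {
      # ranks 7 and 8 are printed with identical flows: a genuine tie
      expect_equal(r$rank, c(1:7, 7L, 9:16))
    } else {
      expect_equal(r$rank, 1:16)
    }
  }
})

test_that("unicriterion flows decompose the net flow exactly", {
  # single criterion with unit weight: the profile IS the net flow
  crit1 <- define_criteria(id = "x", direction = "maximize", weight = 1)
  m1 <- toy_matrix(matrix(c(3, 1, 2, 5), 4, 1), "x")
  fit1 <- promethee(m1, crit1)
  prof1 <- fit1$profile
  expect_equal(prof1$phi, fit1$flows$phi_net, tolerance = 1e-12)
  # weighted sum over criteria reproduces phi_net on a random 6 x 4 problem
  prob <- random_problem(6, 4, seed = 77)
  fit <- promethee(prob$data, prob$criteria)
  recomposed <- fit$profile |>
    dplyr::summarise(phi_net = sum(contribution), .by = alternative)
  expect_equal(recomposed$phi_net,
               fit$flows$phi_net[match(recomposed$alternative, fit$flows$alternative)],
               tolerance = 1e-12)
  # an alternative worst on a criterion in every pairwise comparison has phi_k <= 0
  worst <- which.min(prob$vals[, 1])
  dir1 <- prob$directions[1]
  if (dir1 == "minimize") worst <- which.max(prob$vals[, 1])
  phi_w <- fit$profile$phi[fit$profile$criterion == "k1" &
                             fit$profile$alternative == paste0("A", worst)]
  expect_lte(phi_w, 0)
})

test_that("net flows sum to zero and dominance puts an alternative on top", {
  for (seed in c(2, 3)) {
    prob <- random_problem(7, 3, seed = seed)
    fit <- promethee(prob$data, prob$criteria)
    expect_lt(abs(sum(fit$flows$phi_net)), 1e-10)
  }
  # single-criterion ranking equals sorting by value in the preferred direction
  crit <- define_criteria(id = "cost", direction = "minimize", weight = 1)
  m <- toy_matrix(matrix(c(30, 10, 20, 50), 4, 1), "cost")
  fit <- promethee(m, crit)
  expect_equal(fit$ranking$alternative, paste0("A", order(m$cost)))
})

test_that("zero-weight criteria do not influence the outcome", {
  prob <- random_problem(6, 3, seed = 13)
  crit <- prob$criteria
  extra <- define_criteria(id = "dead", direction = "maximize", weight = 0)
  crit_aug <- dplyr::bind_rows(crit, extra)
  class(crit_aug) <- class(crit)
  set.seed(99)
  data_aug <- dplyr::mutate(prob$data, dead = stats::rnorm(6))
  fit0 <- promethee(prob$data, crit)
  fit1 <- promethee(data_aug, crit_aug)
  expect_equal(fit1$flows$phi_net, fit0$flows$phi_net, tolerance = 1e-12)
  expect_equal(fit1$ranking$alternative, fit0$ranking$alternative)
})

test_that("tidy, glance and plots expose the fit", {
  prob <- random_problem(5, 3, seed = 31)
  fit <- promethee(prob$data, prob$criteria)
  td <- tidy(fit)
  expect_named(td, c("rank", "alternative", "phi_net", "phi_plus", "phi_minus"))
  gl <- glance(fit)
  expect_equal(gl$n_alternatives, 5)
  expect_equal(gl$n_criteria, 3)
  expect_lt(abs(gl$net_flow_sum), 1e-10)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(plot_profile(fit), "ggplot")
})
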