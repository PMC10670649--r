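# Independent brute-force oracles, written directly from the method's
# definitions (no calls into the package's pipeline), plus small random
# problem generators used across the suite.

# Population sd without stats::sd (which uses divisor n - 1).
oracle_pop_sd <- function(x) sqrt(sum((x - mean(x))^2) / length(x))

# Gaussian preference evaluated pointwise.
oracle_gauss <- function(d, s) {
  if (d <= 0 || s == 0) 0 else 1 - exp(-d^2 / (2 * s^2))
}

# Naive triple loop: pairs x criteria -> preference-index matrix.
# vals: n x K numeric; directions: "maximize"/"minimize"; w: raw weights.
oracle_pi <- function(vals, directions, w) {
  n <- nrow(vals); K <- ncol(vals)
  w <- w / sum(w)
  s <- vapply(seq_len(K), function(k) oracle_pop_sd(vals[, k]), double(1))
  pi <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      acc <- 0
      for (k in seq_len(K)) {
        d <- vals[a, k] - vals[b, k]
        if (directions[k] == "minimize") d <- -d
        acc <- acc + w[k] * oracle_gauss(d, s[k])
      }
      pi[a, b] <- acc
    }
  }
  pi
}

# Flows by explicit row/column sums excluding the diagonal.
oracle_flows <- function(pi) {
  n <- nrow(pi)
  plus <- minus <- numeric(n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      plus[a] <- plus[a] + pi[a, b]
      minus[a] <- minus[a] + pi[b, a]
    }
  }
  list(plus = plus / (n - 1), minus = minus / (n - 1))
}

# Kendall tau by concordant/discordant pair counting (no ties expected).
oracle_kendall <- function(r1, r2) {
  n <- length(r1)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(r1[i] - r1[j]) * sign(r2[i] - r2[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  (conc - disc) / (n * (n - 1) / 2)
}

# Random gaussian-preference test problem: n x K values in a data frame
# plus a matching criteria table with random directions and weights.
random_problem <- function(n, K, seed) {
  set.seed(seed)
  directions <- sample(c("maximize", "minimize"), K, replace = TRUE)
  w <- stats::runif(K, 0.1, 1)
  vals <- matrix(stats::rnorm(n * K, mean = 10, sd = 3), n, K)
  crit <- define_criteria(id = paste0("k", seq_len(K)), direction = directions,
                          weight = w)
  data <- dplyr::bind_cols(
    tibble::tibble(alternative = paste0("A", seq_len(n))),
    tibble::as_tibble(as.data.frame(vals) |> stats::setNames(crit$id))
  )
  list(data = data, criteria = crit, vals = vals, directions = directions, w = w)
}
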