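#' Direction-signed pairwise difference
#'
#' The raw ingredient of every pairwise comparison: how much better
#' alternative A is than alternative B on one criterion. For maximized
#' criteria this is `va - vb`; for minimized criteria (cost, turnaround
#' time) the sign flips so that a lower value still counts in A's favour.
#'
#' @param va,vb Criterion values of the two alternatives (vectorised).
#' @param direction `"maximize"` or `"minimize"`.
#' @return Numeric difference(s) `d`; positive means A preferred.
#' @examples
#' signed_difference(0.9, 0.7, "maximize") #  0.2
#' signed_difference(10, 30, "minimize")   # 20
#' @export
signed_difference <- function(va, vb, direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  if (direction == "maximize") va - vb else vb - va
}

#' Spread of a criterion column
#'
#' The Gaussian preference function scales differences by the standard
#' deviation of the criterion's values across all alternatives. The
#' population form (divisor `n`) is the default; the sample form
#' (divisor `n - 1`) is available as an option.
#'
#' @param values Numeric vector (one criterion column).
#' @param type `"population"` (default) or `"sample"`.
#' @return Non-negative scalar; 0 for constant columns (and for a single
#'   value under `"sample"`).
#' @examples
#' criterion_sd(c(2, 4, 4, 4, 5, 5, 7, 9)) # 2
#' @export
criterion_sd <- function(values, type = c("population", "sample")) {
  type <- match.arg(type)
  if (length(values) == 0) rlang::abort("Cannot compute the spread of an empty column.")
  if (anyNA(values) || any(!is.finite(values))) rlang::abort("Criterion values must be finite.")
  n <- length(values)
  if (n == 1) return(0)
  v <- sum((values - mean(values))^2)
  sqrt(v / if (type == "population") n else n - 1)
}

#' Gaussian preference function
#'
#' Maps a pairwise difference `d` on one criterion to a preference degree:
#' 0 for `d <= 0`, otherwise `1 - exp(-d^2 / (2 s^2))`. The smooth ramp
#' keeps tiny differences from producing outsized preferences; `s` sets
#' the difference scale at which preference becomes substantial. A zero
#' spread (a criterion on which all alternatives agree) yields zero
#' preference everywhere: such a criterion cannot discriminate.
#'
#' @param d Numeric difference(s), positive when the first alternative is
#'   better.
#' @param s Non-negative spread, in the criterion's units.
#' @return Preference degree(s) in `[0, 1)`.
#' @examples
#' gaussian_preference(1, 1)    # 1 - exp(-1/2) = 0.3935
#' gaussian_preference(-0.3, 1) # 0
#' @export
gaussian_preference <- function(d, s) {
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || s < 0) {
    rlang::abort("`s` must be a single non-negative number.")
  }
  out <- numeric(length(d))
  if (s > 0) {
    pos <- d > 0
    out[pos] <- 1 - exp(-d[pos]^2 / (2 * s^2))
  }
  out
}

#' Preference degree under any supported function family
#'
#' The standard catalogue of preference functions: `"usual"` (a step at
#' zero), `"u_shape"` (step at the indifference threshold `q`),
#' `"v_shape"` (linear ramp up to the preference threshold `p`),
#' `"level"` (0 / 0.5 / 1 with thresholds `q` and `p`), `"linear"` (ramp
#' from `q` to `p`) and `"gaussian"` (see [gaussian_preference()]). All
#' families return 0 for `d <= 0` and are nondecreasing in `d`, bounded
#' by 1.
#'
#' @param d Numeric difference(s).
#' @param family One of the six family names.
#' @param q,p,s Thresholds required by the family; `linear` with missing
#'   `q` uses `q = 0` (ramp `d / p`).
#' @return Preference degree(s) in `[0, 1]`.
#' @examples
#' preference_degree(0.1, "usual")           # 1
#' preference_degree(1, "linear", p = 2)     # 0.5
#' preference_degree(1, "gaussian", s = 1)   # 0.3935
#' @export
preference_degree <- function(d, family = pf_families(), q = NA_real_,
                              p = NA_real_, s = NA_real_) {
  family <- match.arg(family)
  need <- function(x, nm) {
    if (is.na(x)) {
      rlang::abort(sprintf("Preference family '%s' requires threshold `%s`.", family, nm))
    }
    x
  }
  out <- numeric(length(d))
  pos <- d > 0
  if (!any(pos)) return(out)
  dp <- d[pos]
  out[pos] <- switch(
    family,
    usual = rep(1, length(dp)),
    u_shape = as.numeric(dp > need(q, "q")),
    v_shape = {
      p <- need(p, "p")
      if (p <= 0) rlang::abort("v_shape requires p > 0.")
      pmin(dp / p, 1)
    },
    level = {
      q <- need(q, "q"); p <- need(p, "p")
      ifelse(dp <= q, 0, ifelse(dp <= p, 0.5, 1))
    },
    linear = {
      p <- need(p, "p")
      if (is.na(q)) q <- 0
      if (p <= q) rlang::abort("linear requires q < p.")
      pmin(pmax((dp - q) / (p - q), 0), 1)
    },
    gaussian = gaussian_preference(dp, need(s, "s"))
  )
  out
}
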