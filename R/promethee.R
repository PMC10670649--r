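#' Resolve a raw decision matrix to crisp values
#'
#' Takes a data frame whose first column labels the alternatives and whose
#' remaining columns are the criteria (matched to `criteria$id`), parses
#' numeric cells and defuzzifies linguistic cells through the scale, and
#' returns an all-numeric tibble. Cell problems are reported with their
#' row and column coordinates.
#'
#' @param data Data frame: first column alternative labels, then one
#'   column per criterion (numeric or linguistic labels).
#' @param criteria A [define_criteria()] tibble.
#' @param scale `linguistic_scale` for linguistic cells.
#' @return Tibble with column `alternative` plus one numeric column per
#'   criterion, in `criteria$id` order.
#' @export
resolve_matrix <- function(data, criteria, scale = uti_linguistic_scale()) {
  stopifnot(is.data.frame(data), inherits(criteria, "criteria"))
  if (ncol(data) < 2) rlang::abort("A decision matrix needs a label column plus at least one criterion.")
  if (nrow(data) < 2) rlang::abort("A decision matrix needs at least two alternatives.")
  alternative <- as.character(data[[1]])
  if (anyDuplicated(alternative)) rlang::abort("Alternative labels must be unique.")
  missing_cols <- setdiff(criteria$id, names(data)[-1])
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Decision matrix is missing criterion column(s): %s.",
                         paste(missing_cols, collapse = ", ")))
  }
  cols <- purrr::map(criteria$id, function(cid) {
    col <- data[[cid]]
    if (is.numeric(col)) {
      vals <- as.double(col)
    } else {
      raw <- trimws(as.character(col))
      vals <- suppressWarnings(as.double(raw))
      lab <- is.na(vals) & !is.na(raw) & raw != ""
      for (i in which(lab)) {
        vals[i] <- tryCatch(defuzzify(resolve_term(raw[i], scale)), error = function(e) {
          rlang::abort(sprintf("Cannot parse cell at row '%s', column '%s': %s",
                               alternative[i], cid, conditionMessage(e)))
        })
      }
    }
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad) > 0) {
      rlang::abort(sprintf("Missing or non-finite cell at row '%s', column '%s'.",
                           alternative[bad[1]], cid))
    }
    vals
  })
  names(cols) <- criteria$id
  dplyr::bind_cols(tibble::tibble(alternative = alternative), tibble::as_tibble(cols))
}

# Crisp values + criteria -> list of per-criterion n x n preference-degree
# matrices, the criteria table with effective spreads, and normalized weights.
prepare_preferences <- function(crisp, criteria, normalize = TRUE,
                                sd_type = "population") {
  vals <- as.matrix(crisp[, criteria$id, drop = FALSE])
  n <- nrow(vals)
  w <- criteria$weight
  if (normalize) {
    w <- normalize_weights(w)
  } else if (any(w < 0)) {
    rlang::abort("Criterion weights must be non-negative.")
  }
  s_eff <- purrr::map_dbl(seq_len(nrow(criteria)), function(k) {
    if (!is.na(criteria$s[k])) criteria$s[k] else criterion_sd(vals[, k], type = sd_type)
  })
  P <- purrr::map(seq_len(nrow(criteria)), function(k) {
    v <- vals[, k]
    d <- outer(v, v, "-")
    if (criteria$direction[k] == "minimize") d <- -d
    m <- matrix(
      preference_degree(as.vector(d), family = criteria$pf[k],
                        q = criteria$q[k], p = criteria$p[k], s = s_eff[k]),
      nrow = n, dimnames = list(crisp$alternative, crisp$alternative)
    )
    diag(m) <- 0
    m
  })
  list(P = P, w = w, s = s_eff, alternatives = crisp$alternative)
}

#' Aggregate pairwise preference indices
#'
#' For each ordered pair of alternatives, the preference index is the
#' weighted sum over criteria of the per-criterion preference degrees,
#' `pi(A, B) = sum_k w_k P_k(d_k(A, B))`. With weights normalized to sum
#' one it lies in `[0, 1]`; the diagonal is 0.
#'
#' @inheritParams resolve_matrix
#' @param normalize Normalize weights to sum 1 (default). Disabling it is
#'   only meaningful for experimentation and requires the caller to
#'   interpret the index scale.
#' @param sd_type Spread estimator for Gaussian criteria without an
#'   explicit `s`: `"population"` (default) or `"sample"`.
#' @return An `n x n` numeric matrix with alternative labels as dimnames.
#' @export
preference_indices <- function(data, criteria, scale = uti_linguistic_scale(),
                               normalize = TRUE, sd_type = "population") {
  crisp <- resolve_matrix(data, criteria, scale)
  prep <- prepare_preferences(crisp, criteria, normalize, sd_type)
  pi_from_prep(prep)
}

pi_from_prep <- function(prep) {
  Reduce(`+`, purrr::map2(prep$w, prep$P, `*`))
}

#' Outranking flows from a preference-index matrix
#'
#' The leaving flow `phi_plus` of an alternative averages its preference
#' indices over the other `n - 1` alternatives (its strength); the
#' entering flow `phi_minus` averages the indices of the others over it
#' (its weakness); the net flow is their difference and sums to zero over
#' all alternatives.
#'
#' @param pi Square preference-index matrix (zero diagonal), with
#'   alternative labels as dimnames.
#' @return Tibble with columns `alternative`, `phi_plus`, `phi_minus`,
#'   `phi_net`.
#' @export
outranking_flows <- function(pi) {
  stopifnot(is.matrix(pi), nrow(pi) == ncol(pi))
  n <- nrow(pi)
  if (n < 2) rlang::abort("Outranking flows need at least two alternatives.")
  labs <- rownames(pi) %||% paste0("A", seq_len(n))
  plus <- rowSums(pi) / (n - 1)
  minus <- colSums(pi) / (n - 1)
  tibble::tibble(
    alternative = labs,
    phi_plus = unname(plus),
    phi_minus = unname(minus),
    phi_net = unname(plus - minus)
  )
}

#' Net outranking flow
#'
#' @param phi_plus,phi_minus Leaving and entering flows (vectorised).
#' @return `phi_plus - phi_minus`.
#' @examples
#' net_flow(0.0064, 0.0001) # 0.0063
#' @export
net_flow <- function(phi_plus, phi_minus) {
  stopifnot(is.numeric(phi_plus), is.numeric(phi_minus))
  phi_plus - phi_minus
}

#' Partial order of alternatives (PROMETHEE I)
#'
#' Classifies every ordered pair from the two flows: `P` (preferred:
#' higher leaving flow with entering flow not higher, or equal leaving
#' and lower entering), `I` (indifferent: both flows equal), `R`
#' (incomparable: one alternative higher on both flows — strength and
#' weakness both larger, so the flows disagree). Flow equality is judged
#' with an absolute tolerance `epsilon`.
#'
#' @param flows Flow tibble from [outranking_flows()].
#' @param epsilon Non-negative absolute tolerance for flow equality.
#' @return Character matrix with entries `"P"`, `"P-"`, `"I"`, `"R"` and
#'   `"self"` on the diagonal.
#' @export
promethee1 <- function(flows, epsilon = 1e-9) {
  stopifnot(is.data.frame(flows), epsilon >= 0)
  n <- nrow(flows)
  cmp <- function(x, y) {
    # -1 / 0 / +1 with epsilon-equality
    ifelse(abs(x - y) <= epsilon, 0L, ifelse(x > y, 1L, -1L))
  }
  rel <- matrix("R", n, n, dimnames = list(flows$alternative, flows$alternative))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { rel[i, j] <- "self"; next }
      cp <- cmp(flows$phi_plus[i], flows$phi_plus[j])
      cm <- cmp(flows$phi_minus[i], flows$phi_minus[j])
      rel[i, j] <- if (cp == 0 && cm == 0) "I"
      else if ((cp == 1 && cm <= 0) || (cp == 0 && cm == -1)) "P"
      else if ((cp == -1 && cm >= 0) || (cp == 0 && cm == 1)) "P-"
      else "R"
    }
  }
  rel
}

#' Complete ranking of alternatives (PROMETHEE II)
#'
#' Sorts alternatives by descending net flow. Net flows within `epsilon`
#' of each other are treated as tied and share a rank (competition
#' ranking: 1, 2, 2, 4).
#'
#' @inheritParams promethee1
#' @return Tibble with columns `rank`, `alternative`, `phi_net`,
#'   `phi_plus`, `phi_minus`, sorted by `phi_net` descending.
#' @export
promethee2 <- function(flows, epsilon = 1e-9) {
  stopifnot(is.data.frame(flows), epsilon >= 0)
  out <- dplyr::arrange(flows, dplyr::desc(.data$phi_net))
  # chain ties: a new rank group starts where the gap to the previous
  # (sorted) net flow exceeds epsilon
  gap <- c(TRUE, diff(out$phi_net) < -epsilon)
  group_start <- which(gap)
  grp <- cumsum(gap)
  out$rank <- group_start[grp]
  dplyr::select(out, "rank", "alternative", "phi_net", "phi_plus", "phi_minus")
}

#' Per-criterion net flow decomposition
#'
#' The unicriterion net flow `phi_k(A)` averages, over the other
#' alternatives, the difference between A's preference degree and the
#' opposing degree on criterion `k` alone. It localises strengths
#' (positive) and weaknesses (negative): the weighted sum over criteria
#' reproduces the overall net flow exactly.
#'
#' @inheritParams preference_indices
#' @return Long tibble with columns `alternative`, `criterion`, `phi`
#'   (unweighted unicriterion net flow) and `contribution`
#'   (`weight * phi`, summing to `phi_net` per alternative).
#' @export
unicriterion_flows <- function(data, criteria, scale = uti_linguistic_scale(),
                               normalize = TRUE, sd_type = "population") {
  crisp <- resolve_matrix(data, criteria, scale)
  prep <- prepare_preferences(crisp, criteria, normalize, sd_type)
  unicriterion_from_prep(prep, criteria)
}

unicriterion_from_prep <- function(prep, criteria) {
  n <- length(prep$alternatives)
  purrr::map2_dfr(seq_along(prep$P), criteria$id, function(k, cid) {
    Pk <- prep$P[[k]]
    phi <- (rowSums(Pk) - colSums(Pk)) / (n - 1)
    tibble::tibble(
      alternative = prep$alternatives,
      criterion = cid,
      phi = unname(phi),
      contribution = unname(prep$w[k] * phi)
    )
  })
}

#' Run a full fuzzy-PROMETHEE analysis
#'
#' The end-to-end pipeline: defuzzify linguistic cells and weights,
#' normalize the weights, estimate per-criterion spreads, build the
#' pairwise preference indices, compute leaving/entering/net flows, the
#' partial (PROMETHEE I) and complete (PROMETHEE II) rankings, and the
#' per-criterion flow profile.
#'
#' @inheritParams preference_indices
#' @param epsilon Absolute tolerance for flow equality in the rankings.
#' @return An object of class `"promethee"`: a list with elements
#'   `crisp` (resolved matrix), `criteria` (with effective spread
#'   `s_effective` and `weight_normalized`), `pi`, `flows`,
#'   `partial_order`, `ranking`, `profile`, `epsilon`.
#' @examples
#' design <- uti_study_design()
#' m <- simulate_decision_matrix(seed = 1)
#' fit <- promethee(m, design$criteria)
#' tidy(fit)
#' @export
promethee <- function(data, criteria, epsilon = 1e-9,
                      scale = uti_linguistic_scale(), normalize = TRUE,
                      sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  crisp <- resolve_matrix(data, criteria, scale)
  prep <- prepare_preferences(crisp, criteria, normalize, sd_type)
  pi <- pi_from_prep(prep)
  flows <- outranking_flows(pi)
  criteria_out <- dplyr::mutate(criteria,
                                weight_normalized = prep$w,
                                s_effective = prep$s)
  structure(
    list(
      crisp = crisp,
      criteria = criteria_out,
      pi = pi,
      flows = flows,
      partial_order = promethee1(flows, epsilon),
      ranking = promethee2(flows, epsilon),
      profile = unicriterion_from_prep(prep, criteria),
      epsilon = epsilon
    ),
    class = "promethee"
  )
}

#' @export
print.promethee <- function(x, ...) {
  cat(sprintf("Fuzzy-PROMETHEE analysis: %d alternatives x %d criteria\n",
              nrow(x$crisp), nrow(x$criteria)))
  cat("Complete ranking (net flow, 4 decimals):\n")
  r <- x$ranking
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %2d  %-45s %8.4f\n", r$rank[i], r$alternative[i], r$phi_net[i]))
  }
  invisible(x)
}

#' Tidy a fuzzy-PROMETHEE fit
#'
#' @param x A `promethee` object.
#' @param ... Unused.
#' @return The complete-ranking tibble (`rank`, `alternative`, `phi_net`,
#'   `phi_plus`, `phi_minus`).
#' @exportS3Method generics::tidy
tidy.promethee <- function(x, ...) x$ranking

#' One-row summary of a fuzzy-PROMETHEE fit
#'
#' @param x A `promethee` object.
#' @param ... Unused.
#' @return Tibble with the problem size, the flow zero-sum residual, and
#'   the number of incomparable pairs in the partial order.
#' @exportS3Method generics::glance
glance.promethee <- function(x, ...) {
  tibble::tibble(
    n_alternatives = nrow(x$crisp),
    n_criteria = nrow(x$criteria),
    epsilon = x$epsilon,
    net_flow_sum = sum(x$flows$phi_net),
    n_incomparable_pairs = sum(x$partial_order == "R") / 2
  )
}

#' Plot net flows of a fuzzy-PROMETHEE fit
#'
#' Bar chart of the net flow of each alternative, best first.
#'
#' @param object A `promethee` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.promethee <- function(object, ...) {
  r <- object$ranking
  r$alternative <- factor(r$alternative, levels = rev(r$alternative))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$phi_net, y = .data$alternative)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = expression(Phi[net]), y = NULL,
                  title = "PROMETHEE II complete ranking") +
    ggplot2::theme_minimal()
}

#' Per-criterion strength/weakness profile plot
#'
#' Stacked weighted unicriterion flow contributions per alternative,
#' ordered by rank: bars above zero are strengths on those criteria,
#' bars below zero weaknesses. The signed bar total equals the net flow.
#'
#' @param x A `promethee` object.
#' @return A ggplot object.
#' @export
plot_profile <- function(x) {
  stopifnot(inherits(x, "promethee"))
  prof <- dplyr::left_join(x$profile,
                           dplyr::select(x$ranking, "alternative", "rank"),
                           by = "alternative")
  prof$alternative <- stats::reorder(prof$alternative, prof$rank)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$alternative,
                                     y = .data$contribution,
                                     fill = .data$criterion)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "weighted unicriterion net flow",
                  title = "Strength/weakness profile by criterion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
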