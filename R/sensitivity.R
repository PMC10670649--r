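#' Drop criteria from a decision problem
#'
#' Removes the named criterion columns from the matrix and the matching
#' rows from the criteria table. Downstream analysis renormalizes the
#' surviving weights to sum one and re-estimates per-column spreads, so
#' an omission is exactly equivalent to building the reduced problem from
#' scratch.
#'
#' @inheritParams promethee
#' @param ids Character vector of criterion ids to omit (may be empty).
#' @return List with elements `data` (matrix without those columns) and
#'   `criteria` (without those rows).
#' @export
omit_criteria <- function(data, criteria, ids) {
  stopifnot(is.data.frame(data), inherits(criteria, "criteria"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, criteria$id)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown criterion id(s): %s.", paste(unknown, collapse = ", ")))
  }
  keep <- setdiff(criteria$id, ids)
  if (length(keep) == 0) rlang::abort("Cannot omit every criterion; at least one must remain.")
  list(
    data = data[, c(names(data)[1], intersect(names(data)[-1], keep)), drop = FALSE],
    criteria = criteria[criteria$id %in% keep, , drop = FALSE]
  )
}

#' Compare two complete rankings
#'
#' Quantifies how much a perturbed ranking departs from a baseline over
#' the same alternatives: the Kendall rank correlation of the two rank
#' orders (1 for identical orders, -1 for a full reversal) plus the
#' per-alternative signed rank displacement.
#'
#' @param base,perturbed Ranking tibbles from [promethee2()] (or
#'   `promethee` objects, whose rankings are used).
#' @return List with elements `tau` (Kendall correlation) and
#'   `displacement`: a tibble `alternative`, `rank_base`,
#'   `rank_perturbed`, `displacement` (`rank_base - rank_perturbed`;
#'   positive = moved up).
#' @export
compare_rankings <- function(base, perturbed) {
  as_rank <- function(x) if (inherits(x, "promethee")) x$ranking else x
  base <- as_rank(base); perturbed <- as_rank(perturbed)
  if (!setequal(base$alternative, perturbed$alternative)) {
    rlang::abort("Rankings compare different alternative sets.")
  }
  tbl <- dplyr::inner_join(
    dplyr::select(base, "alternative", rank_base = "rank"),
    dplyr::select(perturbed, "alternative", rank_perturbed = "rank"),
    by = "alternative"
  )
  tbl <- dplyr::mutate(tbl, displacement = .data$rank_base - .data$rank_perturbed)
  tau <- unname(stats::cor(tbl$rank_base, tbl$rank_perturbed, method = "kendall"))
  list(tau = tau, displacement = tbl)
}

#' Criterion-omission sensitivity analysis
#'
#' Re-runs the full outranking analysis with the given criteria omitted
#' (weights renormalized, spreads re-estimated) and reports how the
#' complete ranking responds: Kendall tau against the baseline and the
#' per-alternative rank displacement. Omitting nothing returns tau = 1.
#'
#' @inheritParams promethee
#' @param drop Character vector of criterion ids to omit.
#' @return An object of class `"promethee_sensitivity"`: list with
#'   `baseline` and `perturbed` (`promethee` fits), `dropped`, `tau`,
#'   `displacement`.
#' @examples
#' design <- uti_study_design()
#' m <- simulate_decision_matrix(seed = 1)
#' sens <- sensitivity_analysis(m, design$criteria, drop = c("C1", "C2"))
#' sens$tau
#' @export
sensitivity_analysis <- function(data, criteria, drop = character(),
                                 epsilon = 1e-9,
                                 scale = uti_linguistic_scale(),
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  baseline <- promethee(data, criteria, epsilon = epsilon, scale = scale,
                        sd_type = sd_type)
  reduced <- omit_criteria(data, criteria, drop)
  perturbed <- promethee(reduced$data, reduced$criteria, epsilon = epsilon,
                         scale = scale, sd_type = sd_type)
  cmp <- compare_rankings(baseline, perturbed)
  structure(
    list(baseline = baseline, perturbed = perturbed,
         dropped = as.character(drop), tau = cmp$tau,
         displacement = cmp$displacement),
    class = "promethee_sensitivity"
  )
}

#' @export
print.promethee_sensitivity <- function(x, ...) {
  cat(sprintf("Criterion-omission sensitivity: dropped {%s}\n",
              paste(x$dropped, collapse = ", ")))
  cat(sprintf("Kendall tau (baseline vs perturbed ranking): %.4f\n", x$tau))
  moved <- sum(x$displacement$displacement != 0)
  cat(sprintf("Alternatives that changed rank: %d of %d\n",
              moved, nrow(x$displacement)))
  invisible(x)
}

#' Tidy a sensitivity analysis
#'
#' @param x A `promethee_sensitivity` object.
#' @param ... Unused.
#' @return The per-alternative displacement tibble.
#' @exportS3Method generics::tidy
tidy.promethee_sensitivity <- function(x, ...) x$displacement

#' One-row summary of a sensitivity analysis
#'
#' @param x A `promethee_sensitivity` object.
#' @param ... Unused.
#' @return Tibble with the dropped ids, Kendall tau and the count of
#'   alternatives whose rank moved.
#' @exportS3Method generics::glance
glance.promethee_sensitivity <- function(x, ...) {
  tibble::tibble(
    dropped = paste(x$dropped, collapse = ","),
    tau = x$tau,
    n_rank_changes = sum(x$displacement$displacement != 0)
  )
}
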