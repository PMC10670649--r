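#' The UTI diagnostic-test study design
#'
#' The built-in replica of the published study design: 16 urinary-tract-
#' infection diagnostic techniques evaluated on 15 criteria whose weights
#' were elicited on the five-level linguistic scale — result time and
#' point-of-care capability Very High; cost, efficiency,
#' limitation/pathogen identification, sensitivity, specificity, PPV, NPV
#' and AST High; the three practicality criteria Moderate; specimen type
#' Low; specimen volume Very Low.
#'
#' The original expert decision matrix is unpublished, so the criterion
#' directions and generator classes below are the package's documented
#' assumptions, not published facts: specimen volume, cost and result
#' time are minimized; all performance criteria are maximized; the
#' percentage criteria are sensitivity/specificity/PPV/NPV; point-of-care
#' capability, direct-from-sample applicability and AST capability are
#' binary; the remaining vague criteria use the five-level linguistic
#' scale.
#'
#' @return List with elements `criteria` (a [define_criteria()] tibble,
#'   15 rows) and `alternatives` (character vector of 16 test labels).
#' @export
uti_study_design <- function() {
  criteria <- define_criteria(
    id = paste0("C", 1:15),
    name = c(
      "specimen volume", "specimen type", "cost", "efficiency",
      "result time", "point of care testing",
      "applicability/direct from sample", "practicality for patients",
      "practicality for personnel", "limitation/pathogen identification",
      "sensitivity", "specificity", "PPV", "NPV",
      "antimicrobial susceptibility testing"
    ),
    direction = c(
      "minimize", "maximize", "minimize", "maximize", "minimize",
      rep("maximize", 10)
    ),
    weight = c(
      "Very Low", "Low", "High", "High", "Very High", "Very High",
      "Moderate", "Moderate", "Moderate", "High",
      "High", "High", "High", "High", "High"
    ),
    class = c(
      "cost_like", "linguistic5", "cost_like", "linguistic5", "time_like",
      "binary", "binary", "linguistic5", "linguistic5", "linguistic5",
      "percentage", "percentage", "percentage", "percentage", "binary"
    )
  )
  alternatives <- c(
    "Nitrite", "Leucocyte esterase", "Combined leucocyte esterase and nitrite",
    "Catalase", "Microscopy", "Conventional culture", "Chromogenic agar",
    "Nucleic acid-based techniques (Multiplex PCR)", "MALDI-TOF-MS",
    "Biosensor", "Urine flow cytometry", "Microfluidics",
    "Sequence-based diagnostics", "Real-time microscopy systems", "FISH",
    "Immunologically based assay"
  )
  list(criteria = criteria, alternatives = alternatives)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Simulate a decision matrix with the study's statistical structure
#'
#' Generates expert-style evaluations per criterion class: percentage
#' criteria (sensitivity, specificity, PPV, NPV) are Beta-shaped in
#' `[50, 100]`; cost-like and time-like criteria are positive and
#' right-skewed (lognormal); five-level linguistic criteria are drawn
#' uniformly over the scale labels and defuzzified; binary criteria are
#' 0/1 capabilities. The draw is a pure function of `(criteria,
#' alternatives, seed, noise)`.
#'
#' @param criteria A [define_criteria()] tibble with a `class` column;
#'   defaults to the UTI replica design.
#' @param alternatives Alternative labels; defaults to the 16 UTI tests.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param noise Positive dispersion multiplier (1 = default spread).
#' @param as_labels If `TRUE`, linguistic criteria keep their labels
#'   (character columns) instead of the defuzzified crisp values.
#' @param scale `linguistic_scale` used for linguistic criteria.
#' @return Tibble: `alternative` plus one column per criterion.
#' @examples
#' m <- simulate_decision_matrix(seed = 42)
#' dim(m)
#' @export
simulate_decision_matrix <- function(criteria = uti_study_design()$criteria,
                                     alternatives = uti_study_design()$alternatives,
                                     seed = NULL, noise = 1,
                                     as_labels = FALSE,
                                     scale = uti_linguistic_scale()) {
  stopifnot(inherits(criteria, "criteria"))
  n <- length(alternatives)
  if (n < 2) rlang::abort("Need at least two alternatives.")
  if (anyDuplicated(alternatives)) rlang::abort("Alternative labels must be unique.")
  if (!is.numeric(noise) || noise <= 0) rlang::abort("`noise` must be positive.")
  known <- c("percentage", "cost_like", "time_like", "linguistic5", "binary")
  bad <- setdiff(stats::na.omit(unique(criteria$class)), known)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Unknown criterion class(es): %s. Valid classes: %s.",
                         paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  with_seed(seed, {
    cols <- purrr::map(seq_len(nrow(criteria)), function(k) {
      cls <- criteria$class[k]
      if (is.na(cls)) cls <- "percentage"
      switch(
        cls,
        percentage = {
          # mean 0.75 of the [0,1] range -> typical 85-90% performance
          prec <- 8 / noise
          50 + 50 * stats::rbeta(n, 0.75 * prec, 0.25 * prec)
        },
        cost_like = stats::rlnorm(n, meanlog = log(20), sdlog = 0.8 * noise),
        time_like = stats::rlnorm(n, meanlog = log(60), sdlog = 1.0 * noise),
        linguistic5 = {
          lab <- sample(scale$label, n, replace = TRUE)
          if (as_labels) lab else defuzzify_terms(lab, scale)
        },
        binary = stats::rbinom(n, 1, 0.5)
      )
    })
    names(cols) <- criteria$id
    dplyr::bind_cols(tibble::tibble(alternative = alternatives),
                     tibble::as_tibble(cols))
  })
}

#' Plant a weakly dominant alternative
#'
#' Sets one alternative's row to the best observed value on every
#' criterion (maximum for maximized, minimum for minimized criteria) and
#' nudges it strictly better, by a margin at floating-point scale, on the
#' first positively weighted criterion. Such an alternative must achieve
#' the unique top net flow; the function refuses to plant when the matrix
#' already contains another alternative that attains every per-criterion
#' best (dominance would no longer be unique).
#'
#' @inheritParams promethee
#' @param label Alternative to promote (must be present).
#' @return The crisp decision matrix with the planted row.
#' @export
plant_dominant_alternative <- function(data, criteria, label,
                                       scale = uti_linguistic_scale()) {
  crisp <- resolve_matrix(data, criteria, scale)
  i <- match(label, crisp$alternative)
  if (is.na(i)) rlang::abort(sprintf("Alternative '%s' not found.", label))
  vals <- as.matrix(crisp[, criteria$id, drop = FALSE])
  best <- purrr::map_dbl(seq_len(nrow(criteria)), function(k) {
    if (criteria$direction[k] == "maximize") max(vals[, k]) else min(vals[, k])
  })
  others <- setdiff(seq_len(nrow(vals)), i)
  already <- others[vapply(others, function(r) all(vals[r, ] == best), logical(1))]
  if (length(already) > 0) {
    rlang::abort(sprintf(
      "Matrix already contains a weakly dominant alternative ('%s'); cannot plant a second one.",
      crisp$alternative[already[1]]
    ))
  }
  vals[i, ] <- best
  k1 <- which(criteria$weight > 0)[1]
  if (is.na(k1)) rlang::abort("Cannot plant dominance: no criterion has positive weight.")
  margin <- 1e-9 * max(1, abs(best[k1]))
  vals[i, k1] <- if (criteria$direction[k1] == "maximize") best[k1] + margin else best[k1] - margin
  out <- crisp
  out[, criteria$id] <- tibble::as_tibble(as.data.frame(vals))
  out
}
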