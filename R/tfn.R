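#' Triangular fuzzy numbers
#'
#' A triangular fuzzy number (TFN) `(a, b, c)` has a piecewise-linear
#' membership function rising from 0 at `a` to 1 at the modal point `b`
#' and falling back to 0 at `c`. TFNs carry the vagueness of linguistic
#' judgements ("High", "Moderate", ...) into the analysis; they are
#' collapsed to crisp numbers with [defuzzify()] before the outranking
#' computations.
#'
#' @param a Lower support point.
#' @param b Modal point (membership exactly 1).
#' @param c Upper support point.
#'
#' @return An object of class `"tfn"`: a named numeric triple.
#' @examples
#' tfn(0.75, 1, 1)      # the "Very High" weight term
#' tfn(0.25, 0.5, 0.75) # symmetric "Moderate"
#' @export
tfn <- function(a, b, c) {
  x <- c(a = as.double(a)[1], b = as.double(b)[1], c = as.double(c)[1])
  if (anyNA(x) || any(!is.finite(x))) {
    rlang::abort("All three points of a triangular fuzzy number must be finite.")
  }
  if (!(x[["a"]] <= x[["b"]] && x[["b"]] <= x[["c"]])) {
    rlang::abort(sprintf(
      "Invalid triangular fuzzy number (%g, %g, %g): points must satisfy a <= b <= c.",
      x[["a"]], x[["b"]], x[["c"]]
    ))
  }
  structure(x, class = "tfn")
}

#' @export
format.tfn <- function(x, ...) {
  sprintf("(%g, %g, %g)", x[["a"]], x[["b"]], x[["c"]])
}

#' @export
print.tfn <- function(x, ...) {
  cat("<tfn> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Test for a triangular fuzzy number
#' @param x Object to test.
#' @return `TRUE` if `x` is a `tfn`.
#' @export
is_tfn <- function(x) inherits(x, "tfn")

#' Yager-index (centroid) defuzzification
#'
#' Collapses a fuzzy quantity to a crisp value at the centre of gravity of
#' its membership surface. For a triangular membership function over
#' `(a, b, c)` the centroid is `(a + b + c) / 3`.
#'
#' @param x A [tfn()], a `linguistic_scale`, or a numeric vector (returned
#'   unchanged, treating crisp numbers as degenerate fuzzy numbers).
#' @param ... Passed to methods.
#'
#' @return A crisp numeric value (or, for a scale, the scale tibble with a
#'   `crisp` column appended).
#' @examples
#' defuzzify(tfn(0.25, 0.5, 0.75)) # 0.5
#' defuzzify(tfn(0.75, 1, 1))      # 0.9167
#' @export
defuzzify <- function(x, ...) UseMethod("defuzzify")

#' @rdname defuzzify
#' @export
defuzzify.tfn <- function(x, ...) {
  # degenerate support: crisp number, return it exactly
  if (x[["a"]] == x[["c"]]) return(unname(x[["b"]]))
  unname(sum(x) / 3)
}

#' @rdname defuzzify
#' @export
defuzzify.numeric <- function(x, ...) x

#' @rdname defuzzify
#' @export
defuzzify.linguistic_scale <- function(x, ...) {
  dplyr::mutate(x, crisp = (.data$a + .data$b + .data$c) / 3)
}

#' Construct a linguistic scale
#'
#' An ordered mapping from verbal labels to triangular fuzzy numbers, used
#' both for criterion weights and for vague criterion values. Labels must
#' be unique and the defuzzified values must strictly increase along the
#' scale, so that "higher" labels really mean more.
#'
#' @param labels Character vector of labels, ordered low to high.
#' @param tfns List of [tfn()] objects, one per label.
#'
#' @return A tibble of class `"linguistic_scale"` with columns `label`,
#'   `a`, `b`, `c`.
#' @seealso [uti_linguistic_scale()] for the built-in five-level scale.
#' @export
linguistic_scale <- function(labels, tfns) {
  stopifnot(is.character(labels), is.list(tfns), length(labels) == length(tfns))
  if (length(labels) == 0) rlang::abort("A linguistic scale needs at least one term.")
  if (anyDuplicated(tolower(trimws(labels)))) {
    rlang::abort("Linguistic scale labels must be unique (case-insensitively).")
  }
  bad <- !vapply(tfns, is_tfn, logical(1))
  if (any(bad)) rlang::abort("Every scale entry must be a triangular fuzzy number; see tfn().")
  out <- tibble::tibble(
    label = labels,
    a = vapply(tfns, `[[`, double(1), "a"),
    b = vapply(tfns, `[[`, double(1), "b"),
    c = vapply(tfns, `[[`, double(1), "c")
  )
  crisp <- (out$a + out$b + out$c) / 3
  if (any(diff(crisp) <= 0)) {
    rlang::abort("Defuzzified scale values must strictly increase from the lowest to the highest term.")
  }
  class(out) <- c("linguistic_scale", class(out))
  out
}

#' The five-level linguistic weighting scale of the UTI study
#'
#' Very Low (0, 0, 0.25), Low (0, 0.25, 0.50), Moderate (0.25, 0.50, 0.75),
#' High (0.50, 0.75, 1) and Very High (0.75, 1, 1): the triangular fuzzy
#' scale used to elicit both criterion weights and vague criterion values
#' in the urinary-tract-infection diagnostic study design shipped with the
#' package.
#'
#' @return A `linguistic_scale` tibble with five rows.
#' @examples
#' defuzzify(uti_linguistic_scale())
#' @export
uti_linguistic_scale <- function() {
  linguistic_scale(
    labels = c("Very Low", "Low", "Moderate", "High", "Very High"),
    tfns = list(
      tfn(0, 0, 0.25),
      tfn(0, 0.25, 0.50),
      tfn(0.25, 0.50, 0.75),
      tfn(0.50, 0.75, 1),
      tfn(0.75, 1, 1)
    )
  )
}

#' Resolve a linguistic term to its fuzzy number
#'
#' Lookup is case-insensitive after trimming surrounding whitespace.
#'
#' @param label A single label, e.g. `"Very High"`.
#' @param scale A `linguistic_scale`; defaults to [uti_linguistic_scale()].
#'
#' @return The matching [tfn()].
#' @examples
#' resolve_term("very high")
#' @export
resolve_term <- function(label, scale = uti_linguistic_scale()) {
  stopifnot(inherits(scale, "linguistic_scale"), nrow(scale) > 0)
  if (!is.character(label) || length(label) != 1L) {
    rlang::abort("`label` must be a single character string.")
  }
  key <- tolower(trimws(label))
  hit <- match(key, tolower(trimws(scale$label)))
  if (is.na(hit)) {
    rlang::abort(sprintf(
      "Unknown linguistic term '%s'. Valid terms: %s.",
      label, paste(scale$label, collapse = ", ")
    ))
  }
  tfn(scale$a[hit], scale$b[hit], scale$c[hit])
}

#' Defuzzify a vector of linguistic terms
#'
#' Vectorised convenience: maps each label through the scale and returns
#' the Yager centroid of its fuzzy number.
#'
#' @param labels Character vector of scale labels.
#' @inheritParams resolve_term
#' @return Numeric vector of crisp values.
#' @export
defuzzify_terms <- function(labels, scale = uti_linguistic_scale()) {
  vapply(labels, function(l) defuzzify(resolve_term(l, scale)), double(1),
         USE.NAMES = FALSE)
}

#' Normalize a weight vector to sum one
#'
#' Criterion weights are divided by their total so that the pairwise
#' preference index, a weight-weighted average of per-criterion preference
#' degrees, stays inside the unit interval.
#'
#' @param w Numeric vector of non-negative weights, at least one positive.
#' @return Numeric vector summing to 1.
#' @examples
#' normalize_weights(c(2, 2))
#' @export
normalize_weights <- function(w) {
  if (!is.numeric(w) || length(w) == 0) rlang::abort("`w` must be a non-empty numeric vector.")
  if (anyNA(w) || any(!is.finite(w))) rlang::abort("Weights must be finite.")
  if (any(w < 0)) rlang::abort("Weights must be non-negative.")
  s <- sum(w)
  if (s <= 0) rlang::abort("At least one weight must be positive.")
  w / s
}
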