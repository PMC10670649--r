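#' Define the criteria of a decision problem
#'
#' Builds the criteria table that drives an outranking analysis: one row
#' per criterion with its optimisation direction, fuzzy weight, preference
#' function and (optional) spread override. Weights may be given as
#' linguistic labels (resolved through `scale`), as [tfn()] objects, or as
#' crisp numbers (treated as degenerate fuzzy numbers).
#'
#' @param id Character vector of short criterion codes (unique).
#' @param direction `"maximize"` or `"minimize"`, recycled.
#' @param weight Linguistic labels, list of [tfn()]s, or crisp numbers.
#' @param name Long names; defaults to `id`.
#' @param pf Preference-function family per criterion, one of `"gaussian"`,
#'   `"usual"`, `"u_shape"`, `"v_shape"`, `"level"`, `"linear"`. Recycled.
#' @param q,p,s Thresholds: indifference `q`, preference `p`, Gaussian
#'   spread `s`, each in the criterion's own units. `NA` means
#'   not-applicable (for `s`, estimate it from the data as the population
#'   standard deviation of the criterion column).
#' @param class Optional generator class used by
#'   [simulate_decision_matrix()]: one of `"percentage"`, `"cost_like"`,
#'   `"time_like"`, `"linguistic5"`, `"binary"`.
#' @param scale The `linguistic_scale` used to resolve label weights.
#'
#' @return A tibble of class `"criteria"` with columns `id`, `name`,
#'   `direction`, `weight_label`, `weight_a`, `weight_b`, `weight_c`,
#'   `weight` (crisp, defuzzified, unnormalized), `pf`, `q`, `p`, `s`,
#'   `class`.
#' @examples
#' define_criteria(
#'   id = c("sens", "cost"),
#'   direction = c("maximize", "minimize"),
#'   weight = c("High", "Moderate")
#' )
#' @export
define_criteria <- function(id, direction, weight, name = id,
                            pf = "gaussian", q = NA_real_, p = NA_real_,
                            s = NA_real_, class = NA_character_,
                            scale = uti_linguistic_scale()) {
  K <- length(id)
  stopifnot(is.character(id), K >= 1)
  if (anyDuplicated(id)) rlang::abort("Criterion ids must be unique.")
  direction <- rep_len(match.arg(direction, c("maximize", "minimize"), several.ok = TRUE), K)
  pf <- rep_len(pf, K)
  bad_pf <- setdiff(unique(pf), pf_families())
  if (length(bad_pf) > 0) {
    rlang::abort(sprintf("Unknown preference-function family: %s. Valid families: %s.",
                         paste(bad_pf, collapse = ", "), paste(pf_families(), collapse = ", ")))
  }
  q <- rep_len(as.double(q), K)
  p <- rep_len(as.double(p), K)
  s <- rep_len(as.double(s), K)
  if (any(!is.na(s) & s < 0)) rlang::abort("Spread overrides `s` must be non-negative.")
  if (any(!is.na(q) & !is.na(p) & (q < 0 | q > p))) {
    rlang::abort("Thresholds must satisfy 0 <= q <= p.")
  }
  class <- rep_len(as.character(class), K)

  wt <- resolve_weights(weight, K, scale)
  out <- tibble::tibble(
    id = id,
    name = rep_len(name, K),
    direction = direction,
    weight_label = wt$label,
    weight_a = wt$a, weight_b = wt$b, weight_c = wt$c,
    weight = (wt$a + wt$b + wt$c) / 3,
    pf = pf, q = q, p = p, s = s,
    class = class
  )
  if (any(out$weight < 0)) rlang::abort("Crisp criterion weights must be non-negative.")
  class(out) <- c("criteria", class(out))
  out
}

# Accept labels, tfn list, or crisp numerics; return label + support points.
resolve_weights <- function(weight, K, scale) {
  if (is.character(weight)) {
    weight <- rep_len(weight, K)
    t <- lapply(weight, resolve_term, scale = scale)
    list(label = weight,
         a = vapply(t, `[[`, double(1), "a"),
         b = vapply(t, `[[`, double(1), "b"),
         c = vapply(t, `[[`, double(1), "c"))
  } else if (is.list(weight)) {
    weight <- rep_len(weight, K)
    bad <- !vapply(weight, is_tfn, logical(1))
    if (any(bad)) rlang::abort("List weights must all be tfn() objects.")
    list(label = rep(NA_character_, K),
         a = vapply(weight, `[[`, double(1), "a"),
         b = vapply(weight, `[[`, double(1), "b"),
         c = vapply(weight, `[[`, double(1), "c"))
  } else if (is.numeric(weight)) {
    weight <- rep_len(as.double(weight), K)
    list(label = rep(NA_character_, K), a = weight, b = weight, c = weight)
  } else {
    rlang::abort("`weight` must be linguistic labels, a list of tfn(), or numeric.")
  }
}

pf_families <- function() c("gaussian", "usual", "u_shape", "v_shape", "level", "linear")

#' Read a criteria configuration from YAML or JSON
#'
#' The file holds a list `criteria:` of entries with fields `id`, `name`,
#' `direction`, `weight` (a linguistic label or an explicit `[a, b, c]`
#' triple), `pf` (family plus optional `q`, `p`, `s`) and optional
#' `class`. An optional top-level `scale:` block (label -> `[a, b, c]`)
#' replaces the built-in five-level scale.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `criteria` tibble; the scale used is attached as attribute
#'   `"scale"`.
#' @export
read_criteria <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("Criteria file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$criteria)) rlang::abort("Criteria config must contain a `criteria:` list.")
  scale <- if (!is.null(cfg$scale)) {
    linguistic_scale(names(cfg$scale),
                     lapply(cfg$scale, function(v) tfn(v[[1]], v[[2]], v[[3]])))
  } else {
    uti_linguistic_scale()
  }
  entries <- cfg$criteria
  get_chr <- function(e, f, default = NA_character_) if (is.null(e[[f]])) default else as.character(e[[f]])
  get_num <- function(e, f) if (is.null(e[[f]])) NA_real_ else as.double(e[[f]])
  ids <- vapply(entries, get_chr, character(1), "id")
  weights <- lapply(entries, function(e) {
    w <- e$weight
    if (is.null(w)) rlang::abort(sprintf("Criterion '%s' has no weight.", get_chr(e, "id")))
    if (is.character(w)) w else tfn(w[[1]], w[[2]], w[[3]])
  })
  # mixed label / explicit-triple weights: resolve labels through the scale
  wt_tfn <- lapply(weights, function(w) if (is_tfn(w)) w else resolve_term(w, scale))
  labels <- vapply(weights, function(w) if (is.character(w)) w else NA_character_, character(1))
  out <- define_criteria(
    id = ids,
    name = vapply(seq_along(entries), function(i) get_chr(entries[[i]], "name", ids[[i]]), character(1)),
    direction = vapply(entries, get_chr, character(1), "direction"),
    weight = wt_tfn,
    pf = vapply(entries, function(e) get_chr(e$pf, "family", "gaussian"), character(1)),
    q = vapply(entries, function(e) get_num(e$pf, "q"), double(1)),
    p = vapply(entries, function(e) get_num(e$pf, "p"), double(1)),
    s = vapply(entries, function(e) get_num(e$pf, "s"), double(1)),
    class = vapply(entries, get_chr, character(1), "class"),
    scale = scale
  )
  out$weight_label <- labels
  attr(out, "scale") <- scale
  out
}
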