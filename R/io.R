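#' Read a decision matrix from CSV
#'
#' Expects the first column to hold alternative labels and the header row
#' the criterion ids. When `criteria` is supplied the cells are validated
#' and linguistic cells defuzzified immediately (missing or unparseable
#' cells are reported with row/column coordinates); otherwise the raw
#' tibble is returned for later resolution.
#'
#' @param path Path to a UTF-8, comma-separated file.
#' @param criteria Optional [define_criteria()] tibble.
#' @param scale `linguistic_scale` for linguistic cells.
#' @return A tibble; crisp (all-numeric criterion columns) when
#'   `criteria` is given.
#' @export
read_decision_matrix <- function(path, criteria = NULL,
                                 scale = uti_linguistic_scale()) {
  if (!file.exists(path)) rlang::abort(sprintf("Decision matrix file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (is.null(criteria)) return(raw)
  resolve_matrix(raw, criteria, scale)
}

#' Write a decision matrix to CSV
#'
#' @param data Decision-matrix tibble (first column = alternative labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decision_matrix <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

fmt4 <- function(x) formatC(round(x, 4), format = "f", digits = 4)

#' Write a ranking report
#'
#' Emits the complete ranking with a provenance block. The CSV dialect
#' shows flows rounded half-even to four decimals (the display
#' convention of the original tables); the JSON dialect carries the
#' full-precision payload plus provenance (criteria-configuration hash,
#' epsilon, problem size, package version). Output is byte-stable for
#' identical inputs.
#'
#' @param fit A `promethee` object.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_ranking_report <- function(fit, path, format = c("csv", "json")) {
  stopifnot(inherits(fit, "promethee"))
  format <- match.arg(format)
  prov <- list(
    tool = "fpromethee",
    version = as.character(utils::packageVersion("fpromethee")),
    n_alternatives = nrow(fit$crisp),
    n_criteria = nrow(fit$criteria),
    epsilon = fit$epsilon,
    criteria_hash = rlang::hash(fit$criteria)
  )
  if (format == "csv") {
    disp <- dplyr::mutate(fit$ranking,
                          phi_net = fmt4(.data$phi_net),
                          phi_plus = fmt4(.data$phi_plus),
                          phi_minus = fmt4(.data$phi_minus))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(sprintf("# %s", jsonlite::toJSON(prov, auto_unbox = TRUE)), con)
    writeLines("rank,alternative,phi_net,phi_plus,phi_minus", con)
    writeLines(sprintf("%d,\"%s\",%s,%s,%s", disp$rank, disp$alternative,
                       disp$phi_net, disp$phi_plus, disp$phi_minus), con)
  } else {
    payload <- list(provenance = prov,
                    ranking = fit$ranking,
                    flows = fit$flows)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

#' Write the unicriterion flow profile as long-format CSV
#'
#' One row per (alternative, criterion) with the unweighted unicriterion
#' net flow and its weighted contribution, ready for strength/weakness
#' profile plotting.
#'
#' @inheritParams write_ranking_report
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(fit, path) {
  stopifnot(inherits(fit, "promethee"))
  readr::write_csv(fit$profile, path, progress = FALSE)
  invisible(path)
}
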