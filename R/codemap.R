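#' Normalize ICD-10 diagnosis codes
#'
#' Uppercases, strips the dot, and truncates to the four-character
#' subcategory level, so that `"e11.9"` and `"E119"` compare equal. A valid
#' code is a letter followed by two digits (the three-character category),
#' optionally followed by one further alphanumeric character (the
#' four-character subcategory).
#'
#' @param x Character vector of raw codes.
#' @return Character vector of normalized codes (3 or 4 characters).
#' @examples
#' normalize_icd10(c("e11.9", "I10", "j44.1x"))
#' @export
normalize_icd10 <- function(x) {
  if (length(x) == 0) return(character(0))
  if (!is.character(x)) stop("ICD-10 codes must be character", call. = FALSE)
  out <- toupper(gsub(".", "", x, fixed = TRUE))
  out <- substr(out, 1L, 4L)
  bad <- !grepl("^[A-Z][0-9]{2}[A-Z0-9]?$", out) | is.na(out)
  if (any(bad)) {
    stop(sprintf(
      "malformed ICD-10 code%s: %s",
      if (sum(bad) > 1) "s" else "",
      paste(unique(x[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  out
}

#' Build a condition-to-ICD-10 code map
#'
#' A code map assigns each chronic condition a set of normalized ICD-10
#' codes. Three-character entries cover all their four-character children
#' (prefix semantics, see [match_code()]). Each code may carry a free-text
#' subcategory label (e.g. "cause", "manifestation", "consequence") used by
#' [subcategory_sensitivity()]; unlabelled codes fall into `"other"`. Each
#' condition may carry an ICD-10 chapter allowlist (first letters) used as
#' the clinical-relevance screen during backward coding.
#'
#' @param codes Data frame with columns `condition`, `code`, and optionally
#'   `subcategory` and `provenance` (defaults `"user"`).
#' @param chapters Named list mapping condition to a character vector of
#'   allowed ICD-10 chapter letters (may be empty for conditions never
#'   backward-coded).
#' @return A `code_map` object: a tibble of codes with a `chapters`
#'   attribute.
#' @seealso [default_code_map()], [read_code_map()], [match_code()]
#' @export
code_map <- function(codes, chapters = list()) {
  check_columns(codes, c("condition", "code"), "code map")
  codes <- tibble::as_tibble(codes)
  if (!"subcategory" %in% names(codes)) codes$subcategory <- NA_character_
  if (!"provenance" %in% names(codes)) codes$provenance <- "user"
  codes$code <- normalize_icd10(codes$code)
  codes <- dplyr::distinct(
    codes[, c("condition", "code", "subcategory", "provenance")],
    .data$condition, .data$code, .keep_all = TRUE
  )
  bad_ch <- setdiff(names(chapters), unique(codes$condition))
  if (length(bad_ch) > 0) {
    stop("chapters given for unmapped condition: ", paste(bad_ch, collapse = ", "),
         call. = FALSE)
  }
  structure(codes, chapters = chapters, class = c("code_map", class(codes)))
}

#' @export
print.code_map <- function(x, ...) {
  cat(sprintf(
    "<code_map> %d codes across %d conditions\n",
    nrow(x), dplyr::n_distinct(x$condition)
  ))
  NextMethod()
}

map_conditions <- function(map) unique(map$condition)

#' Codes mapped to one condition
#'
#' @param map A [code_map()].
#' @param condition Condition identifier present in the map.
#' @return Tibble of the condition's rows (code, subcategory, provenance).
#' @export
codes_for <- function(map, condition) {
  if (!condition %in% map$condition) {
    stop("condition not present in code map: ", condition, call. = FALSE)
  }
  tibble::as_tibble(map)[map$condition == condition, , drop = FALSE]
}

chapters_for <- function(map, condition) {
  ch <- attr(map, "chapters")[[condition]]
  if (is.null(ch)) character(0) else ch
}

#' Match diagnosis codes against a condition's code set
#'
#' A code matches if it is in the condition's set verbatim, or if its
#' three-character category prefix is in the set (a three-character map
#' entry covers every four-character child).
#'
#' @param map A [code_map()].
#' @param condition Condition identifier present in the map.
#' @param codes Character vector of normalized ICD-10 codes.
#' @return Logical vector, one element per input code.
#' @examples
#' m <- code_map(data.frame(condition = "diabetes", code = c("E11", "E100")))
#' match_code(m, "diabetes", c("E119", "E100", "E101", "I10"))
#' @export
match_code <- function(map, condition, codes) {
  set <- codes_for(map, condition)$code
  codes %in% set | substr(codes, 1L, 3L) %in% set[nchar(set) == 3L]
}

#' Read / write a code map as JSON
#'
#' The on-disk schema is
#' `{condition: {codes: [{code, subcategory, provenance}], chapters: [...]}}`.
#'
#' @param path File path.
#' @return For `read_code_map()`, a [code_map()]; `write_code_map()`
#'   returns `path` invisibly.
#' @export
read_code_map <- function(path) {
  raw <- jsonlite::read_json(path)
  raw <- raw[!startsWith(names(raw), "_")]  # top-level "_comment" style keys
  codes <- purrr::map_dfr(names(raw), function(cond) {
    entries <- raw[[cond]]$codes
    tibble::tibble(
      condition = cond,
      code = purrr::map_chr(entries, "code"),
      subcategory = purrr::map_chr(entries, function(e) {
        s <- e$subcategory
        if (is.null(s)) NA_character_ else s
      }),
      provenance = purrr::map_chr(entries, function(e) {
        p <- e$provenance
        if (is.null(p)) "user" else p
      })
    )
  })
  chapters <- purrr::map(raw, function(entry) {
    as.character(unlist(entry$chapters))
  })
  chapters <- chapters[lengths(chapters) > 0]
  code_map(codes, chapters)
}

#' @rdname read_code_map
#' @param map A [code_map()] to serialize.
#' @export
write_code_map <- function(map, path) {
  conds <- map_conditions(map)
  obj <- stats::setNames(purrr::map(conds, function(cond) {
    rows <- codes_for(map, cond)
    list(
      codes = purrr::pmap(
        rows[, c("code", "subcategory", "provenance")],
        function(code, subcategory, provenance) {
          out <- list(code = code, provenance = provenance)
          if (!is.na(subcategory)) out$subcategory <- subcategory
          out
        }
      ),
      chapters = as.list(chapters_for(map, cond))
    )
  }), conds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Default condition-to-ICD-10 map
#'
#' A reconstructed mapping of the twelve questionnaire conditions to ICD-10
#' codes in the spirit of the union of the Royal College of Surgeons
#' Charlson, Quan Charlson and Elixhauser comorbidity index code lists. It
#' is NOT the authoritative list used in any particular study — those lists
#' are not publicly printed — and is intended as a starting point; supply
#' your own map through [read_code_map()] for real analyses.
#'
#' @return A [code_map()].
#' @export
default_code_map <- function() {
  path <- system.file("extdata", "default_codemap.json", package = "chronicagree")
  if (path == "") stop("default code map not found; is the package installed?", call. = FALSE)
  read_code_map(path)
}
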