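#' Normalize ICD-10 code strings
#'
#' Uppercases, strips dots and whitespace, and validates against the ICD-10
#' lexical pattern (letter, two digits, up to two alphanumeric subdivision
#' characters). Subdivision depth accommodates national modifications such as
#' ICD-10-GM.
#'
#' @param codes Character vector of ICD-10 codes (dots allowed).
#' @return Normalized character vector.
#' @export
normalize_icd <- function(codes) {
  out <- toupper(gsub("[.\\s]", "", as.character(codes), perl = TRUE))
  bad <- !grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,2}$", out)
  if (any(bad)) {
    stop("malformed ICD-10 code(s): ", paste(unique(codes[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' ICD-10 code sets
#'
#' A code set is a named collection of normalized ICD-10 prefixes matched by
#' prefix against normalized codes. [read_codeset()] loads one from a YAML
#' file with fields `name` and `codes`; [codeset()] builds one in code.
#' `codeset_charlson_renal()` and `codeset_cdc_exclusion()` return the
#' bundled defaults: the Charlson moderate-to-severe renal-disease mapping
#' and the complementary kidney-disease exclusion list. Both ship as editable
#' YAML under `inst/extdata/codesets/`.
#'
#' @param name Label for the set.
#' @param codes Character vector of ICD-10 prefixes.
#' @param path Path to a YAML file.
#' @return An object of class `icd_codeset`.
#' @export
codeset <- function(name, codes) {
  codes <- normalize_icd(codes)
  if (!length(codes)) stop("a code set must contain at least one code", call. = FALSE)
  structure(list(name = name, codes = unique(codes), match_mode = "prefix"),
    class = "icd_codeset"
  )
}

#' @rdname codeset
#' @export
read_codeset <- function(path) {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$name) || is.null(spec$codes)) {
    stop("code-set YAML must contain `name` and `codes`", call. = FALSE)
  }
  codeset(spec$name, unlist(spec$codes))
}

#' @rdname codeset
#' @export
codeset_charlson_renal <- function() {
  read_codeset(system.file("extdata", "codesets", "charlson_renal.yaml",
    package = "renalphen", mustWork = TRUE
  ))
}

#' @rdname codeset
#' @export
codeset_cdc_exclusion <- function() {
  read_codeset(system.file("extdata", "codesets", "cdc_kidney_exclusion.yaml",
    package = "renalphen", mustWork = TRUE
  ))
}

#' @export
print.icd_codeset <- function(x, ...) {
  cat("<icd_codeset>", x$name, "-", length(x$codes), "prefixes\n")
  cat(" ", paste(x$codes, collapse = " "), "\n")
  invisible(x)
}

#' Match ICD-10 codes against a code set
#'
#' @param codes Character vector of codes (normalized internally).
#' @param set An `icd_codeset`.
#' @return Logical vector: does each code start with any prefix in the set?
#' @export
icd_matches <- function(codes, set) {
  stopifnot(inherits(set, "icd_codeset"))
  codes <- normalize_icd(codes)
  if (!length(codes)) {
    return(logical(0))
  }
  hit <- rep(FALSE, length(codes))
  for (p in set$codes) hit <- hit | startsWith(codes, p)
  hit
}
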