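#' Construct a diagnosis code list
#'
#' A code list is a set of ICD-9/ICD-10 prefix patterns, each with optional
#' exclusion prefixes carved out of it.  A normalized code matches the list
#' when some pattern of the same ICD version is a prefix of the code and no
#' exclusion of that pattern is a prefix of the code.  Prefix (rather than
#' exact-code) matching lets one list cover both 3-digit physician-billing
#' codes and 4-5 character discharge-abstract codes.
#'
#' @param patterns Data frame with columns `icd_version` (9 or 10), `prefix`
#'   (non-empty after normalization) and optionally `exclusions`
#'   (semicolon-separated prefixes, each extending `prefix`).
#' @param tier Optional tier label, one of `CONSERVATIVE`,
#'   `LESS_CONSERVATIVE`, `INCLUSIVE`, or `NA`.
#' @param label Free-text description.
#' @param provenance `"PACKAGE_DEFAULT"` or `"USER_SUPPLIED"`.
#' @return An object of class `code_list`.
#' @seealso [default_codelists()], [match_code()], [load_codelist()]
#' @export
code_list <- function(patterns, tier = NA_character_, label = "",
                      provenance = "USER_SUPPLIED") {
  patterns <- as.data.frame(patterns, stringsAsFactors = FALSE)
  if (!all(c("icd_version", "prefix") %in% names(patterns))) {
    stop("patterns must have columns icd_version and prefix", call. = FALSE)
  }
  if (is.null(patterns$exclusions)) patterns$exclusions <- ""
  patterns <- patterns[c("icd_version", "prefix", "exclusions")]
  if (nrow(patterns) == 0) stop("code list has no patterns", call. = FALSE)
  patterns$icd_version <- as.integer(patterns$icd_version)
  check_enum(patterns$icd_version, c(9L, 10L), "icd_version")
  patterns$prefix <- normalize_code(patterns$prefix)
  if (any(!nzchar(patterns$prefix))) {
    stop("empty code prefix after normalization", call. = FALSE)
  }
  patterns$exclusions <- vapply(seq_len(nrow(patterns)), function(i) {
    ex <- strsplit(patterns$exclusions[i], ";", fixed = TRUE)[[1]]
    ex <- normalize_code(ex)
    ex <- ex[nzchar(ex)]
    bad <- !startsWith(ex, patterns$prefix[i])
    if (any(bad)) {
      stop(sprintf("exclusion %s does not extend its pattern prefix %s",
                   ex[bad][1], patterns$prefix[i]), call. = FALSE)
    }
    paste(sort(unique(ex)), collapse = ";")
  }, character(1))
  patterns <- unique(patterns)
  rownames(patterns) <- NULL
  if (!is.na(tier)) check_enum(tier, TIER_LEVELS, "tier")
  check_enum(provenance, c("PACKAGE_DEFAULT", "USER_SUPPLIED"), "provenance")
  structure(list(tier = tier, label = label, provenance = provenance,
                 patterns = patterns),
            class = "code_list")
}

#' @export
print.code_list <- function(x, ...) {
  cat(sprintf("<code_list> tier=%s provenance=%s (%d patterns)\n",
              x$tier, x$provenance, nrow(x$patterns)))
  if (nzchar(x$label)) cat(" ", x$label, "\n")
  invisible(x)
}

#' Built-in metastasis code-list tiers
#'
#' The three tiers used by the case-finding algorithms, from most to least
#' restrictive:
#'
#' * `CONSERVATIVE` — secondary malignant neoplasm codes only
#'   (ICD-9 196-198; ICD-10 C77-C79).
#' * `LESS_CONSERVATIVE` — conservative plus malignancy of other/ill-defined
#'   or unspecified site (ICD-9 195, 199; ICD-10 C76, C80).
#' * `INCLUSIVE` — any malignancy (ICD-9 140-208; ICD-10 C00-C97) excluding
#'   digestive organs (ICD-9 150-159; ICD-10 C15-C26), so that a primary
#'   gastric cancer code is never itself taken as metastasis evidence.
#'
#' Each tier's matches are a superset of the previous tier's.  The defaults
#' encode the conventional ICD chapter structure for these verbal
#' definitions; any tier can be replaced by a user file via
#' [load_codelist()], and reports record the provenance.
#'
#' @return Named list of three [code_list()] objects
#'   (`CONSERVATIVE`, `LESS_CONSERVATIVE`, `INCLUSIVE`).
#' @export
#' @examples
#' cl <- default_codelists()
#' match_code("1969", 9, cl$CONSERVATIVE)   # TRUE: child of 196
#' match_code("C169", 10, cl$INCLUSIVE)     # FALSE: stomach is digestive
default_codelists <- function() {
  pat <- function(v, p) data.frame(icd_version = v, prefix = p,
                                   exclusions = "",
                                   stringsAsFactors = FALSE)
  cons_pat <- rbind(pat(9L, sprintf("%d", 196:198)),
                    pat(10L, sprintf("C%02d", 77:79)))
  less_pat <- rbind(cons_pat,
                    pat(9L, c("195", "199")),
                    pat(10L, c("C76", "C80")))
  incl_pat <- rbind(pat(9L, sprintf("%d", c(140:149, 160:208))),
                    pat(10L, sprintf("C%02d", c(0:14, 27:97))))
  list(
    CONSERVATIVE = code_list(cons_pat, tier = "CONSERVATIVE",
                             label = "secondary malignant neoplasm codes",
                             provenance = "PACKAGE_DEFAULT"),
    LESS_CONSERVATIVE = code_list(
      less_pat, tier = "LESS_CONSERVATIVE",
      label = "secondary plus unspecified/ill-defined site malignancy",
      provenance = "PACKAGE_DEFAULT"),
    INCLUSIVE = code_list(
      incl_pat, tier = "INCLUSIVE",
      label = "any non-digestive malignancy",
      provenance = "PACKAGE_DEFAULT")
  )
}

#' Match normalized codes against a code list
#'
#' `TRUE` for each code such that some pattern of the matching ICD version is
#' a prefix of the code and no exclusion of that pattern is a prefix of the
#' code.
#'
#' @param code Character vector of codes (normalized with
#'   [normalize_code()]; normalization is applied again defensively).
#' @param icd_version Integer vector (9 or 10), recycled to the length of
#'   `code`.
#' @param list A [code_list()].
#' @return Logical vector.
#' @export
match_code <- function(code, icd_version, list) {
  stopifnot(inherits(list, "code_list"))
  code <- normalize_code(code)
  if (length(code) == 0 || any(!nzchar(code))) {
    stop("empty diagnosis code", call. = FALSE)
  }
  icd_version <- as.integer(rep_len(icd_version, length(code)))
  res <- logical(length(code))
  pat <- list$patterns
  for (i in seq_len(nrow(pat))) {
    cand <- icd_version == pat$icd_version[i] & startsWith(code, pat$prefix[i])
    if (any(cand) && nzchar(pat$exclusions[i])) {
      for (e in strsplit(pat$exclusions[i], ";", fixed = TRUE)[[1]]) {
        cand <- cand & !startsWith(code, e)
      }
    }
    res <- res | cand
  }
  res
}

#' Does a claim carry any qualifying code?
#'
#' Any-position matching: a claim qualifies when at least one of its
#' diagnosis codes matches the list (no primary/secondary position
#' distinction).
#'
#' @param claim A one-row data frame or list with fields `codes`
#'   (semicolon-separated string or character vector) and `icd_version`.
#' @param list A [code_list()].
#' @return Logical scalar.
#' @export
claim_is_qualifying <- function(claim, list) {
  codes <- claim$codes
  if (length(codes) == 1 && grepl(";", codes, fixed = TRUE)) {
    codes <- strsplit(codes, ";", fixed = TRUE)[[1]]
  }
  any(match_code(codes, claim$icd_version, list))
}

#' Read a code list from a plain-text file
#'
#' One pattern per line in the form `icd_version,prefix[,!exclusion...]`;
#' `#` starts a comment.  Duplicate patterns are removed with a warning.
#'
#' @param path File path.
#' @param tier Optional tier label to attach.
#' @param label Description; defaults to the file name.
#' @return A [code_list()] with `provenance = "USER_SUPPLIED"`.
#' @export
load_codelist <- function(path, tier = NA_character_,
                          label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  rows <- list()
  for (i in seq_along(raw)) {
    line <- trimws(sub("#.*$", "", raw[i]))
    if (!nzchar(line)) next
    parts <- trimws(strsplit(line, ",", fixed = TRUE)[[1]])
    if (length(parts) < 2 || !(parts[1] %in% c("9", "10")) ||
        !nzchar(normalize_code(parts[2]))) {
      stop(sprintf("malformed code-list line %d in %s: %s", i, path,
                   dQuote(raw[i])), call. = FALSE)
    }
    excl <- parts[-(1:2)]
    if (length(excl) && !all(startsWith(excl, "!"))) {
      stop(sprintf("malformed code-list line %d in %s: exclusions must start with '!'",
                   i, path), call. = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      icd_version = as.integer(parts[1]),
      prefix = parts[2],
      exclusions = paste(sub("^!", "", excl), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("code-list file ", path, " has no patterns",
                          call. = FALSE)
  patterns <- do.call(rbind, rows)
  key <- paste(patterns$icd_version, normalize_code(patterns$prefix),
               patterns$exclusions)
  if (anyDuplicated(key)) {
    warning(sprintf("removed %d duplicate pattern(s) in %s",
                    sum(duplicated(key)), path), call. = FALSE)
    patterns <- patterns[!duplicated(key), , drop = FALSE]
  }
  code_list(patterns, tier = tier, label = label,
            provenance = "USER_SUPPLIED")
}

#' Write a code list to the plain-text format read by [load_codelist()]
#'
#' @param x A [code_list()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_codelist <- function(x, path) {
  stopifnot(inherits(x, "code_list"))
  header <- sprintf("# code list: %s (tier=%s, provenance=%s)",
                    x$label, x$tier, x$provenance)
  lines <- vapply(seq_len(nrow(x$patterns)), function(i) {
    p <- x$patterns[i, ]
    excl <- ""
    if (nzchar(p$exclusions)) {
      excl <- paste0(",", paste0("!", strsplit(p$exclusions, ";")[[1]],
                                 collapse = ","))
    }
    sprintf("%d,%s%s", p$icd_version, p$prefix, excl)
  }, character(1))
  writeLines(c(header, lines), path)
  invisible(path)
}
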