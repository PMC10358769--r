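#' Normalize clinical free text for lexicon matching
#'
#' Lower-cases, transliterates diacritics to ASCII, replaces every
#' non-alphanumeric character by a space and collapses runs of whitespace.
#' This is the single normalization rule shared by the lexicon and the
#' extractor, so a surface form stored in the lexicon matches itself in any
#' note rendering.
#'
#' @param x character vector.
#' @return normalized character vector of the same length.
#' @export
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  x[is.na(x)] <- ""
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Tokenize normalized text
#'
#' @param x character vector.
#' @return list of character vectors of tokens (empty vector for empty
#'   strings).
#' @export
tokenize_text <- function(x) {
  norm <- normalize_text(x)
  out <- strsplit(norm, " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

#' Read a drug lexicon mapping surface forms to ATC level-5 codes
#'
#' The lexicon is the deterministic stand-in for a hospital drug database:
#' each row maps one drug surface form (an INN or brand name, possibly
#' multi-word) to its ATC level-5 code. Several surface forms may share a
#' code (synonyms); a surface form must be unique after normalization.
#' Combination products carry their own ATC code (for instance the A10BD
#' branch for oral antidiabetic combinations) and are never expanded into
#' their components, following ATC's own convention.
#'
#' @param path path to a CSV file with columns \code{surface_form} and
#'   \code{atc_code}.
#' @return object of class \code{"drug_lexicon"}: a data frame with columns
#'   \code{surface_form}, \code{atc_code}, \code{norm_form},
#'   \code{n_tokens}.
#' @export
read_lexicon <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("surface_form", "atc_code") %in% names(raw))) {
    stop("lexicon file must have columns surface_form, atc_code",
      call. = FALSE
    )
  }
  as_lexicon(raw)
}

#' Build a drug lexicon from a data frame
#'
#' @param entries data frame with columns \code{surface_form},
#'   \code{atc_code} (level-5 codes).
#' @return object of class \code{"drug_lexicon"}.
#' @export
as_lexicon <- function(entries) {
  codes <- atc_parse(entries$atc_code)
  lv <- atc_level(codes)
  if (any(lv != 5L)) {
    stop("lexicon ATC codes must all be level 5; offending: ",
      paste(unique(entries$atc_code[lv != 5L]), collapse = ", "),
      call. = FALSE
    )
  }
  norm <- normalize_text(entries$surface_form)
  if (any(!nzchar(norm))) {
    stop("lexicon contains empty surface forms", call. = FALSE)
  }
  if (anyDuplicated(norm)) {
    stop("surface forms not unique after normalization: ",
      paste(unique(norm[duplicated(norm)]), collapse = ", "),
      call. = FALSE
    )
  }
  lex <- data.frame(
    surface_form = as.character(entries$surface_form),
    atc_code = unclass(codes),
    norm_form = norm,
    n_tokens = lengths(strsplit(norm, " ", fixed = TRUE)),
    stringsAsFactors = FALSE
  )
  class(lex) <- c("drug_lexicon", "data.frame")
  lex
}

#' The packaged drug lexicon
#'
#' A fixture lexicon of common surface forms (metformin, statins, ACE
#' inhibitors, ...) covering the ATC level-2 classes most frequently
#' prescribed to people with type 2 diabetes. It stands in for a hospital
#' drug registry, which is not redistributable.
#'
#' @return object of class \code{"drug_lexicon"}.
#' @export
default_lexicon <- function() {
  path <- system.file("extdata", "drug_lexicon.csv",
    package = "atcprofiles", mustWork = TRUE
  )
  read_lexicon(path)
}

#' @export
print.drug_lexicon <- function(x, ...) {
  cat(
    "<drug_lexicon> ", nrow(x), " surface forms, ",
    length(unique(x$atc_code)), " ATC level-5 codes, ",
    length(unique(atc_truncate(x$atc_code, 2))), " level-2 classes\n",
    sep = ""
  )
  invisible(x)
}

# surface forms available for one ATC level-5 code
.lexicon_forms <- function(lexicon, atc5) {
  lexicon$surface_form[lexicon$atc_code == atc5]
}
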