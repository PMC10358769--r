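#' Parse Anatomical Therapeutic Chemical (ATC) codes
#'
#' Validates one or more ATC codes and returns them normalized to upper
#' case. The ATC system is hierarchical with five levels: level 1 is a
#' single anatomical main-group letter (e.g. \code{"A"}, alimentary tract
#' and metabolism), level 2 adds two digits for the therapeutic subgroup
#' (e.g. \code{"A10"}, drugs used in diabetes), levels 3 and 4 each add one
#' letter (pharmacological and chemical subgroup, e.g. \code{"A10BA"},
#' biguanides), and level 5 adds two final digits identifying the chemical
#' substance (e.g. \code{"A10BA02"}, metformin). Any prefix of a valid code
#' at one of these widths is itself a valid code.
#'
#' @param code character vector of candidate ATC codes.
#' @return The input, upper-cased, invisibly classed \code{"atc"}. Malformed
#'   codes raise an error naming the offending strings.
#' @examples
#' atc_parse("A10BA02")
#' atc_level("A10BA02") # 5
#' atc_truncate("A10BA02", 2) # "A10"
#' @export
atc_parse <- function(code) {
  if (length(code) == 0) {
    return(structure(character(0), class = "atc"))
  }
  if (!is.character(code)) {
    stop("ATC codes must be character strings", call. = FALSE)
  }
  x <- toupper(trimws(code))
  lv <- atc_level(x, strict = FALSE)
  if (anyNA(lv)) {
    bad <- unique(code[is.na(lv)])
    stop(
      "malformed ATC code(s): ",
      paste(sprintf("\"%s\"", bad), collapse = ", "),
      call. = FALSE
    )
  }
  structure(x, class = "atc")
}

# Level-1 anatomical main groups actually assigned by WHO.
.atc_main_groups <- "ABCDGHJLMNPRSV"

#' Detect the level of an ATC code
#'
#' @param code character vector of ATC codes (upper case or mixed case).
#' @param strict error on malformed codes (default) or return \code{NA}.
#' @return integer vector of levels 1-5; \code{NA} for malformed codes when
#'   \code{strict = FALSE}.
#' @export
atc_level <- function(code, strict = TRUE) {
  x <- toupper(trimws(as.character(code)))
  g <- sprintf("[%s]", .atc_main_groups)
  pat <- c(
    paste0("^", g, "$"),
    paste0("^", g, "[0-9]{2}$"),
    paste0("^", g, "[0-9]{2}[A-Z]$"),
    paste0("^", g, "[0-9]{2}[A-Z]{2}$"),
    paste0("^", g, "[0-9]{2}[A-Z]{2}[0-9]{2}$")
  )
  lv <- rep(NA_integer_, length(x))
  for (k in 1:5) {
    lv[grepl(pat[k], x)] <- k
  }
  if (strict && anyNA(lv) && length(x) > 0) {
    bad <- unique(code[is.na(lv)])
    stop(
      "malformed ATC code(s): ",
      paste(sprintf("\"%s\"", bad), collapse = ", "),
      call. = FALSE
    )
  }
  lv
}

#' Truncate ATC codes to a shallower level
#'
#' Truncation exploits the hierarchy: the level-2 class of metformin
#' (\code{"A10BA02"}) is \code{"A10"}. Requesting a level deeper than a
#' code's own level is an error (codes carry no information below their
#' level).
#'
#' @param code character vector of valid ATC codes.
#' @param level target level, 1-5 (scalar or vector recycled against
#'   \code{code}).
#' @return character vector of truncated codes.
#' @export
atc_truncate <- function(code, level) {
  x <- unclass(atc_parse(code))
  level <- as.integer(level)
  if (any(is.na(level)) || any(level < 1L) || any(level > 5L)) {
    stop("level must be an integer in 1..5", call. = FALSE)
  }
  lv <- atc_level(x)
  if (any(level > lv)) {
    stop(
      "cannot truncate to level ", max(level),
      ": code is shallower than the requested level",
      call. = FALSE
    )
  }
  width <- c(1L, 3L, 4L, 5L, 7L)
  substr(x, 1L, width[level])
}

#' @export
print.atc <- function(x, ...) {
  cat("<ATC codes>\n")
  print(unclass(x), ...)
  invisible(x)
}
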