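#' Extract medication mentions from free text
#'
#' Scans a clinical note for drug surface forms from a lexicon and returns
#' one medication event per distinct ATC level-5 code, in order of first
#' appearance. Matching is longest-first over token n-grams: multi-word
#' surface forms are matched before shorter ones and consume their tokens,
#' so \code{"insulin glargine"} never additionally fires a shorter form.
#' Exact (normalized) matches always score 1. With fuzzy matching enabled,
#' unconsumed n-grams whose normalized indel similarity to a surface form
#' of the same token count reaches \code{fuzzy_threshold} are returned with
#' that similarity as score; exact matches are never displaced by fuzzy
#' ones.
#'
#' @param text a single character string (the note).
#' @param lexicon a \code{\link{read_lexicon}} object.
#' @param fuzzy_threshold \code{NULL} (default, fuzzy matching off) or a
#'   similarity threshold in (0, 1]. Similarity is
#'   \code{1 - indel(a, b) / (nchar(a) + nchar(b))}, where indel is the
#'   Levenshtein distance with substitutions costing 2 (equivalently the
#'   longest-common-subsequence distance).
#' @return data frame with columns \code{atc_code}, \code{surface_form}
#'   (the lexicon's canonical form), \code{matched_text} (what was seen in
#'   the note), \code{match_score}, \code{position} (token index of first
#'   appearance). Zero rows for text with no mentions.
#' @export
extract_medications <- function(text, lexicon, fuzzy_threshold = NULL) {
  stopifnot(length(text) == 1L)
  if (!inherits(lexicon, "drug_lexicon")) {
    lexicon <- as_lexicon(lexicon)
  }
  if (nrow(lexicon) == 0L) stop("lexicon is empty", call. = FALSE)
  if (!is.null(fuzzy_threshold)) {
    stopifnot(
      is.numeric(fuzzy_threshold), fuzzy_threshold > 0,
      fuzzy_threshold <= 1
    )
  }
  empty <- data.frame(
    atc_code = character(0), surface_form = character(0),
    matched_text = character(0), match_score = numeric(0),
    position = integer(0), stringsAsFactors = FALSE
  )
  tokens <- tokenize_text(text)[[1]]
  nt <- length(tokens)
  if (nt == 0L) {
    return(empty)
  }

  consumed <- logical(nt)
  hit_idx <- integer(0)
  hit_pos <- integer(0)
  hit_gram <- character(0)
  hit_score <- numeric(0)
  record_hit <- function(idx, start, n, gram, score) {
    consumed[start:(start + n - 1L)] <<- TRUE
    hit_idx[length(hit_idx) + 1L] <<- idx
    hit_pos[length(hit_pos) + 1L] <<- start
    hit_gram[length(hit_gram) + 1L] <<- gram
    hit_score[length(hit_score) + 1L] <<- score
  }

  sizes <- sort(unique(lexicon$n_tokens), decreasing = TRUE)
  # pass 1: exact matches, longest n-grams first
  for (n in sizes) {
    if (nt < n) next
    starts <- seq_len(nt - n + 1L)
    grams <- if (n == 1L) {
      tokens
    } else {
      vapply(
        starts,
        function(s) paste(tokens[s:(s + n - 1L)], collapse = " "),
        character(1)
      )
    }
    idx <- match(grams, lexicon$norm_form)
    for (s in starts[!is.na(idx)]) {
      if (any(consumed[s:(s + n - 1L)])) next
      record_hit(idx[s], s, n, grams[s], 1)
    }
  }

  # pass 2: fuzzy matches on still-unconsumed n-grams
  if (!is.null(fuzzy_threshold)) {
    for (n in sizes) {
      if (nt < n) next
      forms_n <- which(lexicon$n_tokens == n)
      if (length(forms_n) == 0L) next
      starts <- seq_len(nt - n + 1L)
      for (s in starts) {
        if (any(consumed[s:(s + n - 1L)])) next
        gram <- paste(tokens[s:(s + n - 1L)], collapse = " ")
        sims <- indel_similarity(gram, lexicon$norm_form[forms_n])
        best <- which.max(sims)
        if (sims[best] >= fuzzy_threshold && sims[best] < 1) {
          record_hit(forms_n[best], s, n, gram, sims[best])
        }
      }
    }
  }

  if (length(hit_idx) == 0L) {
    return(empty)
  }
  ord <- order(hit_pos)
  out <- data.frame(
    atc_code = lexicon$atc_code[hit_idx[ord]],
    surface_form = lexicon$surface_form[hit_idx[ord]],
    matched_text = hit_gram[ord],
    match_score = hit_score[ord],
    position = hit_pos[ord],
    stringsAsFactors = FALSE
  )
  # de-duplicate: one event per ATC level-5 code, first mention wins
  out <- out[!duplicated(out$atc_code), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalized indel similarity between strings
#'
#' \code{1 - d / (nchar(a) + nchar(b))} where \code{d} is the Levenshtein
#' distance with substitution cost 2 (insert/delete cost 1), i.e. the
#' longest-common-subsequence edit distance. Identical strings score 1.
#'
#' @param a single string.
#' @param b character vector to compare against.
#' @return numeric vector of similarities in [0, 1].
#' @export
indel_similarity <- function(a, b) {
  d <- utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2))[1, ]
  tot <- nchar(a) + nchar(b)
  ifelse(tot == 0, 1, 1 - d / tot)
}

#' Assemble chronologically structured patient timelines
#'
#' Runs medication extraction over every record and organizes records,
#' extracted medication events and patient attributes into one
#' chronologically sorted structure. Records whose visit date cannot be
#' parsed are skipped and collected in an audit of rejected rows.
#'
#' @param records data frame with columns \code{record_id} (optional;
#'   created if absent), \code{patient_id}, \code{visit_date} (Date or
#'   ISO-8601 string), \code{note_text}, \code{diagnoses}
#'   (semicolon-separated ICD codes, up to 10), and optionally lab columns
#'   \code{lab_glucose}, \code{lab_cholesterol}, \code{lab_triglycerides},
#'   \code{lab_egfr}.
#' @param lexicon a \code{\link{read_lexicon}} object.
#' @param patients optional data frame with columns \code{patient_id},
#'   \code{sex}, \code{birth_year}; required by downstream age-based
#'   operations.
#' @param fuzzy_threshold passed to \code{\link{extract_medications}}.
#' @return object of class \code{"patient_timelines"}: a list with
#'   \code{patients}, \code{records} (sorted by patient then date),
#'   \code{events} (one row per record x ATC level-5 code) and
#'   \code{rejected} (unparseable records with reasons).
#' @export
build_timelines <- function(records, lexicon, patients = NULL,
                            fuzzy_threshold = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("patient_id", "visit_date", "note_text", "diagnoses")
  if (!all(needed %in% names(records))) {
    stop("records must have columns ",
      paste(needed, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"record_id" %in% names(records)) {
    records$record_id <- seq_len(nrow(records))
  }
  rejected <- data.frame(
    record_id = records$record_id[0], reason = character(0),
    stringsAsFactors = FALSE
  )
  dates <- suppressWarnings(as.Date(records$visit_date))
  bad <- is.na(dates)
  if (any(bad)) {
    rejected <- data.frame(
      record_id = records$record_id[bad],
      reason = sprintf(
        "unparseable visit_date \"%s\"",
        as.character(records$visit_date[bad])
      ),
      stringsAsFactors = FALSE
    )
    records <- records[!bad, , drop = FALSE]
    dates <- dates[!bad]
  }
  records$visit_date <- dates
  ord <- order(records$patient_id, records$visit_date)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL

  ev <- lapply(records$note_text, extract_medications, lexicon = lexicon,
    fuzzy_threshold = fuzzy_threshold
  )
  n_ev <- vapply(ev, nrow, integer(1))
  idx <- rep.int(seq_len(nrow(records)), n_ev)
  events <- data.frame(
    record_id = records$record_id[idx],
    patient_id = records$patient_id[idx],
    visit_date = records$visit_date[idx],
    atc_code = as.character(unlist(lapply(ev, `[[`, "atc_code"),
      use.names = FALSE
    )),
    surface_form = as.character(unlist(lapply(ev, `[[`, "surface_form"),
      use.names = FALSE
    )),
    match_score = as.numeric(unlist(lapply(ev, `[[`, "match_score"),
      use.names = FALSE
    )),
    stringsAsFactors = FALSE
  )
  if (nrow(events) == 0L) {
    events$visit_date <- as.Date(character(0))
  }
  if (is.null(patients)) {
    pid <- unique(records$patient_id)
    patients <- data.frame(
      patient_id = pid,
      sex = rep(NA_character_, length(pid)),
      birth_year = rep(NA_integer_, length(pid)),
      stringsAsFactors = FALSE
    )
  } else {
    patients <- as.data.frame(patients, stringsAsFactors = FALSE)
    patients <- patients[patients$patient_id %in%
      unique(c(records$patient_id, patients$patient_id)), , drop = FALSE]
  }
  structure(
    list(
      patients = patients, records = records, events = events,
      rejected = rejected
    ),
    class = "patient_timelines"
  )
}

#' @export
print.patient_timelines <- function(x, ...) {
  cat("<patient_timelines> ", nrow(x$records), " records, ",
    length(unique(x$records$patient_id)), " patients, ",
    nrow(x$events), " medication events",
    if (nrow(x$rejected) > 0) {
      paste0(" (", nrow(x$rejected), " records rejected)")
    } else {
      ""
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Extract one patient's timeline
#'
#' @param timelines a \code{"patient_timelines"} object.
#' @param patient_id a single patient id.
#' @return list with \code{patient} (one-row data frame), \code{records}
#'   and \code{events} for that patient, sorted by date.
#' @export
patient_timeline <- function(timelines, patient_id) {
  stopifnot(inherits(timelines, "patient_timelines"))
  list(
    patient = timelines$patients[
      timelines$patients$patient_id == patient_id, ,
      drop = FALSE
    ],
    records = timelines$records[
      timelines$records$patient_id == patient_id, ,
      drop = FALSE
    ],
    events = timelines$events[
      timelines$events$patient_id == patient_id, ,
      drop = FALSE
    ]
  )
}

# does a ;-separated diagnosis string contain a code with the given prefix?
.diag_has_prefix <- function(diagnoses, prefix) {
  vapply(
    strsplit(as.character(diagnoses), ";", fixed = TRUE),
    function(d) any(startsWith(trimws(d), prefix)),
    logical(1)
  )
}
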