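#' 10-year age-group labels
#'
#' The analysis partitions ages 30 and over into six groups: 30-39, 40-49,
#' 50-59, 60-69, 70-79 and 80+ (closed lower bounds; 80+ unbounded above).
#'
#' @return character vector of the six labels in ascending order.
#' @export
age_group_labels <- function() {
  c("30-39", "40-49", "50-59", "60-69", "70-79", "80+")
}

#' Assign completed ages to 10-year age groups
#'
#' @param age integer vector of completed ages in years.
#' @return character vector of group labels; \code{NA} for ages below 30.
#' @export
age_group_of <- function(age) {
  labs <- age_group_labels()
  idx <- findInterval(age, c(30, 40, 50, 60, 70, 80))
  out <- rep(NA_character_, length(age))
  ok <- !is.na(idx) & idx >= 1L
  out[ok] <- labs[idx[ok]]
  out
}

.age_at <- function(dates, birth_year) {
  as.integer(format(as.Date(dates), "%Y")) - as.integer(birth_year)
}

#' Apply the inclusion/exclusion cascade to patient timelines
#'
#' The gates are applied in a fixed order: (1) reject every patient with
#' any O24 diagnosis (gestational diabetes; patient-level); (2) keep only
#' records reporting an E11 diagnosis or a code derived from that branch
#' (record-level); (3) keep only records whose note text is strictly
#' longer than \code{min_text_chars} characters (record-level); (4) keep
#' only patients with at least \code{min_visits} surviving records inside
#' some \code{window_years}-year window (patient-level; by default a
#' sliding window anchored at each visit date, spanning
#' \code{window_years * 365.25} days inclusive); (5) reject patients
#' younger than \code{min_age} (completed years) at their first surviving
#' record. A patient whose records are all removed at a record-level gate
#' is counted as removed at that gate.
#'
#' @param timelines a \code{\link{build_timelines}} object.
#' @param min_visits minimum records in a window (default 10).
#' @param window_years window length in years (default 10).
#' @param min_text_chars strict lower bound on note length (default 100).
#' @param min_age minimum age at first surviving record (default 30).
#' @param window \code{"sliding"} (anchored at every visit) or
#'   \code{"first"} (anchored at the first surviving visit only).
#' @return list with \code{timelines} (the filtered
#'   \code{"patient_timelines"}) and \code{audit} (a
#'   \code{"filter_audit"}: per-stage record and patient removals).
#' @export
apply_inclusion <- function(timelines, min_visits = 10, window_years = 10,
                            min_text_chars = 100, min_age = 30,
                            window = c("sliding", "first")) {
  stopifnot(inherits(timelines, "patient_timelines"))
  window <- match.arg(window)
  rec <- timelines$records
  pat <- timelines$patients

  audit <- list()
  n_rec <- function(r) nrow(r)
  n_pat <- function(r) length(unique(r$patient_id))
  stage <- function(name, before, after) {
    audit[[length(audit) + 1L]] <<- data.frame(
      stage = name,
      records_removed = n_rec(before) - n_rec(after),
      patients_removed = n_pat(before) - n_pat(after),
      records_left = n_rec(after), patients_left = n_pat(after),
      stringsAsFactors = FALSE
    )
  }
  input <- data.frame(
    stage = "input", records_removed = 0L, patients_removed = 0L,
    records_left = n_rec(rec), patients_left = n_pat(rec),
    stringsAsFactors = FALSE
  )

  # 1. O24 gate, patient-level
  o24_pat <- unique(rec$patient_id[.diag_has_prefix(rec$diagnoses, "O24")])
  r1 <- rec[!(rec$patient_id %in% o24_pat), , drop = FALSE]
  stage("o24_patients", rec, r1)

  # 2. E11 gate, record-level
  r2 <- r1[.diag_has_prefix(r1$diagnoses, "E11"), , drop = FALSE]
  stage("e11_records", r1, r2)

  # 3. text-length gate, record-level ("longer than" is strict)
  r3 <- r2[nchar(r2$note_text, type = "chars") > min_text_chars, ,
    drop = FALSE
  ]
  stage("short_text_records", r2, r3)

  # 4. visit-count gate, patient-level over surviving records
  span <- window_years * 365.25
  keep_pat <- vapply(split(r3$visit_date, r3$patient_id), function(d) {
    d <- sort(as.numeric(d))
    anchors <- if (window == "sliding") d else d[1]
    any(vapply(
      anchors,
      function(a) sum(d >= a & d <= a + span) >= min_visits,
      logical(1)
    ))
  }, logical(1))
  r4 <- r3[r3$patient_id %in% names(keep_pat)[keep_pat], , drop = FALSE]
  stage("sparse_patients", r3, r4)

  # 5. age gate, patient-level, age at first surviving record
  first_date <- vapply(
    split(as.character(r4$visit_date), r4$patient_id),
    min, character(1)
  )
  by <- pat$birth_year[match(names(first_date), pat$patient_id)]
  age0 <- .age_at(first_date, by)
  keep <- names(first_date)[!is.na(age0) & age0 >= min_age]
  r5 <- r4[r4$patient_id %in% keep, , drop = FALSE]
  stage("under_age_patients", r4, r5)

  audit <- rbind(input, do.call(rbind, audit))
  class(audit) <- c("filter_audit", "data.frame")

  out <- timelines
  out$records <- r5
  out$events <- timelines$events[
    timelines$events$record_id %in% r5$record_id, ,
    drop = FALSE
  ]
  out$patients <- pat[pat$patient_id %in% unique(r5$patient_id), ,
    drop = FALSE
  ]
  rownames(out$records) <- rownames(out$events) <-
    rownames(out$patients) <- NULL
  list(timelines = out, audit = audit)
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("<filter_audit>\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Serialize a filter audit to JSON
#'
#' @param audit a \code{"filter_audit"}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_audit <- function(audit, path) {
  stopifnot(inherits(audit, "filter_audit"))
  jsonlite::write_json(as.data.frame(audit), path,
    dataframe = "rows",
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Age group at first surviving record
#'
#' Patients are assigned to the 10-year age group of their completed age
#' at initial presentation (their earliest surviving record).
#'
#' @param timelines filtered \code{"patient_timelines"}.
#' @return data frame with columns \code{patient_id}, \code{entry_age},
#'   \code{age_group}.
#' @export
assign_age_group <- function(timelines) {
  stopifnot(inherits(timelines, "patient_timelines"))
  rec <- timelines$records
  if (nrow(rec) == 0L) {
    stop("no surviving records: age group undefined", call. = FALSE)
  }
  first_date <- vapply(
    split(as.character(rec$visit_date), rec$patient_id),
    min, character(1)
  )
  by <- timelines$patients$birth_year[
    match(names(first_date), timelines$patients$patient_id)
  ]
  if (anyNA(by)) {
    stop("birth year unknown for some patients", call. = FALSE)
  }
  age <- .age_at(first_date, by)
  data.frame(
    patient_id = names(first_date), entry_age = age,
    age_group = age_group_of(age), stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Per-record age-group membership
#'
#' Each surviving record is assigned to the age group of the patient's
#' completed age on that record's date; a patient contributes to every age
#' group in which they have at least one record, which is what makes
#' cross-age-group patient tracking possible for anyone followed for more
#' than ten years.
#'
#' @param timelines filtered \code{"patient_timelines"}.
#' @return data frame with columns \code{record_id}, \code{patient_id},
#'   \code{visit_date}, \code{age}, \code{age_group} (records with age
#'   below 30 are dropped).
#' @export
age_group_membership <- function(timelines) {
  stopifnot(inherits(timelines, "patient_timelines"))
  rec <- timelines$records
  by <- timelines$patients$birth_year[
    match(rec$patient_id, timelines$patients$patient_id)
  ]
  age <- .age_at(rec$visit_date, by)
  out <- data.frame(
    record_id = rec$record_id, patient_id = rec$patient_id,
    visit_date = rec$visit_date, age = age,
    age_group = age_group_of(age), stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$age_group), , drop = FALSE]
  rownames(out) <- NULL
  out
}
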