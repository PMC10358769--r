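#' Build one patient's medication profile vector
#'
#' The profile of a patient within one age group is the union, over all
#' their records in that group, of the ATC classes (truncated to
#' \code{level}) of their medication events. In \code{"binary"} mode an
#' entry is 1 if the class was ever prescribed; in \code{"count"} mode it
#' is the number of distinct level-5 codes observed within the class.
#'
#' @param atc_codes character vector of level-5 ATC codes (the patient's
#'   medication events in one age group); may be empty (an all-zero
#'   profile).
#' @param vocabulary sorted character vector of truncated-level classes
#'   defining the vector space.
#' @param level ATC level of the profile entries (default 2).
#' @param mode \code{"binary"} or \code{"count"}.
#' @return named numeric vector over \code{vocabulary}.
#' @export
build_profile <- function(atc_codes, vocabulary, level = 2,
                          mode = c("binary", "count")) {
  mode <- match.arg(mode)
  v <- stats::setNames(numeric(length(vocabulary)), vocabulary)
  if (length(atc_codes) == 0L) {
    return(v)
  }
  codes <- unique(unclass(atc_parse(atc_codes)))
  cls <- atc_truncate(codes, level)
  unknown <- setdiff(unique(cls), vocabulary)
  if (length(unknown)) {
    stop("classes outside the vocabulary: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  tab <- table(cls)
  if (mode == "binary") {
    v[names(tab)] <- 1
  } else {
    v[names(tab)] <- as.numeric(tab)
  }
  v
}

#' Build all patient x age-group medication profiles
#'
#' One profile per (patient, age group) pair with at least one surviving
#' record. The vocabulary is frozen as the sorted union of truncated
#' classes over the whole filtered cohort (unless supplied), so profiles
#' from different age groups live in one common space — a prerequisite for
#' cross-age-group centroid distances.
#'
#' @param timelines filtered \code{"patient_timelines"}.
#' @param membership output of \code{\link{age_group_membership}}
#'   (computed if \code{NULL}).
#' @param level ATC truncation level of the profile entries (default 2).
#' @param mode \code{"binary"} (presence, default) or \code{"count"}
#'   (distinct level-5 codes per class).
#' @param vocabulary optional fixed vocabulary.
#' @return object of class \code{"medication_profiles"}: list with
#'   \code{matrix} (rows = patient x age group, columns = vocabulary),
#'   \code{info} (data frame: \code{id}, \code{patient_id},
#'   \code{age_group}, \code{n_distinct}), \code{vocabulary},
#'   \code{level}, \code{mode}. Row ids are \code{"<patient>|<group>"}.
#' @export
build_profiles <- function(timelines, membership = NULL, level = 2,
                           mode = c("binary", "count"), vocabulary = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(timelines, "patient_timelines"))
  if (is.null(membership)) membership <- age_group_membership(timelines)
  ev <- timelines$events
  ev <- ev[ev$record_id %in% membership$record_id, , drop = FALSE]
  ev$age_group <- membership$age_group[
    match(ev$record_id, membership$record_id)
  ]
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(atc_truncate(ev$atc_code, level)))
  }
  key <- paste(membership$patient_id, membership$age_group, sep = "|")
  ids <- sort(unique(key))
  ev_key <- paste(ev$patient_id, ev$age_group, sep = "|")
  ev_split <- split(ev$atc_code, factor(ev_key, levels = ids))
  mat <- t(vapply(
    ids,
    function(id) build_profile(ev_split[[id]], vocabulary, level, mode),
    numeric(length(vocabulary))
  ))
  if (length(ids) == 1L) {
    mat <- matrix(mat,
      nrow = 1,
      dimnames = list(ids, vocabulary)
    )
  }
  parts <- strsplit(ids, "|", fixed = TRUE)
  info <- data.frame(
    id = ids,
    patient_id = vapply(parts, `[[`, character(1), 1L),
    age_group = vapply(parts, `[[`, character(1), 2L),
    n_distinct = rowSums(mat > 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(
      matrix = mat, info = info, vocabulary = vocabulary,
      level = level, mode = mode
    ),
    class = "medication_profiles"
  )
}

#' @export
print.medication_profiles <- function(x, ...) {
  cat("<medication_profiles> ", nrow(x$matrix), " profiles (",
    length(unique(x$info$patient_id)), " patients, ",
    length(unique(x$info$age_group)), " age groups) over ",
    length(x$vocabulary), " ATC level-", x$level, " classes [",
    x$mode, " mode]\n",
    sep = ""
  )
  invisible(x)
}

#' Pairwise distance matrix between medication profiles
#'
#' @param profiles a \code{"medication_profiles"} object.
#' @param age_group restrict to one age group (\code{NULL} = all
#'   profiles).
#' @param metric \code{"euclidean"} (default; the metric under which a
#'   Ward merge-height cut is meaningful), \code{"jaccard"}
#'   (binary profiles only) or \code{"hamming"}.
#' @return object of class \code{"profile_dist"}: list with \code{dist}
#'   (a \code{stats::dist}), \code{ids}, \code{metric}, \code{age_group}.
#' @export
build_distance_matrix <- function(profiles, age_group = NULL,
                                  metric = c(
                                    "euclidean", "jaccard",
                                    "hamming"
                                  )) {
  metric <- match.arg(metric)
  stopifnot(inherits(profiles, "medication_profiles"))
  mat <- profiles$matrix
  if (!is.null(age_group)) {
    keep <- profiles$info$age_group == age_group
    mat <- mat[keep, , drop = FALSE]
  }
  if (nrow(mat) < 2L) {
    stop("at least two profiles are required for a distance matrix",
      call. = FALSE
    )
  }
  if (metric == "jaccard" && profiles$mode != "binary") {
    stop("jaccard distance requires binary profiles", call. = FALSE)
  }
  method <- switch(metric,
    euclidean = "euclidean", jaccard = "binary", hamming = "manhattan"
  )
  d <- stats::dist(mat, method = method)
  # all-zero profiles: dist(binary) yields NaN; two empty profiles are
  # identical (distance 0)
  if (metric == "jaccard" && anyNA(d)) d[is.na(d)] <- 0
  structure(
    list(
      dist = d, ids = rownames(mat), metric = metric,
      age_group = age_group
    ),
    class = "profile_dist"
  )
}

#' @export
print.profile_dist <- function(x, ...) {
  cat("<profile_dist> ", length(x$ids), " profiles, ", x$metric,
    " metric",
    if (!is.null(x$age_group)) paste0(", age group ", x$age_group) else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Write profiles as a wide CSV
#'
#' Rows are patient x age-group profiles, columns the ATC class
#' vocabulary.
#'
#' @param profiles a \code{"medication_profiles"}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "medication_profiles"))
  out <- cbind(
    profiles$info[, c("patient_id", "age_group")],
    as.data.frame(profiles$matrix, row.names = NULL)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
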