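#' Run the full medication-profiling pipeline
#'
#' Convenience wrapper chaining every stage: timeline assembly (with
#' medication extraction), the inclusion cascade, age-group membership,
#' profile construction over a frozen vocabulary, per-age-group
#' clustering and labeling, cross-age-group identity tracing, patient
#' flows with Not-Worse/Worse odds, and the descriptive tables. Age
#' groups with fewer than \code{min_group_size} profiles are excluded
#' from clustering (and hence tracing/flows) but remain in the profile
#' and usage tables.
#'
#' @param records record table (see \code{\link{build_timelines}}) or a
#'   \code{"synthetic_cohort"}.
#' @param patients patient table; taken from the cohort if \code{records}
#'   is one.
#' @param lexicon a \code{\link{read_lexicon}} object.
#' @param fuzzy_threshold passed to the extractor (default off).
#' @param threshold merge-height cut for clustering (default 16).
#' @param linkage,metric clustering linkage and profile metric.
#' @param level,mode profile granularity and entry mode.
#' @param min_group_size minimum profiles for an age group to be
#'   clustered (default 2).
#' @param ... further arguments passed to \code{\link{apply_inclusion}}.
#' @return list with \code{timelines}, \code{audit}, \code{membership},
#'   \code{profiles}, \code{solutions}, \code{trace}, \code{flow},
#'   \code{odds}, \code{usage_lv1}, \code{usage_lv2}, \code{diversity}.
#' @export
run_pipeline <- function(records, patients = NULL,
                         lexicon = default_lexicon(),
                         fuzzy_threshold = NULL, threshold = 16,
                         linkage = "ward", metric = "euclidean",
                         level = 2, mode = "binary",
                         min_group_size = 2, ...) {
  if (inherits(records, "synthetic_cohort")) {
    patients <- records$patients
    records <- records$records
  }
  tl <- build_timelines(records, lexicon,
    patients = patients,
    fuzzy_threshold = fuzzy_threshold
  )
  flt <- apply_inclusion(tl, ...)
  tl <- flt$timelines
  membership <- age_group_membership(tl)
  profiles <- build_profiles(tl, membership, level = level, mode = mode)

  groups <- intersect(age_group_labels(), unique(profiles$info$age_group))
  groups <- groups[vapply(
    groups,
    function(g) sum(profiles$info$age_group == g) >= min_group_size,
    logical(1)
  )]
  solutions <- lapply(groups, function(g) {
    d <- build_distance_matrix(profiles, age_group = g, metric = metric)
    label_clusters(
      cluster_profiles(d, threshold = threshold, linkage = linkage),
      profiles
    )
  })
  names(solutions) <- groups

  trace <- NULL
  flow <- NULL
  odds <- NULL
  if (length(solutions) >= 1L) {
    trace <- propagate_identities(solutions)
    flow <- build_flow(solutions, trace)
    odds <- suppressWarnings(transition_odds(flow))
  }
  list(
    timelines = tl, audit = flt$audit, membership = membership,
    profiles = profiles, solutions = solutions, trace = trace,
    flow = flow, odds = odds,
    usage_lv1 = usage_frequency(tl, membership, level = 1),
    usage_lv2 = usage_frequency(tl, membership, level = 2),
    diversity = diversity_stats(profiles, solutions)
  )
}
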