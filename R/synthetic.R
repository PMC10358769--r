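#' Define a medication-profile archetype
#'
#' An archetype is a planted "true" medication profile used by the
#' synthetic cohort generator: a core set of ATC level-2 classes that every
#' carrier is prescribed, plus optional classes each included independently
#' with probability \code{p_opt}. The expected medication diversity of an
#' archetype is \code{|core| + p_opt * |optional|}; archetypes of different
#' breadth emulate the low-polypharmacy versus multimorbid profiles seen in
#' real type 2 diabetes cohorts.
#'
#' @param name archetype label.
#' @param atc_lv2_core character vector of ATC level-2 codes always
#'   prescribed.
#' @param atc_lv2_optional character vector of level-2 codes each included
#'   with probability \code{p_opt}; must be disjoint from the core.
#' @param p_opt inclusion probability for optional classes, in [0, 1].
#' @param lab_shift named numeric vector of additive shifts applied to
#'   generated laboratory values (names among \code{"glucose"},
#'   \code{"cholesterol"}, \code{"triglycerides"}, \code{"egfr"}); e.g.
#'   \code{c(egfr = -25)} plants impaired kidney function.
#' @return object of class \code{"archetype_spec"}.
#' @export
archetype_spec <- function(name, atc_lv2_core, atc_lv2_optional = character(0),
                           p_opt = 0.2, lab_shift = numeric(0)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  core <- unclass(atc_parse(atc_lv2_core))
  opt <- if (length(atc_lv2_optional)) {
    unclass(atc_parse(atc_lv2_optional))
  } else {
    character(0)
  }
  if (any(atc_level(core) != 2L) || (length(opt) && any(atc_level(opt) != 2L))) {
    stop("archetype classes must all be ATC level-2 codes", call. = FALSE)
  }
  if (length(intersect(core, opt)) > 0) {
    stop("core and optional class sets must be disjoint", call. = FALSE)
  }
  stopifnot(is.numeric(p_opt), length(p_opt) == 1L, p_opt >= 0, p_opt <= 1)
  if (length(lab_shift)) {
    stopifnot(!is.null(names(lab_shift)), all(names(lab_shift) %in%
      c("glucose", "cholesterol", "triglycerides", "egfr")))
  }
  structure(
    list(
      name = name, atc_lv2_core = sort(core), atc_lv2_optional = sort(opt),
      p_opt = p_opt,
      mean_distinct_lv2 = length(core) + p_opt * length(opt),
      lab_shift = lab_shift
    ),
    class = "archetype_spec"
  )
}

#' @export
print.archetype_spec <- function(x, ...) {
  cat(
    "<archetype> ", x$name, ": core {",
    paste(x$atc_lv2_core, collapse = ", "), "}",
    if (length(x$atc_lv2_optional)) {
      paste0(
        " + optional {", paste(x$atc_lv2_optional, collapse = ", "),
        "} @ p=", x$p_opt
      )
    } else {
      ""
    },
    "; E[distinct LV2] = ", format(x$mean_distinct_lv2), "\n",
    sep = ""
  )
  invisible(x)
}

#' Default archetype set
#'
#' Five archetypes of increasing medication breadth, from a minimal
#' profile (antidiabetics only) to a complex multimorbid profile spanning
#' ten level-2 classes, with progressively lower planted eGFR reflecting
#' the association between polypharmacy and declining kidney function.
#'
#' @return list of \code{\link{archetype_spec}} objects.
#' @export
default_archetypes <- function() {
  list(
    archetype_spec("minimal",
      atc_lv2_core = "A10",
      atc_lv2_optional = c("C10", "C09"), p_opt = 0.15,
      lab_shift = c(egfr = 0)
    ),
    archetype_spec("cardio_basic",
      atc_lv2_core = c("A10", "C10", "C09"),
      atc_lv2_optional = c("B01", "A02"), p_opt = 0.20,
      lab_shift = c(egfr = -5)
    ),
    archetype_spec("cardio_plus",
      atc_lv2_core = c("A10", "C10", "C09", "B01", "C07"),
      atc_lv2_optional = c("C03", "C08", "A02"), p_opt = 0.25,
      lab_shift = c(egfr = -10)
    ),
    archetype_spec("polypharmacy",
      atc_lv2_core = c("A10", "C10", "C09", "B01", "C07", "C08", "C03", "A02"),
      atc_lv2_optional = c("N02", "N05", "M01", "R03"), p_opt = 0.30,
      lab_shift = c(egfr = -18, triglycerides = 0.4)
    ),
    archetype_spec("complex",
      atc_lv2_core = c(
        "A10", "C10", "C09", "B01", "C07", "C08", "C03",
        "A02", "N02", "N05"
      ),
      atc_lv2_optional = c("M01", "R03", "G04", "H03"), p_opt = 0.30,
      lab_shift = c(egfr = -25, triglycerides = 0.6)
    )
  )
}

#' Well-separated planted archetypes
#'
#' Archetypes whose core sets differ pairwise in at least four level-2
#' classes, with low optional-class noise (\code{p_opt = 0.15}). Intended
#' for planted-cluster recovery experiments where the clustering must
#' recover the archetype partition.
#'
#' @param k number of archetypes, 2 to 5.
#' @return list of \code{\link{archetype_spec}} objects.
#' @export
planted_archetypes <- function(k) {
  stopifnot(k >= 2, k <= 5)
  all5 <- list(
    archetype_spec("sep1",
      atc_lv2_core = "A10",
      atc_lv2_optional = "C10", p_opt = 0.15, lab_shift = c(egfr = 0)
    ),
    archetype_spec("sep2",
      atc_lv2_core = c("A10", "C10", "C09", "B01", "C07"),
      atc_lv2_optional = c("C03", "C08"), p_opt = 0.15,
      lab_shift = c(egfr = -8)
    ),
    archetype_spec("sep3",
      atc_lv2_core = c(
        "A10", "C10", "C09", "B01", "C07", "C03", "C08",
        "A02", "N02"
      ),
      atc_lv2_optional = c("N05", "M01"), p_opt = 0.15,
      lab_shift = c(egfr = -15)
    ),
    archetype_spec("sep4",
      atc_lv2_core = c("A10", "N05", "M01", "R03", "G04"),
      atc_lv2_optional = "N02", p_opt = 0.15, lab_shift = c(egfr = -8)
    ),
    archetype_spec("sep5",
      atc_lv2_core = c(
        "A10", "C10", "C09", "B01", "C07", "C03", "C08",
        "A02", "N02", "N05", "M01", "R03", "G04"
      ),
      atc_lv2_optional = "H03", p_opt = 0.15, lab_shift = c(egfr = -25)
    )
  )
  all5[seq_len(k)]
}

#' 10-year age-group mixing proportions for the default archetypes
#'
#' Rows are age groups, columns archetypes; each row sums to 1. The mix
#' shifts toward broader archetypes with age through the 60-69 group, then
#' polarises in the oldest group (dominated by one low- and one
#' high-medication profile).
#'
#' @return numeric matrix with age-group rownames and archetype colnames.
#' @export
default_archetype_mix <- function() {
  m <- rbind(
    "30-39" = c(0.55, 0.35, 0.10, 0.00, 0.00),
    "40-49" = c(0.40, 0.35, 0.20, 0.05, 0.00),
    "50-59" = c(0.25, 0.30, 0.30, 0.12, 0.03),
    "60-69" = c(0.12, 0.25, 0.33, 0.20, 0.10),
    "70-79" = c(0.10, 0.25, 0.30, 0.22, 0.13),
    "80+"   = c(0.30, 0.10, 0.10, 0.35, 0.15)
  )
  colnames(m) <- vapply(default_archetypes(), `[[`, character(1), "name")
  m
}

#' Synthetic cohort configuration
#'
#' Bundles and validates all knobs of the synthetic EMR generator. Decoy
#' fractions plant patients that each fail exactly one gate of the
#' inclusion cascade (and pass all earlier gates by construction), so
#' filter audits can be compared with ground truth exactly; the roles are
#' drawn mutually exclusively per patient.
#'
#' @param n_patients number of patients (>= 0).
#' @param seed integer RNG seed; identical configurations and seeds give
#'   byte-identical cohorts.
#' @param entry_age_range integer range of age at first visit for
#'   non-decoy patients (default 30-79).
#' @param follow_up_years min/max follow-up duration in years; durations
#'   are drawn uniformly.
#' @param visits_per_year Poisson rate of additional visits beyond the ten
#'   guaranteed early visits of non-sparse patients.
#' @param archetype_mix matrix of archetype proportions per age group
#'   (rows = age groups, columns = archetype names, rows summing to 1), or
#'   \code{NULL} for a uniform mix over the supplied archetypes.
#' @param archetype_persistence probability that a patient entering a new
#'   age group keeps the previous group's archetype rather than redrawing
#'   from the new group's mix. 1 freezes every patient's archetype.
#' @param frac_non_e11 fraction of decoy patients with no E11 diagnosis.
#' @param frac_o24 fraction of decoy patients carrying an O24 diagnosis.
#' @param frac_short_text fraction of decoy patients whose notes are all
#'   at most 100 characters.
#' @param frac_sparse fraction of decoy patients with fewer than 10 visits
#'   in any 10-year window.
#' @param frac_under30 fraction of decoy patients younger than 30 at first
#'   visit.
#' @param start_year_range calendar years between which follow-up begins.
#' @return object of class \code{"cohort_config"} (a validated list).
#' @export
cohort_config <- function(n_patients, seed = 1L,
                          entry_age_range = c(30L, 79L),
                          follow_up_years = c(10, 20),
                          visits_per_year = 1.5,
                          archetype_mix = NULL,
                          archetype_persistence = 0.7,
                          frac_non_e11 = 0, frac_o24 = 0,
                          frac_short_text = 0, frac_sparse = 0,
                          frac_under30 = 0,
                          start_year_range = c(1997L, 2003L)) {
  stopifnot(
    is.numeric(n_patients), length(n_patients) == 1L, n_patients >= 0,
    n_patients == floor(n_patients)
  )
  stopifnot(is.numeric(seed), length(seed) == 1L)
  stopifnot(
    length(entry_age_range) == 2L, entry_age_range[1] <= entry_age_range[2]
  )
  stopifnot(
    length(follow_up_years) == 2L, follow_up_years[1] > 0,
    follow_up_years[1] <= follow_up_years[2]
  )
  stopifnot(visits_per_year >= 0)
  fr <- c(frac_non_e11, frac_o24, frac_short_text, frac_sparse, frac_under30)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
    stop("decoy fractions must all be in [0, 1]", call. = FALSE)
  }
  if (sum(fr) > 1 + 1e-12) {
    stop("decoy fractions must sum to at most 1", call. = FALSE)
  }
  stopifnot(
    archetype_persistence >= 0, archetype_persistence <= 1,
    length(start_year_range) == 2L
  )
  if (!is.null(archetype_mix)) {
    if (!is.matrix(archetype_mix) || is.null(rownames(archetype_mix)) ||
      is.null(colnames(archetype_mix))) {
      stop("archetype_mix must be a matrix with age-group rownames and ",
        "archetype colnames",
        call. = FALSE
      )
    }
    if (any(archetype_mix < 0) ||
      any(abs(rowSums(archetype_mix) - 1) > 1e-8)) {
      stop("archetype_mix rows must be nonnegative and sum to 1",
        call. = FALSE
      )
    }
    if (!all(rownames(archetype_mix) %in% age_group_labels())) {
      stop("archetype_mix rownames must be 10-year age-group labels",
        call. = FALSE
      )
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      entry_age_range = as.integer(entry_age_range),
      follow_up_years = as.numeric(follow_up_years),
      visits_per_year = visits_per_year,
      archetype_mix = archetype_mix,
      archetype_persistence = archetype_persistence,
      frac_non_e11 = frac_non_e11, frac_o24 = frac_o24,
      frac_short_text = frac_short_text, frac_sparse = frac_sparse,
      frac_under30 = frac_under30,
      start_year_range = as.integer(start_year_range)
    ),
    class = "cohort_config"
  )
}

.lab_analytes <- c("glucose", "cholesterol", "triglycerides", "egfr")

#' Draw synthetic laboratory values
#'
#' Gaussian values around analyte-specific means (glucose 8.0 +/- 1.8
#' mmol/L, total cholesterol 5.0 +/- 1.0 mmol/L, triglycerides 2.0 +/- 0.7
#' mmol/L, eGFR 12 about an age-declining mean of 100 - 0.8 * (age - 40)
#' mL/min/1.73m2), plus an additive shift (e.g. an archetype's planted
#' eGFR deficit). Values are floored at physiologic minima.
#'
#' @param analyte one of \code{"glucose"}, \code{"cholesterol"},
#'   \code{"triglycerides"}, \code{"egfr"}.
#' @param n number of values.
#' @param age age in years (scalar or length-n vector; only eGFR depends
#'   on it).
#' @param shift additive shift.
#' @return numeric vector of length \code{n}.
#' @export
draw_lab_values <- function(analyte, n, age = 60, shift = 0) {
  analyte <- match.arg(analyte, .lab_analytes)
  base <- switch(analyte,
    glucose = list(mean = 8.0, sd = 1.8, floor = 2.5),
    cholesterol = list(mean = 5.0, sd = 1.0, floor = 1.0),
    triglycerides = list(mean = 2.0, sd = 0.7, floor = 0.3),
    egfr = list(mean = 100 - 0.8 * pmax(age - 40, 0), sd = 12, floor = 5)
  )
  pmax(stats::rnorm(n, base$mean + shift, base$sd), base$floor)
}

# map each level-2 class to the level-5 codes the lexicon can surface
.lv2_options <- function(lexicon) {
  split(lexicon$atc_code, atc_truncate(lexicon$atc_code, 2))
}

#' Render a synthetic clinical note
#'
#' Produces free text embedding each medication event's surface form
#' exactly once, surrounded by filler prose that contains no lexicon
#' surface form. Regular notes are longer than 100 characters; with
#' \code{short = TRUE} a terse prescription line of at most 100 characters
#' is produced (the short-text decoy).
#'
#' @param events data frame with column \code{surface_form} (one row per
#'   medication event), or a character vector of surface forms; may be
#'   empty. If a \code{lexicon} is supplied and a row lacks a surface
#'   form, one is looked up by \code{atc_code} (an ATC code with no
#'   lexicon entry is an error naming the code).
#' @param short produce a short-text decoy note (<= 100 characters).
#' @param lexicon optional \code{\link{read_lexicon}} object for surface
#'   form lookup.
#' @return a single string.
#' @export
render_note <- function(events, short = FALSE, lexicon = NULL) {
  if (is.character(events)) {
    forms <- events
  } else if (is.null(events) || nrow(events) == 0L) {
    forms <- character(0)
  } else {
    forms <- if ("surface_form" %in% names(events)) {
      as.character(events$surface_form)
    } else {
      rep(NA_character_, nrow(events))
    }
    if (anyNA(forms)) {
      if (is.null(lexicon)) {
        stop("events lack surface forms and no lexicon was supplied",
          call. = FALSE
        )
      }
      for (i in which(is.na(forms))) {
        cand <- .lexicon_forms(lexicon, events$atc_code[i])
        if (length(cand) == 0L) {
          stop("no lexicon surface form for ATC code ", events$atc_code[i],
            call. = FALSE
          )
        }
        forms[i] <- cand[[1]]
      }
    }
  }
  doses <- c(
    "5 mg", "10 mg", "20 mg", "40 mg", "80 mg", "500 mg", "850 mg",
    "1000 mg"
  )
  therapy <- if (length(forms)) {
    paste0(
      "Current therapy: ",
      paste(paste(forms, sample(doses, length(forms), replace = TRUE)),
        collapse = ", "
      ), "."
    )
  } else {
    "No regular pharmacological therapy recorded at this visit."
  }
  if (short) {
    note <- if (length(forms)) paste0("Rp: ", forms[1], ".") else "Control."
    if (length(forms) > 1) {
      note <- paste0("Rp: ", paste(forms, collapse = ", "), ".")
    }
    return(substr(note, 1L, 100L))
  }
  openers <- c(
    "Regular follow-up visit at the diabetes outpatient clinic.",
    "Scheduled control examination in the endocrinology department.",
    "Routine review of chronic disease management today."
  )
  fillers <- c(
    "Patient reports feeling stable with no new complaints.",
    "Blood pressure acceptable at today's measurement.",
    "Dietary counselling repeated and regular physical activity encouraged.",
    "No hypoglycaemic episodes reported since the last visit.",
    "Peripheral pulses palpable, no oedema of the lower extremities.",
    "Self-monitoring diary reviewed together with the patient.",
    "Weight essentially unchanged compared with the previous control."
  )
  closers <- c(
    "Therapy continued, next control appointment in three months.",
    "Laboratory results discussed with the patient, control in six months."
  )
  note <- paste(
    sample(openers, 1), paste(sample(fillers, 2), collapse = " "),
    therapy, sample(closers, 1)
  )
  while (nchar(note) <= 100L) {
    note <- paste(note, sample(fillers, 1))
  }
  note
}

#' Generate a synthetic EMR cohort with planted medication archetypes
#'
#' Simulates patients with roughly decade-long follow-up at a hospital
#' diabetes clinic: dated visits carrying free-text notes with embedded
#' drug mentions, up to 10 ICD diagnosis codes per record, and four
#' laboratory analytes. Each patient carries a planted archetype per
#' 10-year age group which determines the level-2 classes prescribed in
#' that group (all of them at the first visit of the group, random subsets
#' afterwards), so the ground truth of every downstream stage is known
#' exactly. Decoy patients failing exactly one inclusion gate are planted
#' according to the configured fractions.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param archetypes list of \code{\link{archetype_spec}} objects; every
#'   class they use must be coverable by the lexicon.
#' @param lexicon a \code{\link{read_lexicon}} object (defaults to the
#'   packaged fixture lexicon).
#' @return object of class \code{"synthetic_cohort"}: list with
#'   \code{patients} (patient_id, sex, birth_year), \code{records} (one
#'   row per visit: record_id, patient_id, visit_date, note_text,
#'   diagnoses, lab_* columns), and \code{truth} (ground truth: decoy
#'   \code{roles}, per-age-group \code{archetypes} with their true class
#'   sets, and all planted medication \code{events}).
#' @export
generate_cohort <- function(config, archetypes = default_archetypes(),
                            lexicon = default_lexicon()) {
  stopifnot(inherits(config, "cohort_config"))
  if (length(archetypes) == 0L) {
    stop("at least one archetype is required", call. = FALSE)
  }
  if (!all(vapply(archetypes, inherits, logical(1), "archetype_spec"))) {
    stop("archetypes must be archetype_spec objects", call. = FALSE)
  }
  arch_names <- vapply(archetypes, `[[`, character(1), "name")
  if (anyDuplicated(arch_names)) {
    stop("archetype names must be unique", call. = FALSE)
  }
  names(archetypes) <- arch_names

  # archetype mix: rows for all bands, columns in archetype order
  bands <- age_group_labels()
  mix <- config$archetype_mix
  if (is.null(mix)) {
    mix <- matrix(1 / length(archetypes),
      nrow = length(bands),
      ncol = length(archetypes),
      dimnames = list(bands, arch_names)
    )
  } else {
    if (!setequal(colnames(mix), arch_names)) {
      stop("archetype_mix columns must match archetype names", call. = FALSE)
    }
    mix <- mix[, arch_names, drop = FALSE]
    missing_bands <- setdiff(bands, rownames(mix))
    if (length(missing_bands)) {
      stop("archetype_mix lacks rows for age groups: ",
        paste(missing_bands, collapse = ", "),
        call. = FALSE
      )
    }
    mix <- mix[bands, , drop = FALSE]
  }

  lv2_opts <- .lv2_options(lexicon)
  used_classes <- unique(unlist(lapply(archetypes, function(a) {
    c(a$atc_lv2_core, a$atc_lv2_optional)
  })))
  uncovered <- setdiff(used_classes, names(lv2_opts))
  if (length(uncovered)) {
    stop("no lexicon surface form for ATC class(es): ",
      paste(uncovered, collapse = ", "),
      call. = FALSE
    )
  }

  empty <- .empty_cohort(config, archetypes)
  if (config$n_patients == 0L) {
    return(empty)
  }

  set.seed(config$seed)
  roles_p <- c(
    non_e11 = config$frac_non_e11, o24 = config$frac_o24,
    short_text = config$frac_short_text, sparse = config$frac_sparse,
    under30 = config$frac_under30
  )
  roles_p <- c(roles_p, clean = 1 - sum(roles_p))
  comorb_pool <- c("I10", "I25.1", "E78.0", "K21.0", "M17.1", "N18.3", "H52.4")

  pat_rows <- vector("list", config$n_patients)
  rec_rows <- vector("list", config$n_patients)
  ev_rows <- vector("list", config$n_patients)
  arch_rows <- vector("list", config$n_patients)

  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%05d", i)
    role <- sample(names(roles_p), 1L, prob = roles_p)
    sex <- sample(c("F", "M"), 1L)

    entry_age <- if (role == "under30") {
      sample(22:28, 1L)
    } else {
      sample(config$entry_age_range[1]:config$entry_age_range[2], 1L)
    }
    start_year <- sample(
      config$start_year_range[1]:config$start_year_range[2], 1L
    )
    start_date <- as.Date(sprintf("%d-01-01", start_year)) +
      sample(0:364, 1L)
    birth_year <- start_year - entry_age
    fu_years <- stats::runif(1, config$follow_up_years[1],
      config$follow_up_years[2])

    if (role == "sparse") {
      n_vis <- sample(3:9, 1L)
      offsets <- sort(round(stats::runif(n_vis, 0, fu_years * 365.25)))
    } else {
      # ten visits inside the first 9.4 years guarantee the 10-in-10-years
      # window gate is passed; extras arrive at the configured rate
      anchors <- stats::runif(10, 0, 9.4 * 365.25)
      extras <- stats::runif(
        stats::rpois(1, config$visits_per_year * fu_years),
        0, fu_years * 365.25
      )
      offsets <- sort(round(c(anchors, extras)))
    }
    dates <- start_date + offsets
    ages <- as.integer(format(dates, "%Y")) - birth_year
    vis_band <- age_group_of(ages) # NA below 30

    # archetype per age group: first group drawn from its mix, later
    # groups kept with the persistence probability, else redrawn
    bands_seq <- unique(vis_band[!is.na(vis_band)])
    if (length(bands_seq) == 0L) bands_seq <- bands[1]
    band_arch <- character(length(bands_seq))
    names(band_arch) <- bands_seq
    for (b in seq_along(bands_seq)) {
      row <- mix[bands_seq[b], ]
      if (sum(row) == 0) row[] <- 1 / length(row)
      if (b == 1L ||
        stats::runif(1) >= config$archetype_persistence) {
        band_arch[b] <- sample(arch_names, 1L, prob = row)
      } else {
        band_arch[b] <- band_arch[b - 1L]
      }
    }

    # per age group: realized class set and one level-5 drug per class
    band_classes <- list()
    band_drugs <- list()
    for (b in bands_seq) {
      a <- archetypes[[band_arch[[b]]]]
      opt_on <- a$atc_lv2_optional[
        stats::runif(length(a$atc_lv2_optional)) < a$p_opt
      ]
      cls <- sort(c(a$atc_lv2_core, opt_on))
      band_classes[[b]] <- cls
      band_drugs[[b]] <- vapply(cls, function(cl) {
        cands <- lv2_opts[[cl]]
        cands[sample.int(length(cands), 1L)]
      }, character(1))
    }

    # diagnoses by role
    base_diag <- function() {
      e11 <- sample(c("E11", "E11.2", "E11.5", "E11.9"), 1L)
      extra <- sample(comorb_pool, sample(0:3, 1L))
      paste(c(e11, extra), collapse = ";")
    }
    lab_shift <- function(b, an) {
      sh <- archetypes[[band_arch[[b]]]]$lab_shift
      if (an %in% names(sh)) sh[[an]] else 0
    }

    nrec <- length(dates)
    note <- character(nrec)
    diag <- character(nrec)
    labg <- labc <- labt <- labe <- numeric(nrec)
    rec_ids <- sprintf("%s-%03d", pid, seq_len(nrec))
    seen_band <- character(0)
    p_events <- vector("list", nrec)

    for (j in seq_len(nrec)) {
      b <- vis_band[j]
      key <- if (is.na(b)) bands_seq[1] else b
      cls <- band_classes[[key]]
      drugs <- band_drugs[[key]]
      first_of_band <- !is.na(b) && !(b %in% seen_band)
      if (first_of_band) seen_band <- c(seen_band, b)
      take <- if (role == "short_text") {
        cls[sample.int(length(cls), 1L)]
      } else if (first_of_band) {
        cls
      } else {
        n_take <- max(1L, stats::rbinom(1L, length(cls), 0.35))
        sort(cls[sample.int(length(cls), n_take)])
      }
      atc5 <- unname(drugs[take])
      forms <- vapply(atc5, function(code) {
        cand <- .lexicon_forms(lexicon, code)
        cand[sample.int(length(cand), 1L)]
      }, character(1))
      note[j] <- render_note(forms, short = (role == "short_text"))
      diag[j] <- switch(role,
        non_e11 = paste(sample(comorb_pool, sample(2:4, 1L)),
          collapse = ";"
        ),
        o24 = paste(c("O24.4", base_diag()), collapse = ";"),
        base_diag()
      )
      labg[j] <- draw_lab_values("glucose", 1,
        age = ages[j],
        shift = lab_shift(key, "glucose")
      )
      labc[j] <- draw_lab_values("cholesterol", 1,
        age = ages[j],
        shift = lab_shift(key, "cholesterol")
      )
      labt[j] <- draw_lab_values("triglycerides", 1,
        age = ages[j],
        shift = lab_shift(key, "triglycerides")
      )
      labe[j] <- draw_lab_values("egfr", 1,
        age = ages[j],
        shift = lab_shift(key, "egfr")
      )
      if (length(atc5)) {
        p_events[[j]] <- data.frame(
          record_id = rec_ids[j], patient_id = pid,
          visit_date = dates[j], atc_code = atc5, surface_form = forms,
          stringsAsFactors = FALSE
        )
      }
    }

    pat_rows[[i]] <- data.frame(
      patient_id = pid, sex = sex, birth_year = birth_year, role = role,
      stringsAsFactors = FALSE
    )
    rec_rows[[i]] <- data.frame(
      record_id = rec_ids, patient_id = pid, visit_date = dates,
      note_text = note, diagnoses = diag,
      lab_glucose = round(labg, 2), lab_cholesterol = round(labc, 2),
      lab_triglycerides = round(labt, 2), lab_egfr = round(labe, 1),
      stringsAsFactors = FALSE
    )
    ev_rows[[i]] <- do.call(rbind, p_events)
    arch_rows[[i]] <- data.frame(
      patient_id = pid, age_group = bands_seq,
      archetype = unname(band_arch[bands_seq]),
      classes = vapply(bands_seq, function(b) {
        paste(band_classes[[b]], collapse = ";")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }

  patients <- do.call(rbind, pat_rows)
  truth <- list(
    roles = patients[, c("patient_id", "role")],
    archetypes = do.call(rbind, arch_rows),
    events = do.call(rbind, ev_rows)
  )
  rownames(truth$archetypes) <- NULL
  rownames(truth$events) <- NULL
  structure(
    list(
      patients = patients[, c("patient_id", "sex", "birth_year")],
      records = do.call(rbind, rec_rows),
      truth = truth, config = config, archetypes = archetypes
    ),
    class = "synthetic_cohort"
  )
}

.empty_cohort <- function(config, archetypes) {
  structure(
    list(
      patients = data.frame(
        patient_id = character(0), sex = character(0),
        birth_year = integer(0), stringsAsFactors = FALSE
      ),
      records = data.frame(
        record_id = character(0), patient_id = character(0),
        visit_date = as.Date(character(0)), note_text = character(0),
        diagnoses = character(0), lab_glucose = numeric(0),
        lab_cholesterol = numeric(0), lab_triglycerides = numeric(0),
        lab_egfr = numeric(0), stringsAsFactors = FALSE
      ),
      truth = list(
        roles = data.frame(
          patient_id = character(0), role = character(0),
          stringsAsFactors = FALSE
        ),
        archetypes = data.frame(
          patient_id = character(0), age_group = character(0),
          archetype = character(0), classes = character(0),
          stringsAsFactors = FALSE
        ),
        events = data.frame(
          record_id = character(0), patient_id = character(0),
          visit_date = as.Date(character(0)), atc_code = character(0),
          surface_form = character(0), stringsAsFactors = FALSE
        )
      ),
      config = config, archetypes = archetypes
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$patients), " patients, ",
    nrow(x$records), " records, ", nrow(x$truth$events),
    " planted medication events (seed ", x$config$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Patients and records as UTF-8 CSV with header rows, ground truth as
#' JSON.
#'
#' @param cohort a \code{"synthetic_cohort"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    patients = file.path(dir, "patients.csv"),
    records = file.path(dir, "records.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  utils::write.csv(cohort$patients, paths["patients"], row.names = FALSE)
  utils::write.csv(cohort$records, paths["records"], row.names = FALSE)
  jsonlite::write_json(
    lapply(cohort$truth, function(x) x),
    paths["truth"],
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Study configuration for planted-cluster recovery experiments
#'
#' A cohort configuration pairing \code{\link{planted_archetypes}} with a
#' uniform archetype mix, frozen archetypes per patient
#' (\code{archetype_persistence = 1}), entry ages 40-69 and 10-15 year
#' follow-up, so each interior age group accumulates well over 100
#' profiles at moderate cohort sizes.
#'
#' @param k number of planted archetypes (2-5).
#' @param n_patients cohort size.
#' @param seed RNG seed.
#' @return a \code{\link{cohort_config}}.
#' @export
planted_cohort_config <- function(k, n_patients, seed) {
  arch <- planted_archetypes(k)
  nm <- vapply(arch, `[[`, character(1), "name")
  mix <- matrix(1 / k,
    nrow = length(age_group_labels()), ncol = k,
    dimnames = list(age_group_labels(), nm)
  )
  cohort_config(n_patients,
    seed = seed,
    entry_age_range = c(40L, 69L), follow_up_years = c(10, 15),
    visits_per_year = 0.3, archetype_mix = mix,
    archetype_persistence = 1
  )
}

#' Calibrated cut height for planted-cluster recovery
#'
#' Ward merge heights grow with the square root of cluster size, so the
#' height separating within-archetype from between-archetype merges
#' depends on how many archetypes share an age group: with the
#' \code{\link{planted_cohort_config}} group sizes (about 130-350
#' profiles), within-archetype merges top out near 6.5 while the lowest
#' between-archetype merge is about 11 for five archetypes and higher for
#' fewer. These cuts sit in that gap, calibrated once per archetype count
#' and frozen.
#'
#' @param k number of planted archetypes (2-5).
#' @return the cut height.
#' @export
planted_threshold <- function(k) {
  stopifnot(k >= 2, k <= 5)
  c(`2` = 12, `3` = 10, `4` = 9, `5` = 8)[[as.character(k)]]
}
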