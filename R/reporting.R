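#' ATC usage frequency per age group
#'
#' The share of patients in each age group prescribed at least one drug
#' of each ATC class at the chosen level. Shares count patients, not
#' records: a class counts once per patient per age group. Classes are
#' ranked by overall patient share (the fraction of all patient x group
#' memberships carrying the class) and the table is truncated to the
#' \code{top_k} highest-ranked classes.
#'
#' @param timelines filtered \code{"patient_timelines"}.
#' @param membership \code{\link{age_group_membership}} rows (computed if
#'   \code{NULL}).
#' @param level ATC level: 1, 2 or 4.
#' @param top_k number of classes to keep (default 10).
#' @return object of class \code{"usage_table"}: data frame with
#'   \code{atc_class}, \code{overall}, then one share column per age
#'   group present.
#' @export
usage_frequency <- function(timelines, membership = NULL, level = 1,
                            top_k = 10) {
  stopifnot(inherits(timelines, "patient_timelines"))
  if (!level %in% c(1, 2, 4)) {
    stop("level must be 1, 2 or 4", call. = FALSE)
  }
  if (is.null(membership)) membership <- age_group_membership(timelines)
  ev <- timelines$events
  ev <- ev[ev$record_id %in% membership$record_id, , drop = FALSE]
  ev$age_group <- membership$age_group[
    match(ev$record_id, membership$record_id)
  ]
  ev$cls <- atc_truncate(ev$atc_code, level)
  groups <- intersect(age_group_labels(), unique(membership$age_group))
  denom <- vapply(groups, function(g) {
    length(unique(membership$patient_id[membership$age_group == g]))
  }, numeric(1))
  classes <- sort(unique(ev$cls))
  share <- sapply(groups, function(g) {
    sub <- ev[ev$age_group == g, , drop = FALSE]
    vapply(classes, function(cl) {
      length(unique(sub$patient_id[sub$cls == cl])) / denom[[g]]
    }, numeric(1))
  })
  share <- matrix(share,
    nrow = length(classes),
    dimnames = list(classes, groups)
  )
  pg <- unique(membership[, c("patient_id", "age_group")])
  overall <- vapply(classes, function(cl) {
    hit <- unique(ev[ev$cls == cl, c("patient_id", "age_group")])
    nrow(hit) / nrow(pg)
  }, numeric(1))
  ord <- order(-overall, classes)
  keep <- ord[seq_len(min(top_k, length(classes)))]
  out <- data.frame(
    atc_class = classes[keep], overall = overall[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- cbind(out, as.data.frame(share[keep, , drop = FALSE],
    row.names = NULL
  ))
  attr(out, "level") <- level
  attr(out, "top_k") <- top_k
  class(out) <- c("usage_table", "data.frame")
  out
}

#' Medication-diversity statistics per age group
#'
#' Order statistics of the number of distinct level-2 classes per patient
#' profile in each age group (the quantities behind diversity boxplots:
#' median, quartiles, 5th/95th percentiles, mean), together with patient
#' and cluster counts.
#'
#' @param profiles a \code{"medication_profiles"}.
#' @param solutions optional named list of \code{"cluster_solution"}
#'   objects supplying per-group cluster counts.
#' @return data frame with one row per age group.
#' @export
diversity_stats <- function(profiles, solutions = NULL) {
  stopifnot(inherits(profiles, "medication_profiles"))
  info <- profiles$info
  groups <- intersect(age_group_labels(), unique(info$age_group))
  rows <- lapply(groups, function(g) {
    nd <- info$n_distinct[info$age_group == g]
    if (length(nd) == 0L) {
      warning("age group ", g, " has no profiles; omitted")
      return(NULL)
    }
    q <- stats::quantile(nd, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    data.frame(
      age_group = g, n_patients = length(nd),
      n_clusters = if (!is.null(solutions) && g %in% names(solutions)) {
        n_clusters(solutions[[g]])
      } else {
        NA_integer_
      },
      mean = mean(nd), p5 = q[1], q1 = q[2], median = q[3], q3 = q[4],
      p95 = q[5], stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cluster prescription frequencies and branch diversity
#'
#' For a labeled cluster solution: the share of cluster members
#' prescribed each ATC level-2 class (truncated to the \code{top_k}
#' classes by overall share), and the mean number of distinct level-2
#' classes per level-1 branch for an average member of each cluster.
#'
#' @param solution a labeled \code{"cluster_solution"}.
#' @param profiles the matching \code{"medication_profiles"} (binary
#'   mode).
#' @param top_k number of level-2 classes in the share table (default
#'   14).
#' @return list with \code{shares} (data frame cluster x class shares)
#'   and \code{lv1_diversity} (data frame cluster x level-1 branch mean
#'   distinct level-2 count).
#' @export
cluster_prescription_frequency <- function(solution, profiles, top_k = 14) {
  stopifnot(
    inherits(solution, "cluster_solution"), isTRUE(solution$labeled),
    inherits(profiles, "medication_profiles")
  )
  mat <- profiles$matrix > 0
  vocab <- profiles$vocabulary
  labs <- names(solution$clusters)
  share_mat <- t(vapply(solution$clusters, function(cl) {
    colMeans(mat[cl$members, , drop = FALSE])
  }, numeric(length(vocab))))
  overall <- colMeans(mat[unlist(lapply(
    solution$clusters, `[[`,
    "members"
  )), , drop = FALSE])
  keep <- order(-overall, vocab)[seq_len(min(top_k, length(vocab)))]
  shares <- data.frame(
    cluster = labs, share_mat[, keep, drop = FALSE],
    stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE
  )
  branches <- sort(unique(substr(vocab, 1, 1)))
  lv1 <- t(vapply(solution$clusters, function(cl) {
    sub <- mat[cl$members, , drop = FALSE]
    vapply(branches, function(b) {
      mean(rowSums(sub[, substr(vocab, 1, 1) == b, drop = FALSE]))
    }, numeric(1))
  }, numeric(length(branches))))
  lv1_diversity <- data.frame(
    cluster = labs, lv1,
    stringsAsFactors = FALSE, row.names = NULL, check.names = FALSE
  )
  list(shares = shares, lv1_diversity = lv1_diversity)
}

#' Compare a laboratory analyte's distribution across clusters
#'
#' A k-sample location test (Kruskal-Wallis by default, one-way ANOVA
#' optionally) of one analyte across the clusters of one labeled
#' solution, with per-cluster summaries. Clusters contribute their
#' members' non-missing values; the row is omitted (with a warning) when
#' fewer than two clusters have at least two values.
#'
#' @param labs data frame with columns \code{patient_id}, \code{analyte},
#'   \code{value} (long format), or a record table carrying
#'   \code{lab_<analyte>} columns.
#' @param solution a labeled \code{"cluster_solution"}.
#' @param analyte analyte name, e.g. \code{"egfr"}.
#' @param test \code{"kruskal"} (default) or \code{"anova"}.
#' @return \code{NULL} if insufficient data; otherwise a one-row data
#'   frame with \code{analyte}, \code{age_group}, \code{test},
#'   \code{statistic}, \code{p_value}, plus a \code{"summaries"}
#'   attribute (per-cluster n, median, IQR).
#' @export
lab_distribution_compare <- function(labs, solution, analyte,
                                     test = c("kruskal", "anova")) {
  test <- match.arg(test)
  stopifnot(
    inherits(solution, "cluster_solution"),
    isTRUE(solution$labeled)
  )
  labs <- as.data.frame(labs, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "analyte", "value") %in% names(labs))) {
    col <- paste0("lab_", analyte)
    if (!col %in% names(labs)) {
      stop("labs must be long format (patient_id, analyte, value) or ",
        "carry a ", col, " column",
        call. = FALSE
      )
    }
    labs <- data.frame(
      patient_id = labs$patient_id, analyte = analyte,
      value = labs[[col]], stringsAsFactors = FALSE
    )
  }
  labs <- labs[labs$analyte == analyte & !is.na(labs$value), , drop = FALSE]
  pid <- vapply(
    strsplit(names(solution$assignment), "|", fixed = TRUE),
    `[[`, character(1), 1L
  )
  cl_of <- stats::setNames(unname(solution$assignment), pid)
  labs$cluster <- cl_of[labs$patient_id]
  labs <- labs[!is.na(labs$cluster), , drop = FALSE]
  sizes <- table(labs$cluster)
  if (sum(sizes >= 2L) < 2L) {
    warning(
      "fewer than two clusters with two or more ", analyte,
      " values; comparison omitted"
    )
    return(NULL)
  }
  labs <- labs[labs$cluster %in% names(sizes)[sizes >= 2L], , drop = FALSE]
  g <- factor(labs$cluster)
  if (test == "kruskal") {
    fit <- stats::kruskal.test(labs$value, g)
    statistic <- unname(fit$statistic)
    p <- fit$p.value
  } else {
    fit <- stats::aov(value ~ cluster, data = labs)
    s <- summary(fit)[[1]]
    statistic <- s[["F value"]][1]
    p <- s[["Pr(>F)"]][1]
  }
  out <- data.frame(
    analyte = analyte,
    age_group = solution$age_group %||% NA_character_,
    test = test, statistic = statistic, p_value = p,
    stringsAsFactors = FALSE
  )
  attr(out, "summaries") <- do.call(rbind, lapply(levels(g), function(cl) {
    v <- labs$value[labs$cluster == cl]
    data.frame(
      cluster = cl, n = length(v), median = stats::median(v),
      iqr = stats::IQR(v), stringsAsFactors = FALSE
    )
  }))
  out
}

#' Lab comparisons for every analyte and age group
#'
#' Convenience wrapper running \code{\link{lab_distribution_compare}} for
#' each analyte across each age group's solution, with an optional
#' Benjamini-Hochberg correction over the collected p-values (off by
#' default; the adjustment setting is recorded in the output).
#'
#' @param timelines filtered \code{"patient_timelines"} whose records
#'   carry \code{lab_*} columns.
#' @param solutions named list of labeled solutions per age group.
#' @param membership \code{\link{age_group_membership}} rows (computed if
#'   \code{NULL}); each group's comparison uses only records belonging to
#'   that age group.
#' @param analytes analyte names (default all four).
#' @param test \code{"kruskal"} or \code{"anova"}.
#' @param p_adjust \code{"none"} (default) or \code{"BH"}.
#' @return data frame with one row per analyte x age group (omissions
#'   warned), columns as in \code{\link{lab_distribution_compare}} plus
#'   \code{p_adjusted} and \code{p_adjust_method}.
#' @export
lab_compare_all <- function(timelines, solutions, membership = NULL,
                            analytes = c(
                              "glucose", "cholesterol",
                              "triglycerides", "egfr"
                            ),
                            test = c("kruskal", "anova"),
                            p_adjust = c("none", "BH")) {
  test <- match.arg(test)
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(timelines, "patient_timelines"))
  if (is.null(membership)) membership <- age_group_membership(timelines)
  rows <- list()
  for (g in names(solutions)) {
    rec_g <- timelines$records[
      timelines$records$record_id %in%
        membership$record_id[membership$age_group == g], ,
      drop = FALSE
    ]
    for (an in analytes) {
      row <- lab_distribution_compare(
        rec_g, solutions[[g]],
        an,
        test = test
      )
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    out$p_adjusted <- if (p_adjust == "BH") {
      stats::p.adjust(out$p_value, method = "BH")
    } else {
      out$p_value
    }
    out$p_adjust_method <- p_adjust
  }
  out
}
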