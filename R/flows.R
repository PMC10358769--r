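#' Build the patient-level flow graph between clusters of adjacent age
#' groups
#'
#' For each adjacent pair of age groups, every patient present in both
#' contributes one transition from their cluster in the younger group to
#' their cluster in the older group; edge weights count patients. A
#' patient first appearing in an age group with no membership in the
#' preceding one is attached to that group's new-entrant pseudo-node.
#' Node sizes therefore decompose exactly into incoming real edges plus
#' new entrants.
#'
#' @param solutions named list (age-group label -> labeled
#'   \code{"cluster_solution"}).
#' @param trace the matching \code{\link{propagate_identities}} trace
#'   (identities are copied onto the nodes).
#' @return object of class \code{"flow_graph"}: list with \code{nodes}
#'   (age_group, cluster, identity, size, mean_distinct_lv2),
#'   \code{edges} (from/to group and cluster, \code{n}, \code{type} =
#'   \code{"real"} or \code{"entrant"}) and \code{age_groups}.
#' @export
build_flow <- function(solutions, trace) {
  stopifnot(is.list(solutions), inherits(trace, "cluster_trace"))
  groups <- trace$age_groups
  solutions <- solutions[groups]

  # per group: patient -> cluster label
  member_map <- lapply(groups, function(g) {
    sol <- solutions[[g]]
    stopifnot(isTRUE(sol$labeled))
    pid <- vapply(
      strsplit(names(sol$assignment), "|", fixed = TRUE),
      `[[`, character(1), 1L
    )
    if (anyDuplicated(pid)) {
      stop("patient assigned to two clusters in one age group",
        call. = FALSE
      )
    }
    stats::setNames(unname(sol$assignment), pid)
  })
  names(member_map) <- groups

  nodes <- do.call(rbind, lapply(groups, function(g) {
    sol <- solutions[[g]]
    data.frame(
      age_group = g,
      cluster = names(sol$clusters),
      identity = unname(trace$identities[[g]][names(sol$clusters)]),
      size = vapply(sol$clusters, `[[`, numeric(1), "size"),
      mean_distinct_lv2 = vapply(
        sol$clusters, `[[`, numeric(1),
        "mean_distinct_lv2"
      ),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))

  edges <- list()
  add_edge <- function(fg, fc, tg, tc, n, type) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from_group = fg, from_cluster = fc, to_group = tg, to_cluster = tc,
      n = n, type = type, stringsAsFactors = FALSE
    )
  }
  for (k in seq_along(groups)) {
    g <- groups[k]
    cur <- member_map[[g]]
    prev <- if (k > 1L) member_map[[groups[k - 1L]]] else character(0)
    stay <- names(cur)[names(cur) %in% names(prev)]
    enter <- setdiff(names(cur), names(prev))
    if (length(stay)) {
      tab <- table(from = prev[stay], to = cur[stay])
      for (fc in rownames(tab)) {
        for (tc in colnames(tab)) {
          if (tab[fc, tc] > 0) {
            add_edge(
              groups[k - 1L], fc, g, tc, as.integer(tab[fc, tc]),
              "real"
            )
          }
        }
      }
    }
    if (length(enter)) {
      tab <- table(cur[enter])
      for (tc in names(tab)) {
        add_edge("(new)", "(new)", g, tc, as.integer(tab[[tc]]), "entrant")
      }
    }
  }
  edges <- if (length(edges)) {
    do.call(rbind, edges)
  } else {
    data.frame(
      from_group = character(0), from_cluster = character(0),
      to_group = character(0), to_cluster = character(0),
      n = integer(0), type = character(0), stringsAsFactors = FALSE
    )
  }
  structure(
    list(nodes = nodes, edges = edges, age_groups = groups),
    class = "flow_graph"
  )
}

#' @export
print.flow_graph <- function(x, ...) {
  real <- x$edges[x$edges$type == "real", , drop = FALSE]
  cat("<flow_graph> ", nrow(x$nodes), " nodes over ",
    length(x$age_groups), " age groups; ", nrow(real),
    " real edges (", sum(real$n), " transitioning patients), ",
    sum(x$edges$n[x$edges$type == "entrant"]), " new entrants\n",
    sep = ""
  )
  invisible(x)
}

#' Classify a cluster-to-cluster transition as Not Worse or Worse
#'
#' A transition is Not Worse when the patient stays in the same traced
#' profile identity, or moves to a cluster with lower or equal mean
#' medication diversity ("healthier" under the only ordering the cluster
#' labeling defines); otherwise it is Worse.
#'
#' @param source,target single-row data frames (or lists) with fields
#'   \code{identity} and \code{mean_distinct_lv2}.
#' @return \code{"NotWorse"} or \code{"Worse"}.
#' @export
classify_transition <- function(source, target) {
  same_identity <- identical(
    as.character(source$identity),
    as.character(target$identity)
  )
  if (same_identity ||
    target$mean_distinct_lv2 <= source$mean_distinct_lv2) {
    "NotWorse"
  } else {
    "Worse"
  }
}

#' Not-Worse/Worse transition statistics per adjacent age-group pair
#'
#' Tallies the classification of every transitioning patient and reports
#' the odds of worsening, \code{n_worse / n_not_worse}. The odds here are
#' a direct count ratio, not a fitted regression;
#' \code{method = "logistic"} instead fits a logistic model of worsening
#' on the source age group and reports the fitted per-group odds. Pairs
#' with no transitioning patients are omitted with a warning.
#'
#' @param flow a \code{\link{build_flow}} graph.
#' @param method \code{"odds"} (default) or \code{"logistic"}.
#' @return data frame of class \code{"transition_stats"} with one row per
#'   adjacent pair: \code{from_group}, \code{to_group},
#'   \code{n_not_worse}, \code{n_worse}, \code{odds} (\code{Inf} flagged
#'   via \code{odds_infinite}), \code{proportion_worse}, \code{method}.
#' @export
transition_odds <- function(flow, method = c("odds", "logistic")) {
  method <- match.arg(method)
  stopifnot(inherits(flow, "flow_graph"))
  real <- flow$edges[flow$edges$type == "real", , drop = FALSE]
  node_key <- paste(flow$nodes$age_group, flow$nodes$cluster, sep = "|")
  groups <- flow$age_groups
  rows <- list()
  if (length(groups) >= 2L) {
    for (k in seq_len(length(groups) - 1L)) {
      gy <- groups[k]
      go <- groups[k + 1L]
      e <- real[real$from_group == gy & real$to_group == go, , drop = FALSE]
      if (nrow(e) == 0L) {
        warning("no transitioning patients between ", gy, " and ", go)
        next
      }
      src <- flow$nodes[
        match(paste(gy, e$from_cluster, sep = "|"), node_key), ,
        drop = FALSE
      ]
      tgt <- flow$nodes[
        match(paste(go, e$to_cluster, sep = "|"), node_key), ,
        drop = FALSE
      ]
      cls <- vapply(
        seq_len(nrow(e)),
        function(i) classify_transition(src[i, ], tgt[i, ]),
        character(1)
      )
      n_nw <- sum(e$n[cls == "NotWorse"])
      n_w <- sum(e$n[cls == "Worse"])
      rows[[length(rows) + 1L]] <- data.frame(
        from_group = gy, to_group = go,
        n_not_worse = n_nw, n_worse = n_w,
        odds = if (n_nw == 0) Inf else n_w / n_nw,
        odds_infinite = n_nw == 0,
        proportion_worse = n_w / (n_nw + n_w),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      from_group = character(0), to_group = character(0),
      n_not_worse = integer(0), n_worse = integer(0), odds = numeric(0),
      odds_infinite = logical(0), proportion_worse = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  if (method == "logistic" && nrow(out) > 1) {
    fit <- stats::glm(
      cbind(n_worse, n_not_worse) ~ 0 + from_group,
      family = stats::binomial(), data = out
    )
    out$odds <- unname(exp(stats::coef(fit)))
    out$odds_infinite <- !is.finite(out$odds)
  }
  # with a single pair the saturated logistic fit equals the count odds
  out$method <- method
  class(out) <- c("transition_stats", "data.frame")
  out
}

#' @export
print.transition_stats <- function(x, ...) {
  cat("<transition_stats> (", x$method[1], " mode)\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Write a flow graph as Sankey-ready CSV tables
#'
#' Writes a link table (source, target, value) and a node table.
#'
#' @param flow a \code{"flow_graph"}.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_flow <- function(flow, dir) {
  stopifnot(inherits(flow, "flow_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  links <- data.frame(
    source = paste(flow$edges$from_group, flow$edges$from_cluster),
    target = paste(flow$edges$to_group, flow$edges$to_cluster),
    value = flow$edges$n, type = flow$edges$type,
    stringsAsFactors = FALSE
  )
  paths <- c(
    links = file.path(dir, "sankey_links.csv"),
    nodes = file.path(dir, "sankey_nodes.csv")
  )
  utils::write.csv(links, paths["links"], row.names = FALSE)
  utils::write.csv(flow$nodes, paths["nodes"], row.names = FALSE)
  invisible(paths)
}
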