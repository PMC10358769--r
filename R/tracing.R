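#' Distance matrix between cluster centroids of adjacent age groups
#'
#' Entry (i, j) is the distance between the centroid (mean profile
#' vector) of cluster i of the younger group and cluster j of the older
#' group. Both solutions must have been built over the same frozen
#' vocabulary.
#'
#' @param solution_younger,solution_older labeled
#'   \code{"cluster_solution"} objects.
#' @param metric \code{"euclidean"} (default) or \code{"manhattan"}.
#' @return numeric matrix with younger cluster labels as rownames and
#'   older cluster labels as colnames.
#' @export
cross_distance <- function(solution_younger, solution_older,
                           metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  stopifnot(
    inherits(solution_younger, "cluster_solution"),
    isTRUE(solution_younger$labeled),
    inherits(solution_older, "cluster_solution"),
    isTRUE(solution_older$labeled)
  )
  cy <- t(vapply(
    solution_younger$clusters, `[[`,
    numeric(length(solution_younger$clusters[[1]]$centroid)), "centroid"
  ))
  co <- t(vapply(
    solution_older$clusters, `[[`,
    numeric(length(solution_older$clusters[[1]]$centroid)), "centroid"
  ))
  if (!identical(colnames(cy), colnames(co))) {
    stop("cluster solutions do not share one profile vocabulary",
      call. = FALSE
    )
  }
  full <- as.matrix(stats::dist(rbind(cy, co), method = metric))
  d <- full[seq_len(nrow(cy)), nrow(cy) + seq_len(nrow(co)), drop = FALSE]
  dimnames(d) <- list(rownames(cy), rownames(co))
  d
}

#' Greedy one-to-one linking of clusters across adjacent age groups
#'
#' Repeatedly accepts the globally smallest remaining entry of the cross
#' distance matrix whose row (younger cluster) and column (older cluster)
#' are both still unmatched, until rows or columns are exhausted. Ties
#' are broken toward the lexicographically smallest (younger, older)
#' label pair. The resulting primary links form a partial bijection: each
#' cluster has at most one outgoing and one incoming primary link. For
#' every matched younger cluster, its second-nearest older cluster is
#' reported as a secondary ("gray") link — context only, never carrying
#' identity. Older clusters left unmatched are flagged for a new
#' identity.
#'
#' @param d cross distance matrix from \code{\link{cross_distance}}.
#' @return list with \code{primary} (data frame: \code{younger},
#'   \code{older}, \code{distance}), \code{secondary} (same shape) and
#'   \code{new_older} (labels of unmatched older clusters).
#' @export
link_clusters <- function(d) {
  empty <- data.frame(
    younger = character(0), older = character(0),
    distance = numeric(0), stringsAsFactors = FALSE
  )
  if (length(d) == 0L) {
    return(list(
      primary = empty, secondary = empty,
      new_older = colnames(d) %||% character(0)
    ))
  }
  stopifnot(is.matrix(d), all(is.finite(d)))
  rn <- rownames(d)
  cn <- colnames(d)
  cells <- expand.grid(i = seq_along(rn), j = seq_along(cn))
  cells$dist <- d[cbind(cells$i, cells$j)]
  cells <- cells[order(cells$dist, rn[cells$i], cn[cells$j]), , drop = FALSE]
  row_free <- rep(TRUE, length(rn))
  col_free <- rep(TRUE, length(cn))
  picks <- list()
  for (k in seq_len(nrow(cells))) {
    i <- cells$i[k]
    j <- cells$j[k]
    if (row_free[i] && col_free[j]) {
      row_free[i] <- FALSE
      col_free[j] <- FALSE
      picks[[length(picks) + 1L]] <- data.frame(
        younger = rn[i], older = cn[j], distance = cells$dist[k],
        stringsAsFactors = FALSE
      )
      if (!any(row_free) || !any(col_free)) break
    }
  }
  primary <- if (length(picks)) do.call(rbind, picks) else empty
  secondary <- empty
  if (length(cn) >= 2L && nrow(primary) > 0) {
    sec <- lapply(primary$younger, function(y) {
      i <- match(y, rn)
      ord <- order(d[i, ], cn)
      data.frame(
        younger = y, older = cn[ord[2L]], distance = d[i, ord[2L]],
        stringsAsFactors = FALSE
      )
    })
    secondary <- do.call(rbind, sec)
  }
  list(
    primary = primary, secondary = secondary,
    new_older = setdiff(cn, primary$older)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trace cluster identities across age groups
#'
#' Runs \code{\link{cross_distance}} and \code{\link{link_clusters}} over
#' every adjacent pair of age groups in ascending order and propagates
#' profile-type identities along the primary links: the youngest group's
#' clusters seed one identity each, a linked older cluster inherits its
#' younger partner's identity, and an unlinked older cluster opens a new
#' identity. Identity tokens are \code{"<seed group>:<seed label>"}, so
#' they are stable across runs.
#'
#' @param solutions named list of labeled \code{"cluster_solution"}
#'   objects, names being age-group labels; ordered or orderable by
#'   \code{\link{age_group_labels}}.
#' @param metric centroid metric, see \code{\link{cross_distance}}.
#' @return object of class \code{"cluster_trace"}: list with
#'   \code{age_groups}, \code{pairs} (per adjacent pair: \code{d},
#'   \code{primary}, \code{secondary}, \code{new_older}),
#'   \code{identities} (per age group: named character vector label ->
#'   identity) and \code{new_identities} (data frame of identity
#'   introductions beyond the youngest group).
#' @export
propagate_identities <- function(solutions,
                                 metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  stopifnot(is.list(solutions), length(solutions) >= 1L)
  groups <- intersect(age_group_labels(), names(solutions))
  if (length(groups) != length(solutions)) {
    stop("solutions must be named by 10-year age-group labels",
      call. = FALSE
    )
  }
  solutions <- solutions[groups]

  identities <- list()
  first <- solutions[[1L]]
  identities[[groups[1L]]] <- stats::setNames(
    paste0(groups[1L], ":", names(first$clusters)),
    names(first$clusters)
  )
  pairs <- list()
  introductions <- list()
  if (length(groups) >= 2L) {
    for (k in seq_len(length(groups) - 1L)) {
      gy <- groups[k]
      go <- groups[k + 1L]
      d <- cross_distance(solutions[[gy]], solutions[[go]], metric)
      links <- link_clusters(d)
      ids <- stats::setNames(
        character(length(solutions[[go]]$clusters)),
        names(solutions[[go]]$clusters)
      )
      if (nrow(links$primary)) {
        ids[links$primary$older] <-
          identities[[gy]][links$primary$younger]
      }
      for (lab in links$new_older) {
        ids[lab] <- paste0(go, ":", lab)
        introductions[[length(introductions) + 1L]] <- data.frame(
          age_group = go, cluster = lab, identity = ids[lab],
          stringsAsFactors = FALSE
        )
      }
      identities[[go]] <- ids
      pairs[[paste(gy, go, sep = " -> ")]] <- c(list(d = d), links)
    }
  }
  structure(
    list(
      age_groups = groups, pairs = pairs, identities = identities,
      new_identities = if (length(introductions)) {
        do.call(rbind, introductions)
      } else {
        data.frame(
          age_group = character(0), cluster = character(0),
          identity = character(0), stringsAsFactors = FALSE
        )
      },
      metric = metric
    ),
    class = "cluster_trace"
  )
}

#' @export
print.cluster_trace <- function(x, ...) {
  cat("<cluster_trace> ", length(x$age_groups), " age groups, ",
    sum(vapply(x$identities, length, integer(1))), " clusters, ",
    length(unique(unlist(x$identities))), " identities (",
    nrow(x$new_identities), " introduced after the youngest group)\n",
    sep = ""
  )
  for (g in x$age_groups) {
    ids <- x$identities[[g]]
    cat(
      "  ", g, ": ",
      paste(names(ids), "=", unname(ids), collapse = ", "), "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Serialize a cluster trace to JSON
#'
#' @param trace a \code{"cluster_trace"}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cluster_trace"))
  payload <- list(
    age_groups = trace$age_groups, metric = trace$metric,
    pairs = lapply(trace$pairs, function(p) {
      list(
        distance_matrix = as.data.frame(p$d), primary = p$primary,
        secondary = p$secondary, new_older = p$new_older
      )
    }),
    identities = lapply(trace$identities, as.list),
    new_identities = trace$new_identities
  )
  jsonlite::write_json(payload, path,
    dataframe = "rows", auto_unbox = TRUE,
    digits = NA
  )
  invisible(path)
}
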