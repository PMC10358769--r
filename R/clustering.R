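#' Agglomerative clustering of medication profiles at a fixed cut height
#'
#' Builds the agglomerative merge tree for one age group's profiles and
#' cuts it at a fixed merge height: clusters are the maximal groups whose
#' internal merges all have height at most \code{threshold}, so raising
#' the threshold can only reduce the number of clusters. The default is
#' Ward linkage (on squared-Euclidean updates, heights on the distance
#' scale) with a cut at 16, the pairing under which a constant cut height
#' is comparable across age groups.
#'
#' @param dmatrix a \code{\link{build_distance_matrix}} object.
#' @param threshold positive cut height.
#' @param linkage \code{"ward"} (ward.D2), \code{"average"} or
#'   \code{"complete"}.
#' @return object of class \code{"cluster_solution"} (unlabeled): list
#'   with \code{ids}, \code{assignment} (named integer vector of cluster
#'   indices), \code{tree} (the \code{stats::hclust} object),
#'   \code{threshold}, \code{linkage}, \code{metric}, \code{age_group},
#'   \code{labeled = FALSE}.
#' @export
cluster_profiles <- function(dmatrix, threshold = 16,
                             linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(dmatrix, "profile_dist"))
  if (!all(is.finite(dmatrix$dist))) {
    stop("distance matrix contains non-finite values", call. = FALSE)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  method <- switch(linkage,
    ward = "ward.D2", average = "average", complete = "complete"
  )
  tree <- stats::hclust(dmatrix$dist, method = method)
  grp <- stats::cutree(tree, h = threshold)
  structure(
    list(
      ids = dmatrix$ids,
      assignment = stats::setNames(as.integer(grp), dmatrix$ids),
      tree = tree, threshold = threshold, linkage = linkage,
      metric = dmatrix$metric, age_group = dmatrix$age_group,
      labeled = FALSE
    ),
    class = "cluster_solution"
  )
}

#' Number of clusters in a solution
#'
#' @param solution a \code{"cluster_solution"}.
#' @return integer.
#' @export
n_clusters <- function(solution) {
  stopifnot(inherits(solution, "cluster_solution"))
  length(unique(solution$assignment))
}

#' Centroid (mean profile) of a set of members
#'
#' @param member_ids profile ids of the cluster members.
#' @param profiles a \code{"medication_profiles"}.
#' @return named numeric vector: the coordinate-wise mean of the member
#'   profile vectors.
#' @export
cluster_centroid <- function(member_ids, profiles) {
  stopifnot(inherits(profiles, "medication_profiles"))
  if (length(member_ids) == 0L) {
    stop("cannot compute the centroid of an empty cluster", call. = FALSE)
  }
  if (!all(member_ids %in% rownames(profiles$matrix))) {
    stop("unknown profile id(s) among cluster members", call. = FALSE)
  }
  colMeans(profiles$matrix[member_ids, , drop = FALSE])
}

#' Label clusters C1..Cn by ascending mean medication diversity
#'
#' Clusters are ordered by the mean number of distinct level-2 classes of
#' their members (\code{n_distinct}), the lowest-diversity cluster
#' becoming C1. Ties are broken by larger member count first, then by
#' lexicographically smallest member id, so labeling is deterministic.
#'
#' @param solution an unlabeled \code{"cluster_solution"}.
#' @param profiles the \code{"medication_profiles"} the solution was
#'   computed from.
#' @return the solution, now labeled: \code{assignment} becomes a named
#'   character vector of labels and \code{clusters} holds one entry per
#'   label with \code{members}, \code{centroid}, \code{size},
#'   \code{mean_distinct_lv2}.
#' @export
label_clusters <- function(solution, profiles) {
  stopifnot(
    inherits(solution, "cluster_solution"),
    inherits(profiles, "medication_profiles")
  )
  grp <- solution$assignment
  info <- profiles$info
  nd <- stats::setNames(info$n_distinct, info$id)[names(grp)]
  groups <- sort(unique(grp))
  meta <- data.frame(
    grp = groups,
    mean_nd = vapply(
      groups, function(g) mean(nd[grp == g]),
      numeric(1)
    ),
    size = vapply(groups, function(g) sum(grp == g), numeric(1)),
    min_id = vapply(
      groups, function(g) min(names(grp)[grp == g]),
      character(1)
    ),
    stringsAsFactors = FALSE
  )
  ord <- order(meta$mean_nd, -meta$size, meta$min_id)
  labels <- stats::setNames(
    paste0("C", seq_along(groups)),
    as.character(meta$grp[ord])
  )
  lab_assign <- stats::setNames(
    unname(labels[as.character(grp)]),
    names(grp)
  )
  clusters <- lapply(seq_along(groups), function(k) {
    g <- meta$grp[ord][k]
    members <- names(grp)[grp == g]
    list(
      label = paste0("C", k), members = members,
      size = length(members),
      centroid = cluster_centroid(members, profiles),
      mean_distinct_lv2 = mean(nd[members])
    )
  })
  names(clusters) <- vapply(clusters, `[[`, character(1), "label")
  solution$assignment <- lab_assign
  solution$clusters <- clusters
  solution$labeled <- TRUE
  solution
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution>",
    if (!is.null(x$age_group)) paste0(" [", x$age_group, "]") else "",
    " ", length(x$ids), " profiles -> ", n_clusters(x), " clusters (",
    x$linkage, " linkage, cut at ", format(x$threshold), ", ",
    x$metric, " metric)\n",
    sep = ""
  )
  if (isTRUE(x$labeled)) {
    for (cl in x$clusters) {
      cat(
        "  ", cl$label, ": n = ", cl$size, ", mean distinct LV2 = ",
        format(round(cl$mean_distinct_lv2, 2)), "\n",
        sep = ""
      )
    }
  }
  invisible(x)
}

#' Serialize a labeled cluster solution to JSON
#'
#' @param solution a labeled \code{"cluster_solution"}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_solution <- function(solution, path) {
  stopifnot(inherits(solution, "cluster_solution"), isTRUE(solution$labeled))
  payload <- list(
    age_group = solution$age_group, threshold = solution$threshold,
    linkage = solution$linkage, metric = solution$metric,
    assignment = as.list(solution$assignment),
    clusters = lapply(solution$clusters, function(cl) {
      list(
        label = cl$label, size = cl$size,
        mean_distinct_lv2 = cl$mean_distinct_lv2,
        centroid = as.list(cl$centroid), members = cl$members
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export the merge tree as Newick text
#'
#' For dendrogram inspection in standard tree viewers. Requires the ape
#' package.
#'
#' @param solution a \code{"cluster_solution"}.
#' @return a Newick string.
#' @export
solution_newick <- function(solution) {
  stopifnot(inherits(solution, "cluster_solution"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the ape package is required for Newick export", call. = FALSE)
  }
  ape::write.tree(ape::as.phylo(solution$tree))
}
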