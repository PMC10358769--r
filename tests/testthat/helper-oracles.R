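# Independent oracles, deliberately naive: a from-scratch Lance-Williams
# agglomerative clusterer and a literal simulation of the greedy
# cross-group matching rule. These never call the implementation paths
# they check.

# Naive agglomerative clustering on a distance matrix. Returns merge
# heights (in merge order) and the membership vector after each merge.
naive_agglomerative <- function(D, method = c("ward", "average", "complete")) {
  method <- match.arg(method)
  D <- as.matrix(D)
  n <- nrow(D)
  sizes <- rep(1, n)
  membership <- seq_len(n)
  active <- seq_len(n)
  d <- D
  heights <- numeric(0)
  snapshots <- list()
  while (length(active) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        a <- active[ii]
        b <- active[jj]
        if (d[a, b] < best_d) {
          best_d <- d[a, b]
          best <- c(a, b)
        }
      }
    }
    i <- best[1]
    j <- best[2]
    heights[length(heights) + 1L] <- best_d
    for (k in setdiff(active, c(i, j))) {
      dk <- switch(method,
        ward = sqrt(
          ((sizes[i] + sizes[k]) * d[k, i]^2 +
            (sizes[j] + sizes[k]) * d[k, j]^2 -
            sizes[k] * d[i, j]^2) /
            (sizes[i] + sizes[j] + sizes[k])
        ),
        average = (sizes[i] * d[k, i] + sizes[j] * d[k, j]) /
          (sizes[i] + sizes[j]),
        complete = max(d[k, i], d[k, j])
      )
      d[k, i] <- d[i, k] <- dk
    }
    sizes[i] <- sizes[i] + sizes[j]
    membership[membership == j] <- i
    active <- setdiff(active, j)
    snapshots[[length(snapshots) + 1L]] <- membership
  }
  list(heights = heights, snapshots = snapshots)
}

# partition after cutting the naive merge sequence at height h
naive_cut <- function(res, h, n) {
  m <- sum(res$heights <= h)
  if (m == 0L) {
    return(seq_len(n))
  }
  res$snapshots[[m]]
}

# are two label vectors the same set partition?
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  nlevels(interaction(a, b, drop = TRUE)) ==
    max(nlevels(factor(a)), nlevels(factor(b)))
}

# literal simulation of the greedy one-to-one matching rule, ties toward
# the lexicographically smallest (row, column) label pair
greedy_match_oracle <- function(d) {
  rn <- rownames(d)
  cn <- colnames(d)
  pairs <- list()
  repeat {
    if (length(rn) == 0L || length(cn) == 0L) break
    sub <- d[rn, cn, drop = FALSE]
    lowest <- min(sub)
    cand <- which(sub == lowest, arr.ind = TRUE)
    cand <- cand[order(rn[cand[, 1]], cn[cand[, 2]]), , drop = FALSE]
    y <- rn[cand[1, 1]]
    o <- cn[cand[1, 2]]
    pairs[[length(pairs) + 1L]] <- data.frame(
      younger = y, older = o, distance = lowest,
      stringsAsFactors = FALSE
    )
    rn <- setdiff(rn, y)
    cn <- setdiff(cn, o)
  }
  do.call(rbind, pairs)
}

# ATC-level-2 vocabulary used for handmade profile fixtures
fixture_vocab <- function() {
  sort(c(
    "A02", "A10", "B01", "C03", "C07", "C08", "C09", "C10",
    "G04", "H03", "J01", "M01", "N02", "N05", "R03", "S01"
  ))
}

# a medication_profiles object built directly from a 0/1 matrix
make_profiles <- function(mat, age_group = "50-59",
                          ids = sprintf("P%03d|%s", seq_len(nrow(mat)), age_group)) {
  vocab <- colnames(mat)
  rownames(mat) <- ids
  parts <- strsplit(ids, "|", fixed = TRUE)
  info <- data.frame(
    id = ids,
    patient_id = vapply(parts, `[[`, character(1), 1L),
    age_group = vapply(parts, `[[`, character(1), 2L),
    n_distinct = rowSums(mat > 0),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      matrix = mat, info = info, vocabulary = vocab, level = 2,
      mode = "binary"
    ),
    class = "medication_profiles"
  )
}

# binary profile matrix for k planted archetypes, n_each members per
# archetype, no optional noise
planted_matrix <- function(k, n_each, vocab = fixture_vocab()) {
  arch <- planted_archetypes(k)
  rows <- lapply(seq_len(k), function(a) {
    v <- as.numeric(vocab %in% arch[[a]]$atc_lv2_core)
    matrix(rep(v, n_each), nrow = n_each, byrow = TRUE)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- vocab
  attr(mat, "truth") <- rep(seq_len(k), each = n_each)
  mat
}

# hand-built labeled cluster solution (for tracing / flow fixtures)
make_solution <- function(age_group, members_by_label, means, centroids,
                          threshold = 16) {
  assignment <- unlist(lapply(names(members_by_label), function(lab) {
    ids <- paste(members_by_label[[lab]], age_group, sep = "|")
    stats::setNames(rep(lab, length(ids)), ids)
  }))
  clusters <- lapply(names(members_by_label), function(lab) {
    ids <- paste(members_by_label[[lab]], age_group, sep = "|")
    list(
      label = lab, members = ids, size = length(ids),
      centroid = centroids[[lab]], mean_distinct_lv2 = means[[lab]]
    )
  })
  names(clusters) <- names(members_by_label)
  structure(
    list(
      ids = names(assignment), assignment = assignment, tree = NULL,
      threshold = threshold, linkage = "ward", metric = "euclidean",
      age_group = age_group, labeled = TRUE, clusters = clusters
    ),
    class = "cluster_solution"
  )
}

# unit centroid vectors over the fixture vocabulary
unit_centroid <- function(classes, vocab = fixture_vocab()) {
  stats::setNames(as.numeric(vocab %in% classes), vocab)
}

# ground-truth archetype per patient x age group, keyed like profile ids
truth_assignments <- function(cohort) {
  tr <- cohort$truth$archetypes
  stats::setNames(
    tr$archetype,
    paste(tr$patient_id, tr$age_group, sep = "|")
  )
}

# long-format note records for hand-built cohorts; notes are padded past
# the 100-character gate and carry no lexicon surface form
make_records <- function(patient_id, dates, diagnoses = "E11.9",
                         note = NULL) {
  filler <- paste(
    "Scheduled control examination, condition stable,",
    "therapy reviewed and continued without modification today."
  )
  if (is.null(note)) note <- filler
  data.frame(
    patient_id = patient_id, visit_date = as.Date(dates),
    note_text = rep_len(note, length(dates)),
    diagnoses = rep_len(diagnoses, length(dates)),
    stringsAsFactors = FALSE
  )
}
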