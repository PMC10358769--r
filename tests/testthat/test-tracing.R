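vocab <- fixture_vocab()

# two-group fixture: clusters with unit centroids on disjoint class sets
two_group_solutions <- function(young_classes, old_classes,
                                young_group = "50-59",
                                old_group = "60-69") {
  mk <- function(group, class_sets) {
    labels <- paste0("C", seq_along(class_sets))
    members <- stats::setNames(
      lapply(seq_along(class_sets), function(i) sprintf("P%d%02d", i, 1:3)),
      labels
    )
    centroids <- stats::setNames(
      lapply(class_sets, unit_centroid), labels
    )
    means <- stats::setNames(
      vapply(class_sets, length, numeric(1)), labels
    )
    make_solution(group, members, means, centroids)
  }
  stats::setNames(
    list(mk(young_group, young_classes), mk(old_group, old_classes)),
    c(young_group, old_group)
  )
}

test_that("cross distances equal hand-computed centroid distances", {
  sols <- two_group_solutions(
    list("A10", c("A10", "C10")),
    list("A10", "C10")
  )
  d <- cross_distance(sols[[1]], sols[[2]])
  expect_equal(d["C1", "C1"], 0)
  expect_equal(d["C2", "C1"], 1) # (1,1) vs (1,0) on {A10, C10}
  expect_equal(d["C1", "C2"], sqrt(2)) # (1,0) vs (0,1)
  # full matrix equals brute-force pairwise computation
  set.seed(51)
  cy <- matrix(runif(3 * 5), 3, dimnames = list(paste0("C", 1:3), NULL))
  co <- matrix(runif(4 * 5), 4, dimnames = list(paste0("C", 1:4), NULL))
  sy <- make_solution("50-59",
    stats::setNames(lapply(1:3, function(i) sprintf("Pa%d", i)), rownames(cy)),
    stats::setNames(1:3, rownames(cy)),
    stats::setNames(asplit(cy, 1), rownames(cy))
  )
  so <- make_solution("60-69",
    stats::setNames(lapply(1:4, function(i) sprintf("Pb%d", i)), rownames(co)),
    stats::setNames(1:4, rownames(co)),
    stats::setNames(asplit(co, 1), rownames(co))
  )
  d2 <- cross_distance(sy, so)
  for (i in 1:3) {
    for (j in 1:4) {
      expect_equal(d2[i, j], sqrt(sum((cy[i, ] - co[j, ])^2)))
    }
  }
})

test_that("vocabulary mismatch between solutions is an error", {
  sols <- two_group_solutions(list("A10"), list("A10"))
  sols[[2]]$clusters$C1$centroid <-
    sols[[2]]$clusters$C1$centroid[1:8]
  expect_error(cross_distance(sols[[1]], sols[[2]]), "vocabulary")
})

test_that("greedy linking follows the documented examples", {
  d1 <- matrix(0.3, 1, 1, dimnames = list("C1", "C1"))
  l1 <- link_clusters(d1)
  expect_equal(nrow(l1$primary), 1L)
  expect_equal(nrow(l1$secondary), 0L)
  expect_equal(l1$new_older, character(0))

  d2 <- matrix(c(1, 4, 5, 2), 2, 2,
    dimnames = list(c("C1", "C2"), c("C1", "C2"))
  )
  l2 <- link_clusters(d2)
  expect_equal(l2$primary$younger, c("C1", "C2"))
  expect_equal(l2$primary$older, c("C1", "C2"))
  expect_equal(l2$primary$distance, c(1, 2))
  expect_equal(l2$secondary$older, c("C2", "C1"))

  d3 <- matrix(c(1, 9, 8, 2, 7, 6), 2, 3,
    dimnames = list(c("C1", "C2"), c("C1", "C2", "C3"))
  )
  l3 <- link_clusters(d3)
  expect_equal(nrow(l3$primary), 2L)
  expect_equal(length(l3$new_older), 1L)
})

test_that("distance ties resolve toward the smallest label pair", {
  d <- matrix(1, 2, 2, dimnames = list(c("C1", "C2"), c("C1", "C2")))
  l <- link_clusters(d)
  expect_equal(l$primary$younger, c("C1", "C2"))
  expect_equal(l$primary$older, c("C1", "C2"))
})

test_that("greedy linking equals a literal simulation on random matrices", {
  set.seed(52)
  for (rep in 1:30) {
    nr <- sample(1:4, 1)
    nc <- sample(1:4, 1)
    d <- matrix(round(runif(nr * nc), 3), nr, nc,
      dimnames = list(paste0("C", seq_len(nr)), paste0("C", seq_len(nc)))
    )
    got <- link_clusters(d)$primary
    want <- greedy_match_oracle(d)
    expect_equal(got, want, ignore_attr = TRUE)
    # partial bijection both ways
    expect_false(anyDuplicated(got$younger) > 0)
    expect_false(anyDuplicated(got$older) > 0)
  }
})

test_that("identities seed in the youngest group and propagate forward", {
  one <- two_group_solutions(list("A10", c("A10", "C10")), list("A10"))[1]
  tr1 <- propagate_identities(one)
  expect_equal(
    unname(tr1$identities[["50-59"]]),
    c("50-59:C1", "50-59:C2")
  )
  expect_equal(nrow(tr1$new_identities), 0L)

  sols <- two_group_solutions(
    list("A10", c("A10", "C10", "C09")),
    list(c("A10", "B01"), c("A10", "C10", "C09", "C07"))
  )
  tr2 <- propagate_identities(sols)
  expect_equal(nrow(tr2$new_identities), 0L)
  expect_equal(
    unname(tr2$identities[["60-69"]]),
    c("50-59:C1", "50-59:C2")
  )
})

test_that("an unmatched older cluster opens exactly one new identity", {
  sols <- two_group_solutions(
    list("A10", c("A10", "C10", "C09")),
    list("A10", c("A10", "C10", "C09"), c("N02", "N05", "M01"))
  )
  tr <- propagate_identities(sols)
  expect_equal(nrow(tr$new_identities), 1L)
  expect_equal(tr$new_identities$age_group, "60-69")
  expect_equal(tr$new_identities$identity, "60-69:C3")
  # identity count per group equals its cluster count
  for (g in tr$age_groups) {
    expect_equal(
      length(tr$identities[[g]]),
      length(sols[[g]]$clusters)
    )
  }
})

test_that("an archetype planted only from 50-59 onward opens one identity", {
  arch <- planted_archetypes(3)
  nm <- vapply(arch, `[[`, character(1), "name")
  mix <- rbind(
    "30-39" = c(0.5, 0.5, 0),
    "40-49" = c(0.5, 0.5, 0),
    "50-59" = c(1, 1, 1) / 3,
    "60-69" = c(1, 1, 1) / 3,
    "70-79" = c(1, 1, 1) / 3,
    "80+" = c(1, 1, 1) / 3
  )
  colnames(mix) <- nm
  cfg <- cohort_config(260,
    seed = 31, entry_age_range = c(40L, 59L),
    follow_up_years = c(10, 15), visits_per_year = 0.3,
    archetype_mix = mix, archetype_persistence = 1
  )
  coh <- generate_cohort(cfg, arch)
  res <- run_pipeline(coh,
    threshold = planted_threshold(3),
    min_group_size = 100
  )
  counts <- vapply(res$solutions, n_clusters, integer(1))
  expect_equal(unname(counts["40-49"]), 2L)
  expect_equal(unname(counts["50-59"]), 3L)
  intro <- res$trace$new_identities
  expect_equal(nrow(intro), 1L)
  expect_equal(intro$age_group, "50-59")
})

test_that("traces serialize to JSON", {
  sols <- two_group_solutions(
    list("A10", c("A10", "C10")),
    list("A10", c("A10", "C10"))
  )
  tr <- propagate_identities(sols)
  path <- withr::local_tempfile(fileext = ".json")
  write_trace(tr, path)
  back <- jsonlite::read_json(path)
  expect_equal(length(back$pairs), 1L)
})
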