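lex <- default_lexicon()

test_that("usage shares match brute-force counting", {
  coh <- generate_cohort(cohort_config(40, seed = 11))
  res <- run_pipeline(coh)
  tl <- res$timelines
  mem <- res$membership
  for (level in c(1, 2)) {
    tab <- usage_frequency(tl, mem, level = level, top_k = 100)
    expect_true(all(tab$overall >= 0 & tab$overall <= 1))
    ev <- tl$events[tl$events$record_id %in% mem$record_id, ]
    ev$age_group <- mem$age_group[match(ev$record_id, mem$record_id)]
    ev$cls <- atc_truncate(ev$atc_code, level)
    for (g in intersect(colnames(tab), age_group_labels())) {
      in_g <- unique(mem$patient_id[mem$age_group == g])
      for (cl in sample(tab$atc_class, min(5, nrow(tab)))) {
        brute <- length(unique(
          ev$patient_id[ev$age_group == g & ev$cls == cl]
        )) / length(in_g)
        expect_equal(tab[tab$atc_class == cl, g], brute,
          info = paste(level, g, cl)
        )
      }
    }
  }
})

test_that("antidiabetics rank first and are universal", {
  coh <- generate_cohort(cohort_config(40, seed = 11))
  res <- run_pipeline(coh)
  lv2 <- res$usage_lv2
  expect_equal(lv2$atc_class[1], "A10")
  groups <- intersect(colnames(lv2), age_group_labels())
  expect_true(all(lv2[lv2$atc_class == "A10", groups] == 1))
})

test_that("diversity statistics agree with a sort-based oracle", {
  # type-7 quantile oracle: linear interpolation on the sorted array
  q7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  mat <- rbind(
    unit_centroid("A10"),
    unit_centroid(c("A10", "C10")),
    unit_centroid(c("A10", "C10", "C09")),
    unit_centroid(c("A10", "C10", "C09", "B01")),
    unit_centroid(c("A10", "C10", "C09", "B01", "C07"))
  )
  colnames(mat) <- fixture_vocab()
  prof <- make_profiles(mat)
  st <- diversity_stats(prof)
  expect_equal(st$median, 3)
  expect_equal(st$mean, 3)
  expect_equal(st$n_patients, 5L)
  nd <- 1:5
  for (col in c(p5 = 0.05, q1 = 0.25, q3 = 0.75, p95 = 0.95)) {
    nm <- names(which(c(p5 = 0.05, q1 = 0.25, q3 = 0.75, p95 = 0.95) == col))
    expect_equal(st[[nm]], q7(nd, col))
  }
  expect_true(st$p5 <= st$q1 && st$q1 <= st$median &&
    st$median <= st$q3 && st$q3 <= st$p95)
})

test_that("identical profiles collapse the interquartile range to zero", {
  mat <- matrix(rep(unit_centroid(c("A10", "C10")), 4),
    nrow = 4,
    byrow = TRUE, dimnames = list(NULL, fixture_vocab())
  )
  st <- diversity_stats(make_profiles(mat))
  expect_equal(st$q3 - st$q1, 0)
  expect_equal(st$mean, 2)
})

test_that("singleton clusters have all-or-nothing prescription shares", {
  mat <- rbind(
    unit_centroid("A10"),
    unit_centroid(c(
      "A10", "C10", "C09", "B01", "C07", "C03", "C08",
      "A02", "N02"
    ))
  )
  colnames(mat) <- fixture_vocab()
  prof <- make_profiles(mat)
  sol <- label_clusters(
    cluster_profiles(build_distance_matrix(prof), threshold = 2), prof
  )
  freq <- cluster_prescription_frequency(sol, prof)
  share_cols <- setdiff(names(freq$shares), "cluster")
  expect_true(all(unlist(freq$shares[share_cols]) %in% c(0, 1)))
  # level-1 branch diversity: C2 takes 2 A-, 5 C-, 1 B-branch classes
  expect_equal(freq$lv1_diversity[2, "A"], 2)
  expect_equal(freq$lv1_diversity[2, "C"], 5)
  expect_equal(freq$lv1_diversity[2, "B"], 1)
  expect_equal(freq$lv1_diversity[1, "A"], 1)
})

test_that("planted cluster shares track archetype parameters", {
  coh <- generate_cohort(
    planted_cohort_config(2, 220, seed = 13),
    planted_archetypes(2)
  )
  res <- run_pipeline(coh,
    threshold = planted_threshold(2),
    min_group_size = 100
  )
  g <- names(res$solutions)[2]
  sol <- res$solutions[[g]]
  freq <- cluster_prescription_frequency(sol, res$profiles, top_k = 16)
  # core classes are prescribed to every member of their cluster
  expect_true(all(freq$shares[freq$shares$cluster == "C1", "A10"] == 1))
  # the optional class of the low archetype appears at about p_opt
  arch <- planted_archetypes(2)
  p_opt <- arch[[1]]$p_opt
  got <- freq$shares[freq$shares$cluster == "C1", "C10"]
  n1 <- sol$clusters$C1$size
  expect_lt(abs(got - p_opt), 3 * sqrt(p_opt * (1 - p_opt) / n1) + 1e-9)
})

test_that("lab comparisons need two populated clusters", {
  mat <- matrix(rep(unit_centroid("A10"), 3),
    nrow = 3, byrow = TRUE,
    dimnames = list(NULL, fixture_vocab())
  )
  prof <- make_profiles(mat)
  sol <- label_clusters(
    cluster_profiles(build_distance_matrix(prof), threshold = 10), prof
  )
  labs <- data.frame(
    patient_id = rep(prof$info$patient_id, 2),
    analyte = "egfr", value = rnorm(6, 90, 10)
  )
  expect_warning(
    out <- lab_distribution_compare(labs, sol, "egfr"),
    "omitted"
  )
  expect_null(out)
})

test_that("a planted eGFR deficit is detected across clusters", {
  set.seed(17)
  n <- 60
  assign_list <- list(
    C1 = sprintf("PA%02d", 1:n), C2 = sprintf("PB%02d", 1:n)
  )
  sol <- make_solution(
    "60-69", assign_list, c(C1 = 1, C2 = 9),
    list(
      C1 = unit_centroid("A10"),
      C2 = unit_centroid(c("A10", "C10", "C09"))
    )
  )
  labs <- data.frame(
    patient_id = c(assign_list$C1, assign_list$C2),
    analyte = "egfr",
    value = c(
      draw_lab_values("egfr", n, age = 65, shift = 0),
      draw_lab_values("egfr", n, age = 65, shift = -25)
    )
  )
  row <- lab_distribution_compare(labs, sol, "egfr")
  expect_lt(row$p_value, 0.01)
  summ <- attr(row, "summaries")
  expect_equal(summ$cluster, c("C1", "C2"))
  expect_lt(summ$median[2], summ$median[1])
  # ANOVA route agrees on so large an effect
  row2 <- lab_distribution_compare(labs, sol, "egfr", test = "anova")
  expect_lt(row2$p_value, 0.01)
})

test_that("cohort-level lab table collects rows with BH option", {
  coh <- generate_cohort(
    planted_cohort_config(2, 200, seed = 19),
    planted_archetypes(2)
  )
  res <- run_pipeline(coh,
    threshold = planted_threshold(2),
    min_group_size = 100
  )
  tab <- lab_compare_all(res$timelines, res$solutions,
    membership = res$membership, p_adjust = "BH"
  )
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$p_adjusted >= tab$p_value - 1e-12))
  expect_equal(unique(tab$p_adjust_method), "BH")
  # the planted eGFR gradient is the strongest signal in the table
  egfr <- tab[tab$analyte == "egfr", ]
  expect_true(all(egfr$p_value < 0.01))
})
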