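test_that("delta counting applies strict cutoffs on follow-up minus baseline", {
  b <- c(p1 = 0.10, p2 = 0.50, p3 = 0.90, p4 = 0.40)
  f <- c(p1 = 0.35, p2 = 0.50, p3 = 0.60, p4 = 0.61)
  dc <- delta_counts(b, f, 0.2)
  expect_equal(dc$n_hyper, 2L)               # +0.25 and +0.21
  expect_equal(dc$n_hypo, 1L)                # -0.30
  expect_setequal(dc$altered, c("p1", "p4", "p3"))
  # a change of exactly 0.2 does not count
  expect_equal(delta_counts(c(p = 0.4), c(p = 0.6), 0.2)$n_total, 0L)
  # identical samples: nothing altered
  expect_equal(delta_counts(b, b)$n_total, 0L)
  expect_length(delta_counts(b, b)$altered, 0L)
  # missing in either sample excludes the probe; disjoint universes error
  f2 <- f; f2["p1"] <- NA
  expect_equal(delta_counts(b, f2)$n_hyper, 1L)
  expect_error(delta_counts(c(a = 0.1), c(b = 0.1)), "no probes")
})

test_that("delta counting is antisymmetric in baseline and follow-up", {
  withr::with_seed(4, {
    for (i in 1:20) {
      v1 <- setNames(runif(200), paste0("p", 1:200))
      v2 <- setNames(runif(200), paste0("p", 1:200))
      a <- delta_counts(v1, v2)
      b <- delta_counts(v2, v1)
      expect_equal(a$n_hypo, b$n_hyper)
      expect_equal(a$n_hyper, b$n_hypo)
      expect_setequal(a$altered, b$altered)
    }
  })
})

test_that("reference drift averages control follow-ups in the 6-18 month window", {
  tb <- data.frame(subject_id = c("CC1", "CC1", "CC2", "HD1", "CC1"),
                   cohort = c("CC", "CC", "CC", "HD", "CC"),
                   timepoint_months = c(6, 12, 6, 6, 24),
                   reference_months = 0,
                   n_hypo = 0, n_hyper = 0,
                   n_total = c(100, 190, 145, 3000, 9999))
  rep <- structure(list(table = tb), class = "longitudinal_report")
  expect_equal(reference_drift(rep), mean(c(100, 190, 145)))  # 24m excluded
  expect_equal(reference_drift(rep, months = 12), 190)
  hd_only <- structure(list(table = tb[tb$cohort == "HD", ]),
                       class = "longitudinal_report")
  expect_error(reference_drift(hd_only), "no CC follow-ups")
})

test_that("fold versus reference is a guarded ratio", {
  expect_equal(fold_vs_reference(2900, 145), 20)
  expect_equal(fold_vs_reference(145, 145), 1)
  expect_error(fold_vs_reference(100, 0), "positive")
})

test_that("treated subjects spike at 6 months while controls stay near reference", {
  co <- small_cohort()
  rep <- longitudinal_report(co$beta, co$manifest)
  ref <- reference_drift(rep)
  tb <- rep$table
  at6 <- tb[tb$timepoint_months == 6, ]
  treated <- at6[at6$cohort != "CC", ]
  expect_true(all(treated$n_total > 10 * ref))
  # non-persisters are back near reference by 12 months
  nonpers <- setdiff(treated$subject_id, co$truth$persisters)
  at12 <- tb[tb$timepoint_months == 12 & tb$subject_id %in% nonpers, ]
  expect_true(all(fold_vs_reference(at12$n_total, ref) < 3))
  # the persister remains elevated at every later follow-up
  pers <- tb[tb$subject_id %in% co$truth$persisters & tb$timepoint_months > 6, ]
  expect_true(all(pers$n_total > 5 * ref))
})

test_that("treated subjects share roughly the configured fraction of pulse sites", {
  # pulse sized well below the probe universe so incidental overlap between
  # subjects' private site draws stays negligible next to the shared pool
  co <- simulate_cohort(sim_config(n_probes = 30000L,
                                   n_per_cohort = c(CC = 2, HD = 2, TC = 1),
                                   timepoints_months = c(0, 6),
                                   treatment_pulse = list(magnitude = 0.3,
                                                          n_sites = 400L,
                                                          decay = 0.15,
                                                          overlap = 0.25,
                                                          persister_decay = 0.9,
                                                          n_persisters = 1L),
                                   rng_seed = 61L))
  rep <- longitudinal_report(co$beta, co$manifest)
  treated <- unique(co$manifest$subject_id[co$manifest$cohort != "CC"])
  sets <- rep$altered[paste0(treated[1:2], "@6")]
  cs <- common_across_subjects(sets)
  expect_true(all(abs(cs$shared_fraction - 0.25) < 0.05))
  expect_equal(common_across_subjects(list(a = c("x", "y"), b = c("x", "y")))$shared_fraction,
               c(a = 1, b = 1))
  expect_equal(common_across_subjects(list(a = "x", b = "y"))$n_shared, 0L)
})

test_that("timepoint intersections partition the union with correct cells", {
  sets <- list(t6 = c("a", "b", "c"), t12 = c("b", "c"), t24 = "c")
  it <- intersect_timepoints(sets)
  expect_identical(it$persistent, "c")
  expect_equal(it$union_size, 3L)
  expect_equal(sum(it$cells$count), it$union_size)
  only6 <- it$cells[it$cells$t6 & !it$cells$t12 & !it$cells$t24, "count"]
  both612 <- it$cells[it$cells$t6 & it$cells$t12 & !it$cells$t24, "count"]
  all3 <- it$cells[it$cells$t6 & it$cells$t12 & it$cells$t24, "count"]
  expect_equal(c(only6, both612, all3), c(1L, 1L, 1L))
  expect_length(intersect_timepoints(list(a = "x", b = "y"))$persistent, 0L)
  expect_error(intersect_timepoints(list(a = "x")), "at least 2")
})

test_that("Venn cells always partition the union (fuzzed)", {
  withr::with_seed(12, {
    for (i in 1:25) {
      k <- sample(2:4, 1)
      sets <- lapply(seq_len(k), function(...)
        sample(paste0("p", 1:50), sample(0:30, 1)))
      names(sets) <- paste0("s", seq_len(k))
      it <- intersect_timepoints(sets)
      expect_equal(sum(it$cells$count), length(unique(unlist(sets))))
    }
  })
})

test_that("common-coverage filter keeps CpGs at the inclusive threshold everywhere", {
  m <- matrix(0.5, 3, 2, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  cov <- matrix(c(9L, 10L, 30L, 15L, 10L, 30L), 3, 2, dimnames = dimnames(m))
  bm <- beta_matrix(m, cov)
  expect_identical(rownames(filter_common_covered(bm, 10)$beta), c("b", "c"))
  # strict mode drops the exactly-10 CpG
  expect_identical(rownames(filter_common_covered(bm, 10, exclusive = TRUE)$beta),
                   "c")
  expect_error(filter_common_covered(beta_matrix(m), 10), "no coverage")
  expect_warning(out <- filter_common_covered(bm, 100), "no CpG")
  expect_equal(nrow(out$beta), 0L)
})

test_that("dynamic classification uses inclusive intermediate bounds", {
  cls <- classify_dynamic(c(a = 0.5, b = 0.05, c = 0.2, d = 0.8, e = 0.81,
                            f = NA))
  expect_equal(cls$class, c("dynamic", "static", "dynamic", "dynamic",
                            "static", "static"))
})

test_that("dynamic share of altered sites is a covered percentage", {
  cls <- classify_dynamic(setNames(c(rep(0.5, 8), rep(0.01, 2)),
                                   paste0("p", 1:10)))
  expect_equal(dynamic_fraction_of_changes(paste0("p", 1:10), cls), 80)
  static_only <- classify_dynamic(setNames(rep(0.01, 4), paste0("p", 1:4)))
  expect_equal(dynamic_fraction_of_changes(paste0("p", 1:4), static_only), 0)
  expect_message(na <- dynamic_fraction_of_changes(character(), cls), "undefined")
  expect_true(is.na(na))
  expect_error(dynamic_fraction_of_changes("missing", cls), "cover")
})

test_that("dynamic CpGs dominate longitudinal changes when their noise is larger", {
  # stochastic dominance over seeds: dynamic share of changes exceeds the
  # dynamic share of the universe, and treated subjects show more
  # between-timepoint alterations than controls
  stats <- vapply(1:5, function(s) {
    co <- simulate_cohort(sim_config(mode = "capture", n_probes = 30000L,
                                     rng_seed = 100L + s))
    bm <- filter_common_covered(co$beta, 10)
    rep <- suppressMessages(longitudinal_report(bm, co$manifest,
                                                consecutive = TRUE))
    cls <- classify_dynamic(rowMeans(bm$beta))
    share <- mean(vapply(rep$altered, dynamic_fraction_of_changes, numeric(1),
                         classification = cls))
    tb <- rep$table
    c(share = share,
      excess = min(tb$n_total[tb$cohort != "CC"]) /
        max(tb$n_total[tb$cohort == "CC"]))
  }, numeric(2))
  expect_true(all(stats["share", ] > 30))    # universe is 30% dynamic
  expect_true(all(stats["excess", ] > 1))    # treated above control drift
})

test_that("Yates chi-squared matches the closed form and base R", {
  y <- yates_chisq(30, 100, 10, 100)
  expect_equal(y$chi2, 200 * (abs(30 * 90 - 70 * 10) - 100)^2 /
                 (100 * 100 * 40 * 160))     # 11.28125
  expect_equal(y$chi2, 11.28125)
  # equal proportions sit at the correction floor: statistic 0, p 1
  y0 <- yates_chisq(10, 100, 10, 100)
  expect_equal(y0$chi2, 0)
  expect_equal(y0$p, 1)
  expect_error(yates_chisq(0, 100, 0, 100), "zero margin")
  withr::with_seed(9, {
    for (i in 1:25) {
      na <- sample(20:500, 1); nb <- sample(20:500, 1)
      a <- sample(1:(na - 1), 1); b <- sample(1:(nb - 1), 1)
      y <- yates_chisq(a, na, b, nb)
      ref <- suppressWarnings(
        stats::chisq.test(matrix(c(a, na - a, b, nb - b), 2, byrow = TRUE),
                          correct = TRUE))
      expect_equal(y$chi2, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(y$p, ref$p.value, tolerance = 1e-10)
      # the continuity correction can only shrink the statistic
      raw <- suppressWarnings(
        stats::chisq.test(matrix(c(a, na - a, b, nb - b), 2, byrow = TRUE),
                          correct = FALSE))
      expect_lte(y$chi2, unname(raw$statistic) + 1e-12)
    }
  })
})
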