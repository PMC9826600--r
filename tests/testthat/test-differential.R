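test_that("probe filter drops multi-mapped and strictly-above-MAF probes", {
  ann <- data.frame(probe_id = paste0("p", 1:5), chrom = "chr1",
                    pos = 1:5 * 100L,
                    multi_mapped = c(FALSE, TRUE, FALSE, FALSE, FALSE),
                    snp_maf = c(NA, NA, 0.02, 0.005, 0.01))
  kept <- filter_probes(ann)
  expect_identical(kept, c("p1", "p4", "p5"))  # MAF 0.005 and exactly 0.01 kept
  clean <- ann; clean$multi_mapped <- FALSE; clean$snp_maf <- NA
  expect_identical(filter_probes(clean), ann$probe_id)
  expect_warning(filter_probes(transform(ann, multi_mapped = TRUE)), "no probes")
})

test_that("per-probe ANOVA matches the hand-computed worked example", {
  bm <- toy_beta(rbind(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)),
                 probes = "p1", samples = paste0("s", 1:9))
  mf <- toy_manifest(paste0("s", 1:9), rep(c("CC", "HD", "TC"), each = 3))
  r <- anova_per_probe(bm, mf)
  expect_equal(r$F, 27)                      # SSB = 0.54, SSW = 0.06
  expect_equal(r$df1, 2)
  expect_equal(r$df2, 6)
  expect_equal(r$p, pf(27, 2, 6, lower.tail = FALSE))
  expect_equal(c(r$mean_CC, r$mean_HD, r$mean_TC), c(0.2, 0.5, 0.8))
})

test_that("degenerate per-probe cases follow the documented conventions", {
  # identical groups -> F = 0, p = 1
  bm <- toy_beta(rbind(rep(0.4, 9)), probes = "p1", samples = paste0("s", 1:9))
  mf <- toy_manifest(paste0("s", 1:9), rep(c("CC", "HD", "TC"), each = 3))
  r <- anova_per_probe(bm, mf)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  # two cohorts: F equals the squared pooled-variance t statistic
  set.seed(1)
  x <- matrix(runif(80), 10, 8,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:8)))
  mf2 <- toy_manifest(paste0("s", 1:8), rep(c("CC", "HD"), each = 4))
  r2 <- anova_per_probe(beta_matrix(x), mf2)
  tsq <- apply(x, 1, function(v)
    t.test(v[1:4], v[5:8], var.equal = TRUE)$statistic^2)
  expect_equal(r2$F, unname(tsq), tolerance = 1e-12)
  # probes left without two 2-sample groups are skipped, not fabricated
  y <- x; y[1, c(1:3, 5:8)] <- NA
  r3 <- anova_per_probe(beta_matrix(y), mf2)
  expect_true(is.na(r3$F[1]))
  expect_equal(attr(r3, "n_skipped"), 1L)
})

test_that("ANOVA and Tukey agree with stats::aov / TukeyHSD on random matrices", {
  set.seed(7)
  n <- c(CC = 7, HD = 7, TC = 6)
  g <- rep(names(n), n)
  mf <- toy_manifest(paste0("s", seq_along(g)), g)
  x <- matrix(runif(50 * sum(n)), 50, sum(n),
              dimnames = list(paste0("p", 1:50), mf$sample_id))
  r <- tukey_posthoc(anova_per_probe(beta_matrix(x), mf))
  for (i in seq_len(nrow(x))) {
    d <- data.frame(v = x[i, ], g = factor(g, levels = names(n)))
    fit <- aov(v ~ g, d)
    ref <- anova(fit)
    expect_equal(r$F[i], ref$`F value`[1], tolerance = 1e-10)
    expect_equal(r$p[i], ref$`Pr(>F)`[1], tolerance = 1e-10)
    tk <- TukeyHSD(fit)$g
    expect_equal(r$diff_HD_CC[i], tk["HD-CC", "diff"], tolerance = 1e-10)
    expect_equal(r$p_HD_CC[i], tk["HD-CC", "p adj"], tolerance = 1e-10)
    expect_equal(r$p_TC_CC[i], tk["TC-CC", "p adj"], tolerance = 1e-10)
    expect_equal(r$p_TC_HD[i], tk["TC-HD", "p adj"], tolerance = 1e-10)
  }
})

test_that("Tukey-Kramer statistic matches the worked example and conventions", {
  bm <- toy_beta(rbind(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)),
                 probes = "p1", samples = paste0("s", 1:9))
  mf <- toy_manifest(paste0("s", 1:9), rep(c("CC", "HD", "TC"), each = 3))
  r <- tukey_posthoc(anova_per_probe(bm, mf))
  # TC vs CC: q = 0.6 / sqrt(MSW/2 * (2/3)) with MSW = 0.01
  q <- abs(r$diff_TC_CC) / sqrt(r$msw / 2 * (1 / 3 + 1 / 3))
  expect_equal(q, 10.39230, tolerance = 1e-5)
  expect_equal(r$p_TC_CC, ptukey(q, 3, 6, lower.tail = FALSE))
  expect_lt(r$diff_TC_CC * -1, 0)            # TC > CC here: positive difference
  # zero within-group variance: p = 0 for unequal means, 1 for equal
  bm0 <- toy_beta(rbind(rep(c(0.1, 0.1, 0.5), each = 3)), probes = "p1",
                  samples = paste0("s", 1:9))
  r0 <- tukey_posthoc(anova_per_probe(bm0, mf))
  expect_equal(r0$p_HD_CC, 1)
  expect_equal(r0$p_TC_CC, 0)
})

test_that("type-I error of the per-probe screen is calibrated under the null", {
  co <- simulate_cohort(sim_config(n_probes = 20000L, timepoints_months = 0,
                                   signature_spec = NULL,
                                   treatment_pulse = NULL, regions = NULL,
                                   rng_seed = 21L))
  r <- anova_per_probe(co$beta, co$manifest)
  expect_lt(abs(mean(r$p < 0.05, na.rm = TRUE) - 0.05), 0.01)
})

test_that("hypo/hyper split counts signed Tukey differences", {
  res <- data.frame(diff_HD_CC = c(-0.3, -0.2, 0.1, 0.4, -0.1),
                    sig_HD_CC = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  hh <- hypo_hyper_fractions(res, "HD_CC")
  expect_equal(hh$n_hypo, 2L)
  expect_equal(hh$n_hyper, 1L)
  expect_equal(hh$pct_hypo, 100 * 2 / 3)
  none <- data.frame(diff_HD_CC = 1, sig_HD_CC = FALSE)
  expect_true(is.na(hypo_hyper_fractions(none, "HD_CC")$pct_hypo))
  allhyper <- data.frame(diff_HD_CC = c(0.2, 0.3), sig_HD_CC = TRUE)
  expect_equal(hypo_hyper_fractions(allhyper, "HD_CC")$pct_hypo, 0)
})

test_that("top-k selection is deterministic with p, F, id tie-breaking", {
  res <- data.frame(probe_id = c("a", "b", "c"), p = c(0.3, 0.001, 0.04),
                    F = c(1, 30, 5))
  expect_identical(select_top_k(res, 2), c("b", "c"))
  tie <- data.frame(probe_id = c("z", "y", "x"), p = c(0.01, 0.01, 0.5),
                    F = c(2, 7, 1))
  expect_identical(select_top_k(tie, 1), "y")   # larger F wins the tie
  expect_identical(select_top_k(tie, 0), character())
  expect_warning(got <- select_top_k(tie, 10), "fewer probes")
  expect_length(got, 3)
  # permutation of input rows changes nothing
  perm <- tie[c(3, 1, 2), ]
  expect_identical(select_top_k(perm, 2), select_top_k(tie, 2))
})

test_that("clustering separates implanted signatures but not random probe sets", {
  co <- small_cohort()
  r <- anova_per_probe(co$beta, co$manifest)
  top <- select_top_k(r, 500)
  cl <- cluster_and_purity(co$beta, top, co$manifest)
  expect_equal(cl$purity, 1.0)
  # truth probes alone also separate perfectly
  truth_probes <- unique(co$truth$signatures$probe_id)
  expect_equal(cluster_and_purity(co$beta, truth_probes, co$manifest)$purity, 1.0)
  # random same-size draws carry no signature signal and fail to separate
  # the cohorts (drawn from the non-implanted background: the reduced test
  # universe concentrates signature density far above the full-scale one)
  bg <- setdiff(co$annotation$probe_id, truth_probes)
  withr::with_seed(5, {
    rand <- replicate(20, {
      p <- sample(bg, length(top))
      cluster_and_purity(co$beta, p, co$manifest)$purity
    })
  })
  expect_lt(mean(rand), 0.9)
  expect_true(all(rand <= 1.0))
  expect_error(cluster_and_purity(co$beta, top[1:5], co$manifest,
                                  n_clusters = 50), "fewer samples")
})

test_that("single-cohort clustering is trivially pure", {
  x <- matrix(runif(40), 4, 10,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:10)))
  mf <- toy_manifest(paste0("s", 1:10), rep("CC", 10))
  expect_equal(cluster_and_purity(beta_matrix(x), rownames(x), mf)$purity, 1.0)
})

test_that("region summary compares per-sample region means between groups", {
  # constructed 20-point difference: CC at 0.75, TC at 0.55
  x <- rbind(rep(c(0.75, 0.55), c(4, 4)), rep(c(0.75, 0.55), c(4, 4)))
  bm <- toy_beta(x, probes = c("a", "b"), samples = paste0("s", 1:8))
  ann <- toy_annotation(c("a", "b"), pos = c(100L, 200L))
  reg <- data.frame(chrom = "chr1", start = 0L, end = 500L, name = "R")
  mf <- toy_manifest(paste0("s", 1:8), rep(c("CC", "TC"), each = 4))
  rs <- region_summary(bm, ann, reg, mf, groups = c("CC", "TC"))
  expect_equal(rs$difference, 0.20)
  expect_equal(rs$p, 0)                     # zero variance, distinct means
  # identical groups: difference 0, p 1
  y <- matrix(0.6, 2, 8, dimnames = dimnames(x))
  rs0 <- region_summary(toy_beta(y, probes = c("a", "b"),
                                 samples = paste0("s", 1:8)),
                        ann, reg, mf, groups = c("CC", "TC"))
  expect_equal(rs0$difference, 0)
  expect_equal(rs0$p, 1)
  expect_error(region_summary(bm, ann, reg, mf, groups = c("CC", "HD")),
               "empty group")
})

test_that("exact Mann-Whitney p for complete separation matches enumeration", {
  x <- rbind(c(seq(0.1, 0.35, length.out = 6), seq(0.6, 0.9, length.out = 6)))
  bm <- toy_beta(x, probes = "a", samples = paste0("s", 1:12))
  ann <- toy_annotation("a", pos = 100L)
  reg <- data.frame(chrom = "chr1", start = 0L, end = 200L, name = "R")
  mf <- toy_manifest(paste0("s", 1:12), rep(c("CC", "TC"), each = 6))
  rs <- region_summary(bm, ann, reg, mf, groups = c("CC", "TC"),
                       test = "mann_whitney")
  expect_equal(rs$p, 2 * factorial(6)^2 / factorial(12), tolerance = 1e-12)
})
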