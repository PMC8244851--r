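make_records <- function(err_by_vendor, sphere = 1L, t1_nmr = 2033,
                         field = 3.0, modality = "vfa") {
  purrr::imap_dfr(err_by_vendor, function(errs, v) {
    tibble::tibble(
      sphere = sphere, t1_nmr_ms = t1_nmr,
      t1_measured_ms = t1_nmr * (1 + errs / 100),
      normalized_error_pct = errs,
      vendor = v, field_tesla = field, modality = modality,
      system = paste0(v, seq_along(errs)))
  })
}

test_that("normalized error is the exact percent deviation and scale invariant", {
  expect_identical(normalized_error(2033, 2033), 0)
  expect_identical(normalized_error(2200, 2000), 10)
  expect_identical(normalized_error(1600, 2000), -20)
  expect_error(normalized_error(1000, 0), "positive")
  # multiplying measured and reference by a common factor changes nothing
  set.seed(2)
  m <- runif(20, 100, 2000); r <- runif(20, 100, 2000)
  expect_equal(normalized_error(m, r), normalized_error(7.3 * m, 7.3 * r))
})

test_that("group summaries match the closed-form t interval", {
  rec <- make_records(list(A = c(0, 10), B = c(4, 4, 4)))
  sm <- group_summary(rec)
  a <- sm[sm$vendor == "A", ]
  expect_equal(a$mean_error_pct, 5)
  half <- qt(0.975, df = 1) * sd(c(0, 10)) / sqrt(2)
  expect_equal(a$ci_lower, 5 - half)
  expect_equal(a$ci_upper, 5 + half)
  b <- sm[sm$vendor == "B", ]
  expect_equal(b$mean_error_pct, 4)
  expect_equal(b$ci_lower, 4)      # zero-width interval
  expect_equal(b$ci_upper, 4)

  # translation equivariance: means shift, widths unchanged
  rec2 <- rec
  rec2$normalized_error_pct <- rec2$normalized_error_pct + 3
  sm2 <- group_summary(rec2)
  expect_equal(sm2$mean_error_pct, sm$mean_error_pct + 3)
  expect_equal(sm2$ci_upper - sm2$ci_lower, sm$ci_upper - sm$ci_lower)
})

test_that("singleton groups report a mean with an undefined interval", {
  rec <- make_records(list(A = c(1, 2), B = 5))
  sm <- group_summary(rec)
  b <- sm[sm$vendor == "B", ]
  expect_true(b$singleton)
  expect_equal(b$mean_error_pct, 5)
  expect_true(is.na(b$ci_lower) && is.na(b$ci_upper))
})

test_that("two-way ANOVA matches a textbook sums-of-squares computation", {
  # balanced 2 vendors x 2 fields x 2 replicates: classical decomposition
  set.seed(31)
  df <- tidyr::expand_grid(vendor = c("A", "B"), field = c(1.5, 3),
                           rep = 1:2)
  df$err <- rnorm(8, mean = ifelse(df$vendor == "A", 0, 2) +
                    ifelse(df$field == 3, 1, 0))
  rec <- tibble::tibble(
    sphere = 1L, t1_nmr_ms = 1000, t1_measured_ms = NA_real_,
    normalized_error_pct = df$err, vendor = df$vendor,
    field_tesla = df$field, modality = "ir", system = as.character(1:8))
  got <- two_way_anova(rec)

  # hand computation (balanced, so all SS types coincide)
  g <- mean(df$err)
  gv <- tapply(df$err, df$vendor, mean)
  gf <- tapply(df$err, factor(df$field), mean)
  gc <- tapply(df$err, interaction(df$vendor, df$field), mean)
  ss_int <- 2 * sum((gc - rep(gv, 2) - rep(gf, each = 2) + g)^2)
  ss_err <- sum((df$err - gc[interaction(df$vendor, df$field)])^2)
  f_int <- (ss_int / 1) / (ss_err / 4)
  expect_equal(got$interaction_p, pf(f_int, 1, 4, lower.tail = FALSE))
  expect_error(two_way_anova(rec[rec$vendor == "A", ]), "2 levels")
})

test_that("two-way ANOVA holds its type-I error rate near 5% under the null", {
  reps <- 200
  set.seed(7)
  seeds <- sample.int(1e6, reps)
  rej <- sapply(seeds, function(sd) {
    set.seed(sd)
    rec <- tibble::tibble(
      sphere = 1L, t1_nmr_ms = 1000, t1_measured_ms = NA_real_,
      normalized_error_pct = rnorm(20),
      vendor = rep(c("A", "B"), each = 10),
      field_tesla = rep(c(1.5, 3), 10),
      modality = "ir", system = as.character(1:20))
    two_way_anova(rec)$interaction_p < 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("two-way ANOVA detects an injected vendor-by-field interaction", {
  set.seed(13)
  rej <- sapply(1:60, function(i) {
    cells <- tidyr::expand_grid(vendor = c("A", "B"), field = c(1.5, 3),
                                rep = 1:10)
    # 10% interaction: vendor B at 3 T shifted, sigma 3%
    mu <- ifelse(cells$vendor == "B" & cells$field == 3, 10, 0)
    rec <- tibble::tibble(
      sphere = 1L, t1_nmr_ms = 1000, t1_measured_ms = NA_real_,
      normalized_error_pct = rnorm(nrow(cells), mu, 3),
      vendor = cells$vendor, field_tesla = cells$field,
      modality = "ir", system = as.character(seq_len(nrow(cells))))
    two_way_anova(rec)$interaction_p < 0.05
  })
  expect_gt(mean(rej), 0.9)
})

test_that("pairwise comparisons: degenerate and 2-group cases", {
  # two vendors with identical per-system values: no group difference, p = 1
  rec <- make_records(list(A = c(1, 2, 3), B = c(1, 2, 3)))
  res <- per_sphere_pairwise(rec)
  expect_equal(res$pairwise$p_adj, 1)
  expect_false(res$pairwise$significant)

  # with 2 groups the Tukey-Kramer p equals the one-way ANOVA p
  set.seed(41)
  rec2 <- make_records(list(A = rnorm(5, 0, 2), B = rnorm(6, 1.5, 2)))
  res2 <- per_sphere_pairwise(rec2)
  expect_equal(res2$pairwise$p_adj, res2$anova$anova_p, tolerance = 1e-6)
})

test_that("an offset vendor is flagged against both others but the null pair is not", {
  runs <- 60
  set.seed(53)
  hits_offset <- 0; hits_null <- 0
  for (i in seq_len(runs)) {
    rec <- make_records(list(A = rnorm(6, 0, 2), B = rnorm(6, 0, 2),
                             C = rnorm(6, 10, 2)))
    pw <- per_sphere_pairwise(rec)$pairwise
    offset_pairs <- pw$significant[grepl("C", pw$comparison)]
    null_pair <- pw$significant[pw$comparison == "B-A"]
    if (all(offset_pairs)) hits_offset <- hits_offset + 1
    if (!null_pair) hits_null <- hits_null + 1
  }
  expect_gte(hits_offset / runs, 0.95)
  expect_gte(hits_null / runs, 0.85)
})

test_that("pairwise p-values are invariant under vendor relabelling", {
  set.seed(61)
  rec <- make_records(list(A = rnorm(5), B = rnorm(5, 1), C = rnorm(5, 2)))
  p1 <- unname(sort(per_sphere_pairwise(rec)$pairwise$p_adj))
  relabel <- c(A = "Z", B = "Y", C = "X")
  rec2 <- dplyr::mutate(rec, vendor = unname(relabel[vendor]))
  p2 <- unname(sort(per_sphere_pairwise(rec2)$pairwise$p_adj))
  expect_equal(p1, p2)
})

test_that("spheres missing a second vendor are skipped with a warning", {
  rec <- dplyr::bind_rows(
    make_records(list(A = c(1, 2), B = c(2, 3)), sphere = 1L),
    make_records(list(A = c(1, 2)), sphere = 2L))
  expect_warning(res <- per_sphere_pairwise(rec), "skipped")
  expect_identical(res$anova$sphere, 1L)
})

test_that("bias propagation reproduces direct interval arithmetic on glioma T1 values", {
  # identity when unbiased and dispersion-free
  expect_equal(propagate_bias(1355, 187, 0, 0),
               c(lower = 1168, upper = 1542))
  # low-grade glioma 1355 +/- 187 ms under -15% bias, 10% dispersion
  got <- propagate_bias(1355, 187, -15, 10)
  expect_equal(got, c(lower = 0.75 * 1168, upper = 0.95 * 1542))

  lgg <- c(1355, 187); gbm <- c(1863, 70)
  # IR-like biases keep the two tissue ranges separable
  for (b in list(c(2, 7), c(10, 7))) {
    r_lgg <- propagate_bias(lgg[1], lgg[2], b[1], b[2])
    r_gbm <- propagate_bias(gbm[1], gbm[2], b[1], b[2])
    expect_lt(r_lgg["upper"], r_gbm["lower"])
  }
  # the strongly negative VFA bias with wide dispersion makes them overlap
  r_lgg <- propagate_bias(lgg[1], lgg[2], 7, 10)
  r_gbm <- propagate_bias(gbm[1], gbm[2], -15, 10)
  expect_gt(r_lgg["upper"], r_gbm["lower"])

  # widening dispersion never narrows the range
  r1 <- propagate_bias(1355, 187, -15, 5)
  r2 <- propagate_bias(1355, 187, -15, 12)
  expect_lte(r2["lower"], r1["lower"])
  expect_gte(r2["upper"], r1["upper"])
  expect_error(propagate_bias(-1, 5, 0, 0), "positive")
  expect_error(propagate_bias(1000, 5, 0, -1), "nonnegative")
})
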