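test_that("two-way ANOVA recovers pure effects and handles degenerate input", {
  d <- tidyr::expand_grid(sex = c("F", "M"), time = c("HT", "15min"),
                          rep = 1:4)
  d$y <- ifelse(d$time == "15min", 2, 0)
  out <- tidy(anova_eta2(d, "y", "sex", "time"))
  expect_equal(out$eta_sq[out$term == "time"], 1)
  expect_equal(out$eta_sq[out$term == "sex"], 0)

  d$y <- 3
  flat <- tidy(anova_eta2(d, "y", "sex", "time"))
  expect_true(all(flat$eta_sq[1:3] == 0))
  expect_true(all(is.na(flat$statistic)))

  d2 <- d[!(d$sex == "F" & d$time == "HT"), ]
  expect_error(anova_eta2(d2, "y", "sex", "time"),
               regexp = "empty design cell",
               class = "fishmap_error_validation")
})

test_that("balanced ANOVA matches a hand-coded sums-of-squares decomposition", {
  set.seed(31)
  d <- tidyr::expand_grid(A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                          rep = 1:5)
  d$y <- rnorm(nrow(d)) + 1.5 * (d$A == "a2") + 0.8 * (d$B == "b2")
  out <- tidy(anova_eta2(d, "y", "A", "B"))

  grand <- mean(d$y)
  ma <- tapply(d$y, d$A, mean); mb <- tapply(d$y, d$B, mean)
  # cell means as a 2 x 3 matrix (A levels x B levels)
  mab <- tapply(d$y, list(d$A, d$B), mean)
  ss_a <- 15 * sum((ma - grand)^2)
  ss_b <- 10 * sum((mb - grand)^2)
  ss_ab <- 5 * sum((sweep(sweep(mab, 1, ma), 2, mb) + grand)^2)
  ss_tot <- sum((d$y - grand)^2)
  expect_equal(out$sumsq[out$term == "A"], ss_a)
  expect_equal(out$sumsq[out$term == "B"], ss_b)
  expect_equal(out$sumsq[out$term == "A:B"], ss_ab)
  # balanced case: components sum to the total
  expect_equal(sum(out$sumsq), ss_tot)
  expect_equal(out$eta_sq[1:3], out$sumsq[1:3] / ss_tot)
})

test_that("Dunnett adjustment reduces to the t-test for one comparison", {
  set.seed(5)
  d <- data.frame(g = rep(c("ctrl", "trt"), each = 8),
                  y = rnorm(16) + rep(c(0, 1), each = 8))
  out <- dunnett_vs_control(d, "y", "g", "ctrl")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(out$adj.p.value, tt$p.value, tolerance = 1e-12)
  expect_equal(out$p.value, out$adj.p.value)
})

test_that("Dunnett adjusted p dominates raw p and matches a Monte-Carlo max-|t| oracle", {
  set.seed(8)
  k <- 6; n <- 8
  d <- data.frame(g = rep(paste0("g", 0:(k - 1)), each = n),
                  y = rnorm(k * n))
  d$y[d$g == "g3"] <- d$y[d$g == "g3"] + 2
  out <- dunnett_vs_control(d, "y", "g", "g0")
  expect_true(all(out$adj.p.value >= out$p.value))
  expect_true(all(out$adj.p.value <= 1))

  # Monte-Carlo oracle for the balanced many-to-one max-|t| null:
  # group means ~ N(0, 1/n), pooled variance ~ chi^2_nu / nu
  nu <- k * n - k
  set.seed(123)
  ndraw <- 1e6
  m0 <- rnorm(ndraw, sd = 1 / sqrt(n))
  dmax <- rep(0, ndraw)
  for (j in 1:(k - 1)) {
    mj <- rnorm(ndraw, sd = 1 / sqrt(n))
    dmax <- pmax(dmax, abs(mj - m0))
  }
  s <- sqrt(stats::rchisq(ndraw, nu) / nu)   # one pooled SD per draw
  tmax <- dmax / (s * sqrt(2 / n))
  for (i in seq_len(nrow(out))) {
    mc_p <- mean(tmax >= abs(out$statistic[i]))
    expect_equal(out$adj.p.value[i], mc_p, tolerance = 2e-3)
  }
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(fdr_adjust(0.37), 0.37)
  # hand computation on an unsorted vector
  p <- c(0.03, 0.001, 0.8, 0.02, 0.2)
  o <- order(p)
  q_sorted <- rev(cummin(rev(sort(p) * 5 / seq_len(5))))
  expect_equal(fdr_adjust(p)[o], pmin(q_sorted, 1))
  # monotone in the p-ranks and capped at 1
  set.seed(2)
  p2 <- runif(50)
  q2 <- fdr_adjust(p2)
  expect_true(all(diff(q2[order(p2)]) >= -1e-12))
  expect_true(all(q2 <= 1))
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "fishmap_error_validation")
})

test_that("Cohen's d is the pooled-SD standardised mean difference", {
  x <- c(0.5, 1.5, 1, 1); y <- c(-0.5, 0.5, 0, 0)
  sp <- sqrt(((3 * var(x)) + (3 * var(y))) / 6)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "fishmap_error_validation")
  expect_error(cohens_d(1, c(1, 2)), class = "fishmap_error_validation")
})

make_region_table <- function(n_regions, elevated, n_a = 13, n_b = 9,
                              d_eff = 2, seed = 1) {
  set.seed(seed)
  subj <- c(sprintf("a%02d", 1:n_a), sprintf("b%02d", 1:n_b))
  grp <- rep(c("15min", "HT"), c(n_a, n_b))
  purrr::map_dfr(seq_len(n_regions), function(r) {
    mu <- ifelse(grp == "15min" & r %in% elevated, d_eff, 0)
    tibble::tibble(subject_id = subj, group = grp, region_id = r,
                   region_abbrev = sprintf("R%03d", r),
                   count = rnorm(length(subj), mu, 1))
  })
}

test_that("region-wise tests recover planted elevations and control false positives", {
  tbl <- make_region_table(140, elevated = 1:40, seed = 42)
  res <- regionwise_tests(tbl, "15min", "HT")
  hits <- res$region_id[res$q.value < 0.05 & !is.na(res$q.value)]
  expect_gte(length(intersect(hits, 1:40)), 36)      # >= 90% of planted
  expect_lte(length(setdiff(hits, 1:40)), 5)         # <= 5% of 100 nulls
  expect_true(all(res$direction[res$region_id %in% hits &
                                  res$region_id <= 40] == "up"))

  # identical groups: nothing passes
  null_tbl <- make_region_table(60, elevated = integer(0), seed = 7)
  null_res <- regionwise_tests(null_tbl, "15min", "HT")
  expect_equal(sum(null_res$q.value < 0.05, na.rm = TRUE), 0L)

  # permuting group labels destroys recovery
  set.seed(3)
  perm <- tbl
  relab <- dplyr::distinct(tbl, subject_id)
  relab$group <- sample(rep(c("15min", "HT"), c(13, 9)))
  perm$group <- relab$group[match(perm$subject_id, relab$subject_id)]
  perm_res <- regionwise_tests(perm, "15min", "HT")
  expect_lte(sum(perm_res$q.value < 0.05, na.rm = TRUE), 3L)
})

test_that("paired region-wise tests match a by-hand paired t-test", {
  set.seed(9)
  subj <- sprintf("s%d", 1:8)
  tbl <- dplyr::bind_rows(
    tibble::tibble(subject_id = subj, group = "punctate", region_id = 1L,
                   region_abbrev = "R001", count = rnorm(8, 5)),
    tibble::tibble(subject_id = subj, group = "diffuse", region_id = 1L,
                   region_abbrev = "R001", count = rnorm(8, 4)))
  res <- regionwise_tests(tbl, "punctate", "diffuse", paired = TRUE)
  dd <- tbl$count[tbl$group == "punctate"] - tbl$count[tbl$group == "diffuse"]
  tt <- t.test(dd)
  expect_equal(res$p.value, tt$p.value)
  expect_equal(res$estimate, mean(dd))
  expect_equal(res$cohens_d, mean(dd) / sd(dd))
})
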