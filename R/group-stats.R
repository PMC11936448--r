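#' Two-way factorial ANOVA with effect sizes
#'
#' Classical two-way ANOVA (e.g. sex x time for whole-brain c-fos counts)
#' with eta-squared per effect, `SS_effect / SS_total`. Cell sizes of 3-7
#' animals are rarely balanced, so sums of squares are Type II
#' (each main effect adjusted for the other, the interaction for both),
#' computed via [car::Anova()]; with balanced data these coincide with the
#' classical sequential decomposition.
#'
#' @param data A data frame.
#' @param response,factor_a,factor_b Column names (strings) of the numeric
#'   response and the two factors.
#' @return A `fishmap_anova` object; see [tidy.fishmap_anova()].
#' @examples
#' d <- expand.grid(sex = c("F", "M"), time = c("HT", "15min"),
#'                  rep = 1:4)
#' d$y <- rnorm(nrow(d)) + 2 * (d$time == "15min")
#' tidy(anova_eta2(d, "y", "sex", "time"))
#' @export
anova_eta2 <- function(data, response, factor_a, factor_b) {
  data <- as.data.frame(data)
  for (v in c(response, factor_a, factor_b)) {
    if (!v %in% names(data)) {
      abort(sprintf("column '%s' not found", v), class = "fishmap_error_validation")
    }
  }
  y <- data[[response]]
  A <- factor(data[[factor_a]])
  B <- factor(data[[factor_b]])
  if (nlevels(A) < 2 || nlevels(B) < 2) {
    abort("both factors need at least two levels", class = "fishmap_error_validation")
  }
  cell_n <- table(A, B)
  if (any(cell_n == 0)) {
    empty <- which(cell_n == 0, arr.ind = TRUE)[1, ]
    abort(sprintf("empty design cell: %s = %s, %s = %s", factor_a,
                  levels(A)[empty[1]], factor_b, levels(B)[empty[2]]),
          class = "fishmap_error_validation")
  }
  ss_total <- sum((y - mean(y))^2)
  df <- data.frame(y = y, A = A, B = B)
  fit <- stats::lm(y ~ A * B, data = df)

  if (ss_total == 0) {
    tab <- tibble(term = c(factor_a, factor_b,
                           paste0(factor_a, ":", factor_b), "Residuals"),
                  sumsq = 0, df = c(nlevels(A) - 1L, nlevels(B) - 1L,
                                    (nlevels(A) - 1L) * (nlevels(B) - 1L),
                                    stats::df.residual(fit)),
                  statistic = NA_real_, p.value = NA_real_, eta_sq = 0)
  } else {
    # a perfect fit (zero residual SS) breaks the Type-II computation; the
    # sequential table is identical there for the balanced designs in which
    # perfect fits arise
    a2 <- suppressWarnings(tryCatch(car::Anova(fit, type = 2),
                                    error = function(e) stats::anova(fit)))
    tab <- tibble(
      term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "Residuals"),
      sumsq = as.numeric(a2[["Sum Sq"]]),
      df = as.numeric(a2[["Df"]]),
      statistic = as.numeric(a2[["F value"]]),
      p.value = as.numeric(a2[["Pr(>F)"]]),
      eta_sq = as.numeric(a2[["Sum Sq"]]) / ss_total
    )
    tab$eta_sq[tab$term == "Residuals"] <- NA_real_
  }
  structure(list(table = tab, ss_total = ss_total, fit = fit,
                 factors = c(factor_a, factor_b), response = response),
            class = "fishmap_anova")
}

#' @export
print.fishmap_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (Type II SS): %s ~ %s * %s\n", x$response,
              x$factors[1], x$factors[2]))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @rdname anova_eta2
#' @param x A `fishmap_anova` object.
#' @param ... Unused.
#' @exportS3Method
tidy.fishmap_anova <- function(x, ...) x$table

#' @rdname anova_eta2
#' @exportS3Method
glance.fishmap_anova <- function(x, ...) {
  tibble(ss_total = x$ss_total,
         df_residual = x$table$df[x$table$term == "Residuals"],
         n = length(x$fit$residuals))
}

#' Dunnett many-to-one comparisons against a control group
#'
#' Compares every non-control group mean to a single control, adjusting
#' for the family using the exact many-to-one multivariate-t distribution:
#' under the null the comparison t statistics are jointly multivariate t
#' with correlation `sqrt(lambda_j * lambda_k)`,
#' `lambda_j = n_j / (n_j + n_0)`, on the pooled-error degrees of freedom.
#' The adjusted p-value for comparison j is the probability that the
#' maximum absolute component exceeds `|t_j|`.
#'
#' @param data A data frame.
#' @param response,group Column names of the numeric response and the
#'   grouping factor.
#' @param control Label of the control level of `group`.
#' @return A tibble: `comparison`, `estimate` (group minus control),
#'   `statistic`, `df`, `p.value` (unadjusted), `adj.p.value`.
#' @export
dunnett_vs_control <- function(data, response, group, control) {
  data <- as.data.frame(data)
  y <- data[[response]]
  g <- factor(data[[group]])
  if (!control %in% levels(g)) {
    abort("control level not present", class = "fishmap_error_validation")
  }
  ns <- table(g)
  if (any(ns < 2)) {
    abort("every group needs n >= 2", class = "fishmap_error_validation")
  }
  k <- nlevels(g)
  if (k < 2) abort("need at least two groups", class = "fishmap_error_validation")
  means <- tapply(y, g, mean)
  vars <- tapply(y, g, var)
  nu <- length(y) - k
  s2 <- sum((ns - 1) * vars) / nu
  if (s2 <= 0) abort("zero pooled variance", class = "fishmap_error_validation")

  others <- setdiff(levels(g), control)
  n0 <- ns[[control]]
  nj <- as.numeric(ns[others])
  est <- as.numeric(means[others] - means[[control]])
  se <- sqrt(s2 * (1 / nj + 1 / n0))
  tstat <- est / se
  lam <- sqrt(nj / (nj + n0))
  R <- outer(lam, lam)
  diag(R) <- 1

  raw_p <- 2 * pt(abs(tstat), nu, lower.tail = FALSE)
  adj_p <- vapply(abs(tstat), function(tt) {
    if (length(others) == 1L) return(2 * pt(tt, nu, lower.tail = FALSE))
    pr <- with_preserved_seed(20240317, {
      mvtnorm::pmvt(lower = rep(-tt, length(others)),
                    upper = rep(tt, length(others)),
                    df = as.integer(nu), corr = R,
                    algorithm = mvtnorm::GenzBretz(abseps = 1e-6,
                                                   maxpts = 250000))
    })
    min(max(1 - as.numeric(pr), 0), 1)
  }, numeric(1))

  tibble(comparison = paste(others, "-", control),
         group = others,
         estimate = est, statistic = tstat, df = nu,
         p.value = raw_p, adj.p.value = pmax(adj_p, raw_p))
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment, capped at 1. A thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]", class = "fishmap_error_validation")
  }
  stats::p.adjust(p, method = "BH")
}

#' Cohen's d (pooled standard deviation)
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return Standardised mean difference `(mean(x) - mean(y)) / s_pooled`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) abort("need n >= 2 per group", class = "fishmap_error_validation")
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 <= 0) abort("zero pooled SD", class = "fishmap_error_validation")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Region-wise two-group tests with FDR correction
#'
#' For every region, a t-test comparing two groups of animals (independent
#' samples by default; paired matches animals by `subject_id`), with
#' Benjamini-Hochberg correction across regions and Cohen's d. Used to
#' find regions with elevated c-fos between a control and a
#' post-behaviour time point. Independent tests use the pooled-variance t
#' (matching the pooled-SD d); set `welch = TRUE` for unequal variances.
#' Masked (missing) entries are dropped per region; regions left with
#' fewer than 2 observations per group are skipped with a warning.
#'
#' @param table Regional count table (columns `subject_id`, `group`,
#'   `region_id`, `region_abbrev`, value column).
#' @param group_a,group_b Labels of the two groups to compare (estimate
#'   and direction are `group_a` minus `group_b`).
#' @param value Name of the value column (default `"count"`).
#' @param paired Pair observations by subject (for within-animal
#'   comparisons); requires the same subjects in both groups.
#' @param welch Use Welch's t instead of pooled variance (independent
#'   tests only).
#' @return A tibble: `region_id`, `region_abbrev`, `n_a`, `n_b`,
#'   `estimate`, `statistic`, `df`, `p.value`, `q.value`, `cohens_d`,
#'   `direction` (`"up"` if `group_a` exceeds `group_b`).
#' @export
regionwise_tests <- function(table, group_a, group_b, value = "count",
                             paired = FALSE, welch = FALSE) {
  table <- as_tibble(table)
  stopifnot(all(c("subject_id", "group", "region_id") %in% names(table)))
  sub <- table[table$group %in% c(group_a, group_b) & !is.na(table[[value]]), ]
  if (nrow(sub) == 0) abort("groups not found", class = "fishmap_error_validation")

  regions <- unique(sub[, intersect(c("region_id", "region_abbrev"), names(sub))])
  res <- purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    rid <- regions$region_id[i]
    da <- sub[sub$region_id == rid & sub$group == group_a, ]
    db <- sub[sub$region_id == rid & sub$group == group_b, ]
    base <- tibble(region_id = rid,
                   region_abbrev = regions$region_abbrev[i] %||% NA_character_,
                   n_a = nrow(da), n_b = nrow(db))
    if (paired) {
      m <- dplyr::inner_join(da[, c("subject_id", value)],
                             db[, c("subject_id", value)],
                             by = "subject_id", suffix = c("_a", "_b"))
      dd <- m[[paste0(value, "_a")]] - m[[paste0(value, "_b")]]
      if (length(dd) < 2 || sd(dd) == 0) return(dplyr::mutate(base, skipped = TRUE))
      tt <- stats::t.test(dd)
      d <- mean(dd) / sd(dd)
    } else {
      xa <- da[[value]]; xb <- db[[value]]
      if (length(xa) < 2 || length(xb) < 2 ||
          (sd(xa) == 0 && sd(xb) == 0)) {
        return(dplyr::mutate(base, skipped = TRUE))
      }
      tt <- stats::t.test(xa, xb, var.equal = !welch)
      d <- cohens_d(xa, xb)
    }
    dplyr::mutate(base,
                  estimate = unname(if (paired) tt$estimate
                                    else diff(rev(tt$estimate))),
                  statistic = unname(tt$statistic), df = unname(tt$parameter),
                  p.value = tt$p.value, cohens_d = d, skipped = FALSE)
  })
  if (any(res$skipped)) {
    warn(sprintf("%d region(s) skipped (insufficient n or zero variance)",
                 sum(res$skipped)))
  }
  tested <- !res$skipped
  res$q.value <- NA_real_
  if (any(tested)) res$q.value[tested] <- fdr_adjust(res$p.value[tested])
  res$direction <- ifelse(res$skipped, NA_character_,
                          ifelse(res$estimate > 0, "up", "down"))
  dplyr::relocate(res, "q.value", .after = "p.value")
}
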