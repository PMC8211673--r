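# The statistical battery used in the stability analysis.
#
# Closed-form classics (chi-square, Spearman, covariate-adjusted group
# comparison) go through base R model fits; Fisher's exact test is a
# direct hypergeometric probability-mass summation; Steel's many-to-one
# rank test and PERMANOVA are seed-controlled permutation procedures
# implemented on top of the distance/rank machinery here.

new_gut_test <- function(statistic, p_value, method,
                         n_permutations = 0L, seed = NULL, ...) {
  structure(list(statistic = statistic, p_value = p_value,
                 method = method,
                 n_permutations = as.integer(n_permutations),
                 seed = seed, ...),
            class = "gut_test")
}

#' @export
print.gut_test <- function(x, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  if (length(x$statistic) == 1) {
    cat("statistic = ", format(x$statistic, digits = 5),
        ", p-value = ", format(x$p_value, digits = 4), "\n", sep = "")
  } else {
    print(tibble::tibble(comparison = names(x$statistic),
                         statistic = unname(x$statistic),
                         p.value = unname(x$p_value)))
  }
  if (x$n_permutations > 0) {
    cat("(", x$n_permutations, " permutations",
        if (!is.null(x$seed)) paste0(", seed ", x$seed), ")\n", sep = "")
  }
  invisible(x)
}

#' Broom-style tidiers for test results
#'
#' `tidy()` returns one row per comparison (most tests have one);
#' `glance()` returns a one-row summary.
#'
#' @param x A `gut_test` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gut_test
#' @export
tidy.gut_test <- function(x, ...) {
  nm <- names(x$statistic)
  if (is.null(nm)) nm <- x$method
  tibble::tibble(comparison = nm,
                 statistic = unname(x$statistic),
                 p.value = unname(x$p_value),
                 method = x$method)
}

#' @rdname tidy.gut_test
#' @method glance gut_test
#' @export
glance.gut_test <- function(x, ...) {
  tibble::tibble(statistic = unname(x$statistic)[1],
                 p.value = unname(x$p_value)[1],
                 method = x$method,
                 n_permutations = x$n_permutations,
                 seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Coerce a 2x2 count input (matrix, data frame, or length-4 vector
# a,b,c,d filled by row) and validate it.
as_table2x2 <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2, 2))) abort("Need a 2x2 table.")
  } else if (length(x) == 4) {
    x <- matrix(x, 2, 2, byrow = TRUE)
  } else {
    abort("Need a 2x2 table or 4 counts (a, b, c, d by row).")
  }
  if (any(x < 0)) abort("Counts must be nonnegative.")
  if (any(x != round(x))) abort("Counts must be integers.")
  if (sum(x) == 0) abort("Table total must be > 0.")
  x
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing, over all tables with the observed
#' margins, the hypergeometric probabilities no larger than that of the
#' observed table (the probability-mass summation convention, with the
#' usual `1 + 1e-7` relative tie tolerance). Used for group differences
#' in the incidence of substantial microbiota change.
#'
#' @param table A 2x2 matrix of counts, or 4 counts `(a, b, c, d)` filling
#'   the table by row (row = group, column = outcome yes/no).
#' @return A `gut_test`; `statistic` is the sample odds ratio
#'   (`ad / bc`).
#' @examples
#' fisher_exact(c(18, 142, 1, 57))  # p ~ 0.029
#' @export
fisher_exact <- function(table) {
  x <- as_table2x2(table)
  a <- x[1, 1]
  m <- sum(x[1, ]); n <- sum(x[2, ]); k <- sum(x[, 1])
  supp <- max(0, k - n):min(m, k)
  dens <- dhyper(supp, m, n, k)
  p <- min(1, sum(dens[dens <= dens[supp == a] * (1 + 1e-7)]))
  or <- (x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1])
  new_gut_test(c(`odds ratio` = or), p,
               "Fisher's exact test (two-sided, probability summation)")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson X^2 without continuity correction, 1 degree of freedom. Used
#' for group contrasts in categorical covariates (sex ratio, smoking,
#' alcohol, medication).
#'
#' @inheritParams fisher_exact
#' @return A `gut_test`; `statistic` is X^2.
#' @export
chi_square_2x2 <- function(table) {
  x <- as_table2x2(table)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    abort("Zero row or column margin.")
  }
  ct <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  new_gut_test(c(`X-squared` = unname(ct$statistic)),
               unname(ct$p.value),
               "Pearson chi-square (2x2, no continuity correction)")
}

# Tie-corrected standardized Wilcoxon rank-sum z of `trt` against `ctrl`
# on jointly ranked data. Returns 0 when the pooled values are constant.
rank_sum_z <- function(ctrl, trt) {
  nc <- length(ctrl); nt <- length(trt); N <- nc + nt
  x <- c(ctrl, trt)
  r <- rank(x)
  W <- sum(r[(nc + 1):N])
  ties <- tabulate(match(x, x))
  ties <- ties[ties > 0]
  tiecor <- sum(ties^3 - ties) / (N * (N - 1))
  v <- nc * nt / 12 * ((N + 1) - tiecor)
  if (v <= 0) return(0)
  (W - nt * (N + 1) / 2) / sqrt(v)
}

#' Steel's many-to-one rank test (permutation variant)
#'
#' Compares each treatment group with one shared control group on jointly
#' ranked data, controlling the familywise error over the set of
#' comparisons. Each comparison uses the tie-corrected standardized
#' Wilcoxon rank-sum statistic of (control vs that treatment); familywise
#' p-values come single-step from the permutation distribution of the
#' maximum absolute standardized statistic, permuting the pooled
#' observations over all groups. With a single treatment this reduces to
#' a two-sided Wilcoxon rank-sum permutation test.
#'
#' Used to compare intra-individual distances (control) against each
#' year's inter-individual distances.
#'
#' @param control Numeric vector, the control group (length >= 2).
#' @param treatments A numeric vector or list of numeric vectors, each a
#'   treatment group (length >= 2).
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Optional integer seed; the permutation stream is local and
#'   the global RNG state is untouched.
#' @return A `gut_test` with one statistic/p-value per treatment.
#' @export
steel_test <- function(control, treatments, n_permutations = 10000,
                       seed = NULL) {
  if (is.numeric(treatments)) treatments <- list(treatments)
  if (length(control) < 2 || any(lengths(treatments) < 2)) {
    abort("Each group needs at least 2 values.")
  }
  if (is.null(names(treatments))) {
    names(treatments) <- paste0("treatment", seq_along(treatments))
  }
  nc <- length(control)
  sizes <- lengths(treatments)
  pooled <- c(control, unlist(treatments, use.names = FALSE))
  z_obs <- purrr::map_dbl(treatments, ~rank_sum_z(control, .x))
  ends <- nc + cumsum(sizes)
  starts <- ends - sizes + 1
  max_perm <- with_local_seed(seed, {
    purrr::map_dbl(seq_len(n_permutations), function(i) {
      p <- pooled[sample.int(length(pooled))]
      max(abs(purrr::map2_dbl(starts, ends,
                              ~rank_sum_z(p[seq_len(nc)], p[.x:.y]))))
    })
  })
  p <- purrr::map_dbl(abs(z_obs),
                      ~(1 + sum(max_perm >= .x - 1e-12)) /
                        (n_permutations + 1))
  new_gut_test(setNames(z_obs, names(treatments)),
               setNames(p, names(treatments)),
               "Steel's many-to-one rank test (max-T permutation)",
               n_permutations = n_permutations, seed = seed)
}

#' Covariate-adjusted two-group comparison (ANCOVA)
#'
#' Ordinary least-squares fit of the response on an intercept, a binary
#' group indicator and the covariates; the reported statistic is the t
#' value of the group coefficient with residual degrees of freedom
#' (numerically identical to the classic covariate-adjusted ANCOVA F with
#' one numerator df). Incomplete cases are dropped listwise.
#'
#' @param data A data frame.
#' @param y Name of the numeric response column (string).
#' @param group Name of the two-level group column.
#' @param covariates Character vector of adjustment column names
#'   (numeric, logical, or two-level factors); may be empty.
#' @return A `gut_test`; `estimate` holds the adjusted group difference.
#' @export
adjusted_group_compare <- function(data, y, group,
                                   covariates = character()) {
  cols <- c(y, group, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Column(s) not in data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  d <- data[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < length(covariates) + 3) {
    abort("Too few complete cases for the requested adjustment.")
  }
  g <- d[[group]]
  if (dplyr::n_distinct(g) != 2) abort("`group` must have exactly 2 levels.")
  d[[group]] <- factor(g)
  fml <- stats::reformulate(c(group, covariates), response = y)
  fit <- lm(fml, data = d)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Rank-deficient design; drop collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  grow <- grep(paste0("^", group), rownames(sm))[1]
  new_gut_test(c(t = unname(sm[grow, "t value"])),
               unname(sm[grow, "Pr(>|t|)"]),
               "covariate-adjusted group comparison (OLS t on group term)",
               estimate = unname(sm[grow, "Estimate"]),
               df = fit$df.residual, n = nrow(d))
}

#' Levene's test for equality of dispersions
#'
#' Classic Levene: a one-way ANOVA F on the absolute deviations of each
#' value from its group mean. Used to compare the spread of per-family
#' abundance changes between intake groups; `center = "median"` gives the
#' Brown-Forsythe variant.
#'
#' @param values Numeric vector, or a list of numeric vectors (one per
#'   group, in which case `group` is ignored).
#' @param group Group labels, same length as `values`.
#' @param center `"mean"` (classic, default) or `"median"`.
#' @return A `gut_test`; `statistic` is the ANOVA F.
#' @export
levene_test <- function(values, group = NULL, center = c("mean", "median")) {
  center <- match.arg(center)
  if (is.list(values)) {
    group <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(group)
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  if (any(table(g) < 2)) abort("Each group needs at least 2 values.")
  cfun <- if (center == "mean") mean else median
  z <- abs(values - stats::ave(values, g, FUN = cfun))
  if (all(z == 0)) abort("zero dispersion everywhere: all groups constant")
  a <- stats::anova(lm(z ~ g))
  new_gut_test(c(F = a$`F value`[1]), a$`Pr(>F)`[1],
               paste0("Levene's test (", center, "-centered)"),
               df = unname(a$Df))
}

#' Spearman rank correlation test
#'
#' Rho on average-ranked data (ties share their average rank); the
#' p-value uses the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}. For small samples
#' (`n <= 10`, no ties) `exact = TRUE` switches to the exact permutation
#' null.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact Use the exact null distribution (small n, no ties).
#' @return A `gut_test`; `statistic` is rho.
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (length(x) < 3) abort("Need at least 3 pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("rho undefined: constant x or y.")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  new_gut_test(c(rho = unname(ct$estimate)), unname(ct$p.value),
               paste0("Spearman rank correlation (",
                      if (exact) "exact" else "t approximation", ")"))
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance computed
#' directly from the pairwise dissimilarities: total and within-group
#' sums of squared distances give the pseudo-F
#' \eqn{F = [(SS_T - SS_W)/(g-1)] / [SS_W/(n-g)]}; the p-value is the
#' fraction of label permutations (plus one, over `n_permutations + 1`)
#' whose pseudo-F reaches the observed one.
#'
#' @param d A [pairwise_distances()] result, `dist`, or square symmetric
#'   matrix.
#' @param labels Group label per sample (length n, >= 2 distinct values,
#'   no missing).
#' @param n_permutations Number of label permutations (default 10000).
#' @param seed Optional integer seed for the permutation stream.
#' @return A `gut_test`; `statistic` is the pseudo-F, with `r_squared`
#'   (SS_between / SS_total) attached.
#' @export
permanova <- function(d, labels, n_permutations = 10000, seed = NULL) {
  if (inherits(d, "gut_dist")) d <- unclass_dist(d)
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (length(labels) != n) abort("One label per sample required.")
  if (anyNA(labels)) abort("Labels must not be missing.")
  g <- factor(labels)
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  D2 <- d^2
  sst <- sum(D2) / (2 * n)
  ssw_of <- function(gi) {
    lv <- levels(gi)
    s <- 0
    for (l in lv) {
      idx <- gi == l
      s <- s + sum(D2[idx, idx]) / (2 * sum(idx))
    }
    s
  }
  ssw <- ssw_of(g)
  k <- nlevels(g)
  f_from_ssw <- function(w) ((sst - w) / (k - 1)) / (w / (n - k))
  f_obs <- f_from_ssw(ssw)
  # vectorised permutation null: indicator matmuls per group
  f_perm <- with_local_seed(seed, {
    perms <- replicate(n_permutations, sample.int(n))
    ssw_p <- numeric(n_permutations)
    for (l in levels(g)) {
      idx <- which(g == l)
      E <- matrix(0, n, n_permutations)
      E[cbind(as.vector(perms[idx, ]),
              rep(seq_len(n_permutations), each = length(idx)))] <- 1
      ssw_p <- ssw_p + colSums((D2 %*% E) * E) / (2 * length(idx))
    }
    f_from_ssw(ssw_p)
  })
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (n_permutations + 1)
  new_gut_test(c(`pseudo-F` = f_obs), p,
               "PERMANOVA (one-way, distance-based pseudo-F)",
               n_permutations = n_permutations, seed = seed,
               r_squared = (sst - ssw) / sst, df = c(k - 1, n - k))
}

# Evaluate `expr` under a local RNG stream: the global .Random.seed is
# saved and restored, so seeded tests never perturb user code.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
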