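# Compositional dissimilarities: Jensen-Shannon distance and Bray-Curtis.
#
# JSD(a, b) = sqrt(JSd(Pa, Pb)), JSd = KLD(x, m)/2 + KLD(y, m)/2 with
# m = (x + y)/2 and KLD in nats. Zeros are handled by adding a pseudocount
# (default 1e-7) to each distribution and renormalizing BEFORE forming m,
# so JSD is a true metric bounded by sqrt(ln 2) ~ 0.8326.

#' Kullback-Leibler divergence between two discrete distributions
#'
#' \eqn{KLD(x, y) = \sum_i x_i \log(x_i / y_i)} in nats (natural log).
#' Inputs must already be strictly positive (apply a pseudocount first);
#' this is the raw asymmetric divergence used inside [jsd()].
#'
#' @param x,y Numeric probability vectors of equal length, strictly
#'   positive, each summing to 1.
#' @return Nonnegative divergence in nats; 0 iff `x == y`.
#' @export
kld <- function(x, y) {
  if (length(x) != length(y)) abort("kld: length mismatch.")
  if (any(x <= 0) || any(y <= 0)) {
    abort("kld: zero or negative entry; apply a pseudocount first.")
  }
  sum(x * log(x / y))
}

# Pseudocount + renormalize a vector or a samples-x-families matrix.
pseudocount_normalize <- function(p, pseudocount) {
  if (is.matrix(p)) {
    p <- p + pseudocount
    p / rowSums(p)
  } else {
    p <- p + pseudocount
    p / sum(p)
  }
}

#' Jensen-Shannon distance between two compositions
#'
#' The square root of the Jensen-Shannon divergence between two abundance
#' profiles, the beta-diversity measure commonly used for enterotype
#' analysis. A pseudocount is added to every entry of each profile and the
#' profiles renormalized before the divergence is computed, so zero
#' abundances are safe. Values lie in `[0, sqrt(ln 2)]`; higher means more
#' different compositions.
#'
#' @param a,b Numeric relative-abundance vectors over the same ordered
#'   family list (equal length). Named vectors must share names.
#' @param pseudocount Constant added to every entry before renormalizing
#'   (default `1e-7`).
#' @return JSD value in `[0, sqrt(ln 2)]`.
#' @examples
#' jsd(c(0.5, 0.5), c(0.25, 0.75))  # ~0.1839
#' @export
jsd <- function(a, b, pseudocount = 1e-7) {
  check_same_families(a, b)
  x <- pseudocount_normalize(a, pseudocount)
  y <- pseudocount_normalize(b, pseudocount)
  m <- (x + y) / 2
  # rounding can push the divergence a hair below 0 for near-equal inputs
  sqrt(max(kld(x, m) / 2 + kld(y, m) / 2, 0))
}

#' Bray-Curtis dissimilarity between two compositions
#'
#' \eqn{1 - 2 \sum_i \min(a_i, b_i) / \sum_i (a_i + b_i)}, the quantitative
#' Bray-Curtis form on relative abundances, in `[0, 1]`. No pseudocount is
#' applied (the formula is zero-safe).
#'
#' @inheritParams jsd
#' @return Dissimilarity in `[0, 1]`; 0 iff `a == b`, 1 for disjoint
#'   supports.
#' @export
bray_curtis <- function(a, b) {
  check_same_families(a, b)
  1 - 2 * sum(pmin(a, b)) / sum(a + b)
}

check_same_families <- function(a, b) {
  if (length(a) != length(b)) abort("Profiles are on different family lists.")
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))) {
    abort("Profiles are on different family lists (names differ).")
  }
  invisible(TRUE)
}

metric_fun <- function(metric) {
  metric <- match.arg(metric, c("jsd", "bcd"))
  if (metric == "jsd") function(a, b) jsd(a, b) else bray_curtis
}

new_gut_dist <- function(m, metric) {
  structure(m, metric = metric, class = c("gut_dist", "matrix", "array"))
}

unclass_dist <- function(x) {
  attr(x, "metric") <- NULL
  class(x) <- NULL
  x
}

#' @export
print.gut_dist <- function(x, ...) {
  cat("<gut_dist> ", nrow(x), " samples, metric: ", attr(x, "metric"),
      "\n", sep = "")
  print(unclass_dist(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' @export
as.matrix.gut_dist <- function(x, ...) unclass_dist(x)

#' Tidy a distance matrix into one row per unordered sample pair
#' @param x A `gut_dist` object.
#' @param ... Unused.
#' @return A tibble with columns `sample_a`, `sample_b`, `distance`.
#' @export
as_tibble.gut_dist <- function(x, ...) {
  m <- unclass_dist(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(sample_a = rownames(m)[idx[, 1]],
                 sample_b = colnames(m)[idx[, 2]],
                 distance = m[idx])
}

#' All pairwise distances between cohort samples
#'
#' Computes the full symmetric sample-by-sample distance matrix under the
#' chosen metric; entry (i, j) equals the elementwise [jsd()] or
#' [bray_curtis()] call on the two profiles.
#'
#' @param cohort A [gut_cohort()] with at least 2 samples.
#' @param metric `"jsd"` (default) or `"bcd"`.
#' @param pseudocount Pseudocount for the JSD metric.
#' @return A `gut_dist` object: symmetric matrix with zero diagonal,
#'   labelled by `sample_id`.
#' @export
pairwise_distances <- function(cohort, metric = c("jsd", "bcd"),
                               pseudocount = 1e-7) {
  metric <- match.arg(metric)
  p <- abundance_matrix(cohort)
  if (nrow(p) < 2) abort("Need at least 2 samples.")
  if (metric == "jsd") {
    m <- jsd_cross(p, p, pseudocount)
  } else {
    m <- bcd_cross(p, p)
  }
  # enforce exact symmetry / zero diagonal against rounding
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(rownames(p), rownames(p))
  new_gut_dist(m, metric = metric)
}

# Vectorised cross-distance blocks (rows of `pa` vs rows of `pb`).
# plogp terms are accumulated per pair; x*log(x) with x > 0 after the
# pseudocount, so no special-casing is needed.
jsd_cross <- function(pa, pb, pseudocount) {
  x <- pseudocount_normalize(pa, pseudocount)
  y <- pseudocount_normalize(pb, pseudocount)
  hx <- rowSums(x * log(x))   # -entropy of each row
  hy <- rowSums(y * log(y))
  out <- matrix(0, nrow(x), nrow(y))
  for (j in seq_len(nrow(y))) {
    m <- (x + rep(y[j, ], each = nrow(x))) / 2
    hm <- rowSums(m * log(m))
    jsdiv <- (hx + hy[j]) / 2 - hm
    out[, j] <- sqrt(pmax(jsdiv, 0))
  }
  out
}

bcd_cross <- function(pa, pb) {
  out <- matrix(0, nrow(pa), nrow(pb))
  for (j in seq_len(nrow(pb))) {
    mins <- rowSums(pmin(pa, rep(pb[j, ], each = nrow(pa))))
    sums <- rowSums(pa) + sum(pb[j, ])
    out[, j] <- 1 - 2 * mins / sums
  }
  out
}

#' Intra-individual distances between two collection waves
#'
#' One distance per subject sampled at both waves of `year_pair`
#' (same-subject, different-year). Subjects lacking either wave are
#' silently omitted: the eligible set, not an error.
#'
#' @param cohort A [gut_cohort()].
#' @param year_pair Integer pair `(t, u)` with `u > t`; default `c(1, 2)`,
#'   the consecutive first-to-second-year change.
#' @inheritParams pairwise_distances
#' @return A tibble with columns `subject_id`, `year_a`, `year_b`,
#'   `distance`, carrying attributes `kind = "intra"` and `metric`.
#' @export
intra_individual <- function(cohort, year_pair = c(1, 2),
                             metric = c("jsd", "bcd"), pseudocount = 1e-7) {
  metric <- match.arg(metric)
  year_pair <- as.integer(year_pair)
  if (length(year_pair) != 2 || year_pair[2] <= year_pair[1]) {
    abort("year_pair must be two increasing wave indices (t, u), u > t.")
  }
  md <- cohort$metadata
  a <- md[md$year_index == year_pair[1], c("sample_id", "subject_id")]
  b <- md[md$year_index == year_pair[2], c("sample_id", "subject_id")]
  both <- dplyr::inner_join(a, b, by = "subject_id",
                            suffix = c("_a", "_b"))
  p <- abundance_matrix(cohort)
  f <- metric_fun(metric)
  d <- purrr::map2_dbl(both$sample_id_a, both$sample_id_b,
                       function(i, j) if (metric == "jsd")
                         jsd(p[i, ], p[j, ], pseudocount)
                       else bray_curtis(p[i, ], p[j, ]))
  out <- tibble::tibble(subject_id = both$subject_id,
                        year_a = year_pair[1], year_b = year_pair[2],
                        distance = d)
  structure(out, kind = "intra", metric = metric)
}

#' Inter-individual distances within one collection wave
#'
#' All unordered distinct-subject pair distances among the samples of wave
#' `year` (n(n-1)/2 values for n subjects).
#'
#' @param cohort A [gut_cohort()].
#' @param year Integer wave index.
#' @inheritParams pairwise_distances
#' @return A tibble with columns `subject_a`, `subject_b`, `year`,
#'   `distance`, carrying attributes `kind = "inter"` and `metric`.
#' @export
inter_individual <- function(cohort, year = 1, metric = c("jsd", "bcd"),
                             pseudocount = 1e-7) {
  metric <- match.arg(metric)
  md <- cohort$metadata[cohort$metadata$year_index == as.integer(year), ]
  if (nrow(md) < 2) abort("Need at least 2 subjects sampled in that year.")
  p <- abundance_matrix(cohort)[md$sample_id, , drop = FALSE]
  m <- if (metric == "jsd") jsd_cross(p, p, pseudocount) else bcd_cross(p, p)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  out <- tibble::tibble(subject_a = md$subject_id[idx[, 1]],
                        subject_b = md$subject_id[idx[, 2]],
                        year = as.integer(year),
                        distance = m[idx])
  structure(out, kind = "inter", metric = metric)
}
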