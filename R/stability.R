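# Stability classification and persistence typology.
#
# A subject whose intra-individual JSD between consecutive yearly samples
# is >= 0.4 is classed "changed" (substantial compositional change,
# typically a replacement of the predominant families). 0.4 is the study
# default because it matches the median inter-individual JSD; for other
# cohorts derive_threshold() recomputes that median.

#' Threshold from inter-individual distances
#'
#' The median of the inter-individual distance distribution (midpoint of
#' the middle two values for even counts). Used to anchor the "substantial
#' change" cut-off; the packaged default stays at the fixed 0.4 unless you
#' pass a derived value explicitly.
#'
#' @param inter An [inter_individual()] tibble (or any data frame with a
#'   `distance` column).
#' @return The median distance (scalar).
#' @export
derive_threshold <- function(inter) {
  d <- inter$distance
  if (is.null(d) || length(d) == 0) abort("Empty inter-individual set.")
  median(d)
}

#' Classify subjects as stable vs changed
#'
#' A subject is `changed` iff its intra-individual distance is greater
#' than or equal to `threshold` (boundary inclusive: a distance of exactly
#' 0.4 counts as changed).
#'
#' @param intra An [intra_individual()] tibble (columns `subject_id`,
#'   `distance`).
#' @param threshold Positive cut-off; default 0.4.
#' @return A tibble `subject_id`, `distance`, `class`
#'   (factor stable/changed), with attributes `counts` (named integer
#'   vector) and `prevalence` (changed fraction).
#' @export
classify_stability <- function(intra, threshold = 0.4) {
  if (nrow(intra) == 0) abort("Empty intra-individual set.")
  if (!is.numeric(threshold) || threshold <= 0) {
    abort("threshold must be > 0.")
  }
  cls <- factor(ifelse(intra$distance >= threshold, "changed", "stable"),
                levels = c("stable", "changed"))
  out <- tibble::tibble(subject_id = intra$subject_id,
                        distance = intra$distance, class = cls)
  counts <- table(cls)
  structure(out,
            threshold = threshold,
            counts = setNames(as.integer(counts), names(counts)),
            prevalence = mean(cls == "changed"))
}

#' Persistence typology over three yearly waves
#'
#' For subjects with three consecutive yearly samples, combines the
#' first-to-second and second-to-third wave distances (and, for subjects
#' changed in both intervals, the first-to-third distance) into a
#' four-way typology:
#' \describe{
#'   \item{stable_both}{both interval distances below the threshold — no
#'     substantial change over the two years.}
#'   \item{transient}{exactly one interval at or above the threshold — a
#'     single substantial change.}
#'   \item{continuous_reverted}{both intervals at or above the threshold
#'     but the first-to-third distance below it: the composition returned
#'     to its initial state.}
#'   \item{continuous_progressive}{both intervals changed and the
#'     first-to-third distance also at or above the threshold: each wave
#'     markedly different.}
#' }
#'
#' @param distances A data frame with one row per subject and columns
#'   `subject_id`, `jsd_12`, `jsd_23` (both required for scoring) and
#'   `jsd_13` (needed only to subtype continuous subjects; if missing
#'   there the subtype is `NA` with a warning).
#' @param threshold Classification cut-off, default 0.4.
#' @return A tibble `subject_id`, `jsd_12`, `jsd_23`, `jsd_13`,
#'   `class_12`, `class_23`, `persistence`, with attributes `threshold`
#'   and `contingency` — the 2x2 table of counts with rows
#'   `class_12` changed/stable and columns `class_23` changed/stable.
#' @export
persistence <- function(distances, threshold = 0.4) {
  req <- c("subject_id", "jsd_12", "jsd_23")
  if (!all(req %in% names(distances))) {
    abort("`distances` needs columns subject_id, jsd_12, jsd_23.")
  }
  if (anyNA(distances$jsd_12) || anyNA(distances$jsd_23)) {
    abort("jsd_12 and jsd_23 must be present for all scored subjects.")
  }
  d <- tibble::as_tibble(distances)
  if (!"jsd_13" %in% names(d)) d$jsd_13 <- NA_real_
  lab <- function(x) factor(ifelse(x >= threshold, "changed", "stable"),
                            levels = c("stable", "changed"))
  d$class_12 <- lab(d$jsd_12)
  d$class_23 <- lab(d$jsd_23)
  both <- d$class_12 == "changed" & d$class_23 == "changed"
  pers <- character(nrow(d))
  pers[d$class_12 == "stable" & d$class_23 == "stable"] <- "stable_both"
  pers[xor(d$class_12 == "changed", d$class_23 == "changed")] <- "transient"
  pers[both & !is.na(d$jsd_13) & d$jsd_13 < threshold] <- "continuous_reverted"
  pers[both & !is.na(d$jsd_13) & d$jsd_13 >= threshold] <- "continuous_progressive"
  if (any(both & is.na(d$jsd_13))) {
    warn("jsd_13 missing for continuous subject(s); subtype set to NA.")
    pers[both & is.na(d$jsd_13)] <- NA_character_
  }
  d$persistence <- factor(pers, levels = c("stable_both", "transient",
                                           "continuous_reverted",
                                           "continuous_progressive"))
  tab <- table(class_12 = factor(d$class_12,
                                 levels = c("changed", "stable")),
               class_23 = factor(d$class_23,
                                 levels = c("changed", "stable")))
  out <- d[c("subject_id", "jsd_12", "jsd_23", "jsd_13",
             "class_12", "class_23", "persistence")]
  structure(out, threshold = threshold,
            contingency = unclass(tab))
}

#' Full per-subject stability report for a cohort
#'
#' Runs the whole classification pipeline: intra-individual JSD (and
#' Bray-Curtis for the first interval) per subject, two-class labels per
#' interval, and, for subjects with three waves, the persistence
#' typology.
#'
#' @param cohort A [gut_cohort()].
#' @param threshold Classification cut-off, default 0.4.
#' @param pseudocount Pseudocount for JSD.
#' @return A `stability_report` tibble, one row per subject with at least
#'   two consecutive waves: `subject_id`, `jsd_12`, `jsd_23`, `jsd_13`,
#'   `bcd_12`, `class_12`, `class_23`, `persistence` (`NA` where a third
#'   wave is absent). Attributes: `threshold`, `contingency` (for the
#'   three-wave subset, if any).
#' @export
stability_report <- function(cohort, threshold = 0.4, pseudocount = 1e-7) {
  j12 <- intra_individual(cohort, c(1, 2), "jsd", pseudocount)
  b12 <- intra_individual(cohort, c(1, 2), "bcd")
  base <- tibble::tibble(subject_id = j12$subject_id,
                         jsd_12 = j12$distance,
                         bcd_12 = b12$distance[match(j12$subject_id,
                                                     b12$subject_id)])
  has3 <- any(cohort$metadata$year_index >= 3)
  if (has3) {
    j23 <- intra_individual(cohort, c(2, 3), "jsd", pseudocount)
    j13 <- intra_individual(cohort, c(1, 3), "jsd", pseudocount)
    base$jsd_23 <- j23$distance[match(base$subject_id, j23$subject_id)]
    base$jsd_13 <- j13$distance[match(base$subject_id, j13$subject_id)]
  } else {
    base$jsd_23 <- NA_real_
    base$jsd_13 <- NA_real_
  }
  lab <- function(x) factor(ifelse(x >= threshold, "changed", "stable"),
                            levels = c("stable", "changed"))
  base$class_12 <- lab(base$jsd_12)
  base$class_23 <- lab(base$jsd_23)
  scored <- !is.na(base$jsd_23)
  base$persistence <- factor(NA_character_,
                             levels = c("stable_both", "transient",
                                        "continuous_reverted",
                                        "continuous_progressive"))
  contingency <- NULL
  if (any(scored)) {
    p <- persistence(base[scored, c("subject_id", "jsd_12", "jsd_23",
                                    "jsd_13")],
                     threshold = threshold)
    base$persistence[scored] <- p$persistence
    contingency <- attr(p, "contingency")
  }
  out <- base[c("subject_id", "jsd_12", "jsd_23", "jsd_13", "bcd_12",
                "class_12", "class_23", "persistence")]
  structure(out, threshold = threshold, contingency = contingency,
            class = c("stability_report", class(out)))
}

#' Per-family abundance change between two waves
#'
#' Signed change in relative abundance of each family per subject,
#' `abundance(year u) - abundance(year t)`. Because both profiles sum to
#' 1, the deltas of each subject sum to 0; families gaining abundance are
#' balanced by families losing it.
#'
#' @param cohort A [gut_cohort()].
#' @param year_pair Integer pair `(t, u)`, `u > t`; default `c(1, 2)`.
#' @return A tibble `subject_id`, `family`, `delta`, with a
#'   `family_medians` attribute (named per-family median delta — near 0
#'   when no cohort-wide directional shift exists).
#' @export
family_deltas <- function(cohort, year_pair = c(1, 2)) {
  year_pair <- as.integer(year_pair)
  if (year_pair[2] <= year_pair[1]) abort("year_pair must be increasing.")
  md <- cohort$metadata
  a <- md[md$year_index == year_pair[1], c("sample_id", "subject_id")]
  b <- md[md$year_index == year_pair[2], c("sample_id", "subject_id")]
  both <- dplyr::inner_join(a, b, by = "subject_id", suffix = c("_a", "_b"))
  if (nrow(both) == 0) abort("No subjects sampled at both waves.")
  p <- abundance_matrix(cohort)
  dmat <- p[both$sample_id_b, , drop = FALSE] -
    p[both$sample_id_a, , drop = FALSE]
  out <- tibble::tibble(subject_id = rep(both$subject_id,
                                         each = ncol(dmat)),
                        family = rep(colnames(dmat), times = nrow(dmat)),
                        delta = as.vector(t(dmat)))
  structure(out, family_medians = apply(dmat, 2, median))
}
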