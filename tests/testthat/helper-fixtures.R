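# Fixtures are built in code: random simplex profiles and a small
# hand-sized cohort used across the io/distance/stability tests.

random_profile <- function(n_families = 8) {
  x <- -log(runif(n_families))  # Dirichlet(1, ..., 1)
  x / sum(x)
}

# A cohort of n subjects x 2-3 waves with Dirichlet-uniform profiles.
random_cohort <- function(n_subjects = 6, n_families = 5, waves = 2) {
  fams <- paste0("Fam", seq_len(n_families))
  meta <- tidyr::expand_grid(subject_id = sprintf("S%02d",
                                                  seq_len(n_subjects)),
                             year_index = seq_len(waves))
  meta$sample_id <- paste0(meta$subject_id, "_Y", meta$year_index)
  ab <- t(replicate(nrow(meta), random_profile(n_families)))
  colnames(ab) <- fams
  gut_cohort(dplyr::bind_cols(tibble::tibble(sample_id = meta$sample_id),
                              tibble::as_tibble(as.data.frame(ab))),
             meta[c("sample_id", "subject_id", "year_index")])
}

# Independent slow-path JSD oracle: literal equation chain, scalar sums.
jsd_oracle <- function(a, b, pseudocount = 1e-7) {
  x <- a + pseudocount; x <- x / sum(x)
  y <- b + pseudocount; y <- y / sum(y)
  m <- (x + y) / 2
  kl <- function(p, q) {
    s <- 0
    for (i in seq_along(p)) s <- s + p[i] * log(p[i] / q[i])
    s
  }
  sqrt(0.5 * kl(x, m) + 0.5 * kl(y, m))
}

# Two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities from log binomial coefficients
# (independent of dhyper).
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n):min(m, k)
  logp <- lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k)
  p <- exp(logp)
  obs <- p[supp == tab[1, 1]]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}
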