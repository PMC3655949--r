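# Independent brute-force oracles. These deliberately avoid the package's
# incremental-refinement / recurrence code paths: everything here is direct
# pairwise enumeration or direct probability evaluation.

# Pairwise-identity EHH oracle, O(n^2 m): among `members` (row indices),
# the fraction of pairs identical over the closed span [core..target].
oracle_ehh_span <- function(hap, members, core, target) {
  span <- seq(min(core, target), max(core, target))
  n <- length(members)
  if (n < 2) return(NA_real_)
  ident <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (all(hap[members[i], span] == hap[members[j], span])) ident <- ident + 1L
    }
  }
  ident / choose(n, 2)
}

# Allele-conditioned EHH oracle at every target.
oracle_ehh_curve <- function(hap, core, allele) {
  members <- which(hap[, core] == allele)
  if (length(members) < 2) return(rep(NA_real_, ncol(hap)))
  vapply(seq_len(ncol(hap)), function(t) oracle_ehh_span(hap, members, core, t), 0)
}

# Site EHHS oracle (all haplotypes, normalized at the core).
oracle_ehhs_curve <- function(hap, core) {
  members <- seq_len(nrow(hap))
  if (length(members) < 2) return(rep(NA_real_, ncol(hap)))
  h0 <- oracle_ehh_span(hap, members, core, core)
  if (h0 <= 0) return(rep(NA_real_, ncol(hap)))
  vapply(seq_len(ncol(hap)), function(t) oracle_ehh_span(hap, members, core, t), 0) / h0
}

# HWE exact-test oracle: direct evaluation of every heterozygote count's
# conditional probability from log-factorials, renormalized, then summed
# over configurations no more probable than the observed one.
oracle_hwe_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  x <- 2L * n_hom2 + n_het
  hets <- seq.int(x %% 2L, min(x, 2L * n - x), by = 2L)
  logp <- vapply(hets, function(h) {
    ha <- (x - h) / 2
    hb <- n - h - ha
    lfactorial(n) - lfactorial(ha) - lfactorial(h) - lfactorial(hb) +
      h * log(2) + lfactorial(x) + lfactorial(2L * n - x) - lfactorial(2L * n)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[p <= p[match(n_het, hets)] * (1 + 1e-12)])
}

# Random haplotype panel on a random marker map.
random_panel <- function(n_hap = 20, n_markers = 50, seed = 1,
                         chrom_len = n_markers * 5000) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_len, n_markers))
  mm <- marker_map(sprintf("m%03d", seq_len(n_markers)), "1", pos,
                   rep("A", n_markers), rep("G", n_markers), ancestral = "A")
  f <- runif(n_markers, 0.1, 0.9)
  hap <- matrix(rbinom(n_hap * n_markers, 1, rep(f, each = n_hap)), n_hap)
  # guarantee validity even for tiny panels
  haplotype_panel(hap, sprintf("s%02d", seq_len(n_hap %/% 2)), mm)
}

# Random complete genotype panel.
random_genotype_panel <- function(n_samples = 10, n_markers = 20, seed = 1) {
  hp <- random_panel(2 * n_samples, n_markers, seed)
  as_genotypes(hp)
}

as_polarized <- function(panel) polarize(panel, panel$markers)

# Genotype panel over an arbitrary call matrix with a generic marker map.
make_dense_panel <- function(calls) {
  m <- ncol(calls)
  genotype_panel(calls, sprintf("s%02d", seq_len(nrow(calls))),
                 marker_map(sprintf("m%05d", seq_len(m)), "1",
                            seq_len(m) * 100L, rep("A", m), rep("G", m)))
}
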