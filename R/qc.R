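#' Quality-control thresholds
#'
#' Defaults follow standard SNP-array practice for selection scans: markers
#' must have minor allele frequency >= 0.03, an exact Hardy-Weinberg test
#' P >= 1e-6 and call rate >= 90%; after marker filtering, samples with call
#' rate below 90% are dropped; pairs sharing more than 20% of alleles
#' identical-by-descent are pruned (removes duplicates ~1.0, parent-offspring
#' ~0.5 and half-sibs ~0.25 with margin).
#'
#' @param maf_min minimum minor allele frequency (inclusive).
#' @param hwe_p_min minimum exact HWE P-value (inclusive).
#' @param cr_snp_min minimum per-marker call rate (inclusive).
#' @param cr_ind_min minimum per-sample call rate (inclusive).
#' @param pi_hat_max maximum tolerated pairwise PI_HAT.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.03, hwe_p_min = 1e-6, cr_snp_min = 0.90,
                          cr_ind_min = 0.90, pi_hat_max = 0.20) {
  th <- list(maf_min = maf_min, hwe_p_min = hwe_p_min, cr_snp_min = cr_snp_min,
             cr_ind_min = cr_ind_min, pi_hat_max = pi_hat_max)
  stopifnot(all(unlist(th) >= 0), all(unlist(th) <= 1))
  structure(th, class = "qc_thresholds")
}

#' Per-marker minor allele frequency
#'
#' `min(f, 1 - f)` where `f` is the allele2 frequency among non-missing
#' calls. Markers with no non-missing call return `NA` (and fail QC).
#'
#' @param panel a [genotype_panel()].
#' @return Numeric vector, one entry per marker.
#' @export
compute_maf <- function(panel) {
  f <- allele2_freq(panel)
  pmin(f, 1 - f)
}

allele2_freq <- function(panel) {
  nn <- colSums(!is.na(panel$calls))
  f <- colSums(panel$calls, na.rm = TRUE) / (2 * nn)
  f[nn == 0L] <- NA_real_
  f
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the allele counts, the P-value is the sum of
#' the probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count. Well-defined at low counts,
#' unlike the chi-square approximation. Vectorised over genotype tables.
#'
#' @param n_hom1,n_het,n_hom2 non-negative integer genotype counts
#'   (allele1 homozygotes, heterozygotes, allele2 homozygotes).
#' @return P-values in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  mapply(hwe_exact_one, as.integer(n_hom1), as.integer(n_het), as.integer(n_hom2))
}

hwe_exact_one <- function(n1, nh, n2) {
  stopifnot(n1 >= 0L, nh >= 0L, n2 >= 0L)
  n <- n1 + nh + n2
  if (n == 0L) stop("empty genotype table")
  x <- 2L * n2 + nh                 # allele2 count
  if (x > n) x <- 2L * n - x       # work with the rarer allele
  hets <- seq.int(x %% 2L, min(x, 2L * n - x), by = 2L)
  if (length(hets) == 1L) return(1.0)
  # unnormalized log-probabilities via the standard recurrence:
  # P(h+2)/P(h) = 4 (x-h)/2 (2n-x-h)/2 / ((h+2)(h+1))
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1L]) {
    h <- hets[k - 1L]
    lp[k] <- lp[k - 1L] + log((x - h) / 2) + log((2L * n - x - h) / 2) +
      log(4) - log(h + 2) - log(h + 1)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(nh, hets)
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

#' Per-marker and per-sample call rates
#'
#' @param panel a [genotype_panel()].
#' @return List with `snp` (per-marker fraction of non-missing calls) and
#'   `ind` (per-sample fraction).
#' @export
call_rates <- function(panel) {
  list(snp = colMeans(!is.na(panel$calls)), ind = rowMeans(!is.na(panel$calls)))
}

#' Apply marker and sample quality control
#'
#' Order is fixed: (1) markers failing the MAF, HWE or call-rate filters are
#' dropped; (2) per-sample call rates are recomputed on the surviving markers
#' and failing samples dropped. All thresholds are inclusive. QC is intended
#' to run per population; the exact HWE test assumes a single randomly-mating
#' population and must never be applied to pooled panels.
#'
#' @param panel a [genotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @return List with `panel` (filtered) and `report` (counts per filter).
#' @export
apply_qc <- function(panel, thresholds = qc_thresholds()) {
  maf <- compute_maf(panel)
  cr <- call_rates(panel)
  nn <- colSums(!is.na(panel$calls))
  n_het <- colSums(panel$calls == 1L, na.rm = TRUE)
  n_hom2 <- colSums(panel$calls == 2L, na.rm = TRUE)
  hwe <- rep(NA_real_, n_markers(panel))
  ok_counts <- nn > 0L
  hwe[ok_counts] <- hwe_exact_p(nn[ok_counts] - n_het[ok_counts] - n_hom2[ok_counts],
                                n_het[ok_counts], n_hom2[ok_counts])
  fail_maf <- is.na(maf) | maf < thresholds$maf_min
  fail_hwe <- is.na(hwe) | hwe < thresholds$hwe_p_min
  fail_cr <- cr$snp < thresholds$cr_snp_min
  keep_m <- !(fail_maf | fail_hwe | fail_cr)
  report <- list(n_markers_in = n_markers(panel),
                 fail_maf = sum(fail_maf), fail_hwe = sum(fail_hwe),
                 fail_cr_snp = sum(fail_cr), markers_dropped = sum(!keep_m))
  if (!any(keep_m)) {
    e <- simpleError("all markers removed by QC")
    e$report <- report
    stop(e)
  }
  out <- subset_markers(panel, which(keep_m))
  cr_ind <- rowMeans(!is.na(out$calls))
  keep_s <- cr_ind >= thresholds$cr_ind_min
  report$fail_cr_ind <- sum(!keep_s)
  report$n_markers_out <- sum(keep_m)
  report$n_samples_out <- sum(keep_s)
  if (!all(keep_s)) out <- subset_samples(out, out$samples[keep_s])
  list(panel = out, report = report)
}

#' PLINK-style method-of-moments IBD estimate
#'
#' Estimates P(IBD = 0, 1, 2) for a sample pair from observed
#' identity-by-state counts and the panel's allele frequencies, and returns
#' `PI_HAT = P(IBD=2) + P(IBD=1)/2`, clamped to `[0, 1]`. Estimates based on
#' fewer than `min_markers` overlapping non-missing markers are flagged
#' unreliable.
#'
#' @param panel a [genotype_panel()].
#' @param pairs optional 2-column matrix/data.frame of sample ids; default is
#'   all pairs.
#' @param min_markers reliability floor on overlapping markers.
#' @return Data frame `sample_a`, `sample_b`, `pi_hat`, `n_markers`,
#'   `reliable`.
#' @export
estimate_pi_hat <- function(panel, pairs = NULL, min_markers = 100L) {
  s <- panel$samples
  if (is.null(pairs)) {
    if (length(s) < 2L) stop("need at least two samples")
    pairs <- t(utils::combn(s, 2L))
  }
  pairs <- as.matrix(pairs)
  p <- allele2_freq(panel)
  q <- 1 - p
  # expected IBS-state probabilities per marker, conditional on IBD state
  e0_ibs0 <- 2 * p^2 * q^2
  e0_ibs1 <- 4 * p^3 * q + 4 * p * q^3
  e0_ibs2 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibs1 <- 2 * p^2 * q + 2 * p * q^2
  e1_ibs2 <- p^3 + q^3 + p^2 * q + p * q^2
  informative <- !is.na(p) & p > 0 & p < 1
  res <- apply(pairs, 1L, function(pr) {
    ga <- panel$calls[match(pr[1], s), ]
    gb <- panel$calls[match(pr[2], s), ]
    use <- informative & !is.na(ga) & !is.na(gb)
    m <- sum(use)
    if (m == 0L) return(c(NA_real_, 0))
    ibs <- 2L - abs(ga[use] - gb[use])
    n_ibs <- tabulate(ibs + 1L, nbins = 3L)
    p0 <- n_ibs[1] / sum(e0_ibs0[use])
    p1 <- (n_ibs[2] - p0 * sum(e0_ibs1[use])) / sum(e1_ibs1[use])
    p2 <- (n_ibs[3] - p0 * sum(e0_ibs2[use]) - p1 * sum(e1_ibs2[use])) / m
    pr3 <- pmax(c(p0, p1, p2), 0)
    pr3 <- pr3 / sum(pr3)
    c(min(max(pr3[3] + pr3[2] / 2, 0), 1), m)
  })
  data.frame(sample_a = pairs[, 1], sample_b = pairs[, 2],
             pi_hat = res[1, ], n_markers = as.integer(res[2, ]),
             reliable = res[2, ] >= min_markers,
             stringsAsFactors = FALSE)
}

#' Prune related samples
#'
#' Greedy, deterministic removal: while any pair exceeds `pi_hat_max`, remove
#' the member involved in more such pairs; ties break toward the sample with
#' the lower call rate, then the lexicographically larger id.
#'
#' @param panel a [genotype_panel()].
#' @param estimates output of [estimate_pi_hat()] covering all pairs.
#' @param pi_hat_max threshold above which a pair is considered related.
#' @return The panel restricted to the retained samples, with the removed
#'   ids in attribute `removed`.
#' @export
prune_related <- function(panel, estimates, pi_hat_max = 0.20) {
  cr <- call_rates(panel)$ind
  names(cr) <- panel$samples
  active <- !is.na(estimates$pi_hat) & estimates$pi_hat > pi_hat_max
  edges <- estimates[active, c("sample_a", "sample_b")]
  removed <- character(0)
  while (nrow(edges) > 0L) {
    deg <- table(c(edges$sample_a, edges$sample_b))
    cand <- names(deg)[deg == max(deg)]
    if (length(cand) > 1L) {
      cand <- cand[cr[cand] == min(cr[cand])]
      cand <- min(cand)  # lexicographic tie-break
    }
    removed <- c(removed, cand)
    edges <- edges[edges$sample_a != cand & edges$sample_b != cand, , drop = FALSE]
  }
  out <- if (length(removed)) subset_samples(panel, setdiff(panel$samples, removed)) else panel
  structure(out, removed = removed)
}

#' Restrict panels to their shared markers
#'
#' After per-population QC, the scans use only markers passing QC in every
#' population. Original marker order is preserved.
#'
#' @param panels list of panels sharing a marker-id namespace.
#' @return List of panels restricted to the marker-id intersection.
#' @export
intersect_markers <- function(panels) {
  ids <- Reduce(intersect, lapply(panels, function(p) p$markers$marker_id))
  if (length(ids) == 0L) stop("no markers shared across panels")
  lapply(panels, function(p) subset_markers(p, p$markers$marker_id %in% ids))
}
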