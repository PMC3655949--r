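score_track <- function(markers, raw, z, p, test_name, focal_pop,
                        other_pop = NA_character_) {
  if (!identical(is.na(z), is.na(p)))
    stop("internal error: p must be present exactly where z is")
  out <- data.frame(marker_id = markers$marker_id, chrom = markers$chrom,
                    pos = markers$pos, raw = raw, z = z, p = p,
                    stringsAsFactors = FALSE)
  structure(out, class = c("score_track", "data.frame"),
            test_name = test_name, focal_pop = focal_pop, other_pop = other_pop)
}

#' @export
print.score_track <- function(x, ...) {
  nm <- attr(x, "test_name")
  op <- attr(x, "other_pop")
  cat(sprintf("score_track %s [%s%s]: %d markers, %d scored\n", nm,
              attr(x, "focal_pop"),
              if (!is.na(op)) paste0(" vs ", op) else "",
              nrow(x), sum(!is.na(x$z))))
  invisible(x)
}

#' Integrated haplotype score (iHS)
#'
#' Raw score `ln(iHH_A / iHH_D)` per marker (missing when either integral is
#' missing or zero, or when an allele has fewer than two carriers).
#' Standardization follows the canonical practice: markers are grouped into
#' `n_bins` derived-allele-frequency bins and each raw score is centred and
#' scaled by its bin's mean and standard deviation, so that extreme values
#' flag unusually long haplotypes relative to markers of comparable DAF.
#' Bins with fewer than two scored markers yield missing scores. Because
#' both tails are of interest, two-sided P-values are
#' `1 - 2|Phi(z) - 0.5|`.
#'
#' @param panel a [polarize()]d panel for one population.
#' @param policy an [integration_policy()].
#' @param n_bins number of DAF bins (default 20).
#' @param binning `"width"` (default): equal-width bins on (0,1);
#'   `"count"`: equal-count (quantile) bins.
#' @param scan optional precomputed [ehh_scan()] result.
#' @param pop population label stored on the track.
#' @return A `score_track` (columns `marker_id`, `chrom`, `pos`, `raw`,
#'   `z`, `p`).
#' @export
scan_ihs <- function(panel, policy = integration_policy(), n_bins = 20L,
                     binning = c("width", "count"), scan = NULL,
                     pop = "focal") {
  binning <- match.arg(binning)
  if (is.null(scan)) scan <- ehh_scan(panel, policy)
  raw <- ifelse(!is.na(scan$ihh_a) & !is.na(scan$ihh_d) &
                  scan$ihh_a > 0 & scan$ihh_d > 0,
                log(scan$ihh_a / scan$ihh_d), NA_real_)
  daf <- scan$daf
  raw[daf <= 0 | daf >= 1] <- NA_real_
  z <- standardize_binned(raw, daf, n_bins, binning)
  p <- 1 - 2 * abs(pnorm(z) - 0.5)
  score_track(panel$markers, raw, z, p, "iHS", pop)
}

standardize_binned <- function(raw, daf, n_bins, binning) {
  z <- rep(NA_real_, length(raw))
  scored <- which(!is.na(raw))
  if (!length(scored)) return(z)
  if (binning == "width") {
    edges <- seq(0, 1, length.out = n_bins + 1L)
  } else {
    edges <- unique(stats::quantile(daf[scored], probs = seq(0, 1, length.out = n_bins + 1L)))
    edges[1] <- 0; edges[length(edges)] <- 1
  }
  bin <- cut(daf[scored], breaks = edges, include.lowest = TRUE, labels = FALSE)
  for (b in unique(bin)) {
    idx <- scored[bin == b]
    if (length(idx) < 2L) next
    s <- sd(raw[idx])
    if (!is.finite(s) || s == 0) next
    z[idx] <- (raw[idx] - mean(raw[idx])) / s
  }
  z
}

#' Cross-population Rsb scan
#'
#' Raw score `ln(iES_focal / iES_other)` per marker, standardized with the
#' genome-wide median and standard deviation of the raw scores (no frequency
#' bins). Positive values flag selection in the focal (numerator)
#' population; one-sided upper-tail P-values are `1 - Phi(z)`.
#'
#' @param focal,other [polarize()]d panels sharing the same markers.
#' @param policy an [integration_policy()].
#' @param scan_focal,scan_other optional precomputed [ehh_scan()] results.
#' @param pops character of length 2: labels for the focal and other
#'   populations.
#' @return A `score_track`.
#' @export
scan_rsb <- function(focal, other, policy = integration_policy(),
                     scan_focal = NULL, scan_other = NULL,
                     pops = c("focal", "other")) {
  if (is.null(scan_focal)) scan_focal <- ehh_scan(focal, policy)
  if (is.null(scan_other)) scan_other <- ehh_scan(other, policy)
  if (!identical(scan_focal$marker_id, scan_other$marker_id))
    stop("panels must share the same markers")
  ok <- !is.na(scan_focal$ies) & !is.na(scan_other$ies) &
    scan_focal$ies > 0 & scan_other$ies > 0
  raw <- ifelse(ok, log(scan_focal$ies / scan_other$ies), NA_real_)
  z <- standardize_median(raw, "Rsb")
  p <- pnorm(z, lower.tail = FALSE)
  p[is.na(z)] <- NA_real_
  score_track(focal$markers, raw, z, p, "Rsb", pops[1], pops[2])
}

standardize_median <- function(raw, what) {
  scored <- !is.na(raw)
  s <- sd(raw[scored])
  if (!sum(scored) || !is.finite(s) || s == 0)
    stop(what, " scores are degenerate (zero variance); cannot standardize")
  ifelse(scored, (raw - median(raw[scored])) / s, NA_real_)
}

#' Between-population difference in derived allele frequency
#'
#' Raw score `DAF_focal - DAF_other` in `[-1, 1]`, standardized by the raw
#' distribution's mean and standard deviation; one-sided upper-tail
#' P-values.
#'
#' @inheritParams scan_rsb
#' @return A `score_track`.
#' @export
scan_ddaf <- function(focal, other, pops = c("focal", "other")) {
  stopifnot(inherits(focal, "polarized_panel"), inherits(other, "polarized_panel"))
  if (!identical(focal$markers$marker_id, other$markers$marker_id))
    stop("panels must share the same markers")
  raw <- focal$daf - other$daf
  s <- sd(raw)
  if (!is.finite(s) || s == 0)
    stop("dDAF scores are degenerate (zero variance); cannot standardize")
  z <- (raw - mean(raw)) / s
  p <- pnorm(z, lower.tail = FALSE)
  score_track(focal$markers, raw, z, p, "dDAF", pops[1], pops[2])
}

#' Site heterozygosity depression score (SHp)
#'
#' Per-marker observed heterozygosity (fraction of heterozygous individuals
#' among those genotyped) is standardized genome-wide and negated, so that
#' large positive values flag local depressions of diploid heterozygosity --
#' a per-site adaptation of the windowed ZHp statistic. One-sided upper-tail
#' P-values.
#'
#' @param panel a [genotype_panel()], or a [haplotype_panel()] whose
#'   haplotypes are re-paired by sample (heterozygosity is a diploid
#'   concept).
#' @param pop population label stored on the track.
#' @return A `score_track`.
#' @export
scan_shp <- function(panel, pop = "focal") {
  if (inherits(panel, "haplotype_panel")) panel <- as_genotypes(panel)
  stopifnot(inherits(panel, "genotype_panel"))
  nn <- colSums(!is.na(panel$calls))
  if (any(nn == 0L)) stop("SHp requires at least one non-missing genotype per marker")
  h_obs <- colSums(panel$calls == 1L, na.rm = TRUE) / nn
  s <- sd(h_obs)
  if (!is.finite(s) || s == 0)
    stop("observed heterozygosity is constant; cannot standardize SHp")
  shp <- -(h_obs - mean(h_obs)) / s
  p <- pnorm(shp, lower.tail = FALSE)
  score_track(panel$markers, unname(h_obs), unname(shp), unname(p), "SHp", pop)
}
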