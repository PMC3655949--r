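#' Synthetic panel configuration
#'
#' Defines the study conditions for the seeded generator. Each marker's
#' minor-allele frequency is drawn from a Beta distribution (default the
#' U-shaped Beta(0.5, 0.5), echoing a neutral site-frequency spectrum)
#' truncated to `freq_range`, so every simulated marker would pass a
#' MAF-style filter by construction; the derived allele is then the minor or
#' the major allele with equal probability (outgroup polarization does not
#' constrain the derived allele to be rare, and DAF must span (0,1) for the
#' 20-bin iHS standardization to be meaningful). The same per-marker derived
#' frequency is shared by all populations (common ancestral polymorphism),
#' with per-population haplotypes drawn independently around it.
#'
#' @param n_pops number of populations (default 2).
#' @param n_haplotypes phased haplotypes per population (2N, default 50).
#' @param n_markers markers per panel (default 20000).
#' @param chrom_length_bp chromosome length in bp (default 1e8, giving a
#'   realistic SNP-array density of ~5 kb between markers at the default
#'   marker count).
#' @param freq_shape Beta shape pair for the minor-allele-frequency spectrum.
#' @param freq_range truncation interval for the minor-allele frequency
#'   (default `[0.03, 0.5]`).
#' @param missing_rate missing-call rate applied when genotype panels are
#'   derived with [degrade_genotypes()].
#' @param ld optional list `list(n_founders, switch_rate)` enabling the
#'   haplotype-copying variant with background LD (default off: sites are
#'   independent, which gives an analytically known null).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 2L, n_haplotypes = 50L, n_markers = 20000L,
                       chrom_length_bp = 1e8, freq_shape = c(0.5, 0.5),
                       freq_range = c(0.03, 0.5), missing_rate = 0,
                       ld = NULL, seed = 1L) {
  stopifnot(n_pops >= 1, n_haplotypes >= 2, n_markers >= 2,
            chrom_length_bp > n_markers, missing_rate >= 0, missing_rate <= 1,
            freq_range[1] > 0, freq_range[2] <= 1, freq_range[1] < freq_range[2])
  structure(list(n_pops = as.integer(n_pops),
                 n_haplotypes = as.integer(n_haplotypes),
                 n_markers = as.integer(n_markers),
                 chrom_length_bp = chrom_length_bp, freq_shape = freq_shape,
                 freq_range = freq_range, missing_rate = missing_rate,
                 ld = ld, seed = as.integer(seed)),
            class = "sim_config")
}

rbeta_trunc <- function(n, shape, range) {
  lo <- stats::pbeta(range[1], shape[1], shape[2])
  hi <- stats::pbeta(range[2], shape[1], shape[2])
  stats::qbeta(lo + runif(n) * (hi - lo), shape[1], shape[2])
}

#' Simulate neutral multi-population panels
#'
#' Marker positions are uniform on the chromosome (sorted, deduplicated);
#' each marker's true derived-allele frequency comes from the configured
#' MAF spectrum (minor/major assignment at random, see [sim_config()]) and
#' is shared across populations; haplotypes are drawn site-independently
#' (no LD) unless the copying variant is enabled. The
#' true ancestral allele is `allele1` ("A") at every marker, recorded in the
#' returned marker map, so the panels are already coded 1 = derived.
#'
#' @param config a [sim_config()].
#' @return List with `panels` (named [haplotype_panel()]s `pop1`, `pop2`,
#'   ...), `markers` (marker map with the true ancestral alleles) and
#'   `truth` (list: `freq`, the per-marker derived frequencies drawn).
#' @export
simulate_neutral <- function(config = sim_config()) {
  set.seed(config$seed, kind = "Mersenne-Twister")
  M <- config$n_markers
  pos <- sort(sample.int(config$chrom_length_bp - 1L, M)) + 1L
  maf <- rbeta_trunc(M, config$freq_shape, config$freq_range)
  freq <- ifelse(runif(M) < 0.5, maf, 1 - maf)  # derived allele minor or major
  mm <- marker_map(sprintf("snp%06d", seq_len(M)), "1", pos,
                   rep("A", M), rep("G", M), ancestral = "A")
  H <- config$n_haplotypes
  panels <- lapply(seq_len(config$n_pops), function(k) {
    hap <- if (is.null(config$ld)) {
      matrix(rbinom(H * M, 1L, rep(freq, each = H)), nrow = H)
    } else {
      copy_process_haplotypes(H, M, freq, config$ld)
    }
    haplotype_panel(hap, sprintf("pop%d_s%03d", k, seq_len(H %/% 2L)), mm)
  })
  names(panels) <- paste0("pop", seq_len(config$n_pops))
  list(panels = panels, markers = mm, truth = list(freq = freq))
}

# Haplotype-copying variant with background LD: each haplotype walks along a
# pool of founder haplotypes, switching founders with a per-marker rate.
copy_process_haplotypes <- function(H, M, freq, ld) {
  n_founders <- ld$n_founders
  switch_rate <- ld$switch_rate
  founders <- matrix(rbinom(n_founders * M, 1L, rep(freq, each = n_founders)),
                     nrow = n_founders)
  hap <- matrix(0L, H, M)
  for (i in seq_len(H)) {
    f <- sample.int(n_founders, 1L)
    switches <- runif(M) < switch_rate
    for (j in seq_len(M)) {
      if (switches[j]) f <- sample.int(n_founders, 1L)
      hap[i, j] <- founders[f, j]
    }
  }
  hap
}

#' Sweep specification
#'
#' Parameters of an injected hard sweep: a derived allele at frequency `f`
#' whose carriers share one identical haplotype over `+/- L_bp` around the
#' target -- exactly the extended-homozygosity signature the scans detect.
#'
#' @param target_index marker index of the sweep core.
#' @param f derived-allele frequency at the core (default 0.8).
#' @param L_bp shared-haplotype half-length in bp (default 500 kb).
#' @param bg_switch_rate optional per-marker haplotype-copying switch rate:
#'   when set, non-carrier haplotypes inside the span are re-drawn by
#'   copying among themselves with this switch rate, a cheap proxy for
#'   background recombination/LD around the sweep (default: non-carriers
#'   keep their original draws).
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(target_index, f = 0.8, L_bp = 500000,
                       bg_switch_rate = NULL) {
  stopifnot(f > 0, f < 1, L_bp > 0,
            is.null(bg_switch_rate) ||
              (bg_switch_rate >= 0 && bg_switch_rate <= 1))
  structure(list(target_index = as.integer(target_index), f = f, L_bp = L_bp,
                 bg_switch_rate = bg_switch_rate),
            class = "sweep_spec")
}

#' Inject a hard sweep into a haplotype panel
#'
#' A fraction `f` of haplotypes are designated carriers: they receive the
#' derived allele at the target marker and an identical haplotype -- copied
#' from one carrier template -- at every marker within `+/- L_bp` of the
#' target; outside that span they keep their original independent draws.
#' Non-carriers are set ancestral at the target, so the realized derived
#' frequency is `round(f * 2N) / 2N`.
#'
#' @param panel a [haplotype_panel()] (coded 1 = derived).
#' @param spec a [sweep_spec()].
#' @return The modified panel, with attributes `carriers` (row indices) and
#'   `swept_markers` (column indices of the shared span).
#' @export
inject_sweep <- function(panel, spec) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(spec, "sweep_spec"))
  pos <- panel$markers$pos
  tpos <- pos[spec$target_index]
  if (tpos - spec$L_bp < min(pos) || tpos + spec$L_bp > max(pos))
    stop("sweep target must lie at least L_bp from both chromosome ends")
  span <- which(abs(pos - tpos) <= spec$L_bp)
  H <- nrow(panel$hap)
  n_car <- round(spec$f * H)
  stopifnot(n_car >= 2, n_car < H)
  carriers <- sample.int(H, n_car)
  template <- panel$hap[carriers[1], span]
  template[span == spec$target_index] <- 1L
  hap <- panel$hap
  hap[carriers, span] <- matrix(template, n_car, length(span), byrow = TRUE)
  non_carriers <- setdiff(seq_len(H), carriers)
  if (!is.null(spec$bg_switch_rate) && length(non_carriers) >= 2L) {
    donors <- panel$hap[non_carriers, span, drop = FALSE]
    for (i in seq_along(non_carriers)) {
      d <- sample.int(nrow(donors), 1L)
      sw <- runif(length(span)) < spec$bg_switch_rate
      for (j in seq_along(span)) {
        if (sw[j]) d <- sample.int(nrow(donors), 1L)
        hap[non_carriers[i], span[j]] <- donors[d, j]
      }
    }
  }
  hap[non_carriers, spec$target_index] <- 0L
  out <- haplotype_panel(hap, panel$samples, panel$markers)
  attr(out, "carriers") <- sort(carriers)
  attr(out, "swept_markers") <- span
  out
}

#' Simulate outgroup genotypes consistent with a true ancestral state
#'
#' Emulates the outgroup panel used for ancestral-allele discovery: each
#' outgroup sample is homozygous for the true ancestral allele at every
#' marker; missing calls are then introduced at `missing_rate` and
#' heterozygous "contamination" (residual outgroup polymorphism or
#' genotyping error) at `contamination_rate`, per call.
#'
#' @param markers a [marker_map()] whose `ancestral` column is the truth.
#' @param species named integer vector of samples per outgroup species.
#' @param missing_rate,contamination_rate per-call rates in `[0, 1]`.
#' @param seed integer seed.
#' @return An `outgroup_pool` (see [pool_outgroups()]).
#' @export
simulate_outgroups <- function(markers,
                               species = c(gaur = 2L, water_buffalo = 6L, yak = 2L),
                               missing_rate = 0, contamination_rate = 0,
                               seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            contamination_rate >= 0, contamination_rate <= 1,
            all(!is.na(markers$ancestral)))
  set.seed(seed, kind = "Mersenne-Twister")
  M <- nrow(markers)
  anc_code <- ifelse(markers$ancestral == markers$allele1, 0L, 2L)
  panels <- lapply(names(species), function(sp) {
    n <- species[[sp]]
    calls <- matrix(rep(anc_code, each = n), nrow = n)
    contam <- matrix(runif(n * M) < contamination_rate, n, M)
    calls[contam] <- 1L
    miss <- matrix(runif(n * M) < missing_rate, n, M)
    calls[miss] <- NA_integer_
    genotype_panel(calls, sprintf("%s_%02d", sp, seq_len(n)), markers)
  })
  names(panels) <- names(species)
  pool_outgroups(panels)
}

#' Introduce missing genotype calls
#'
#' Degrades a complete genotype panel for QC testing: each call is set
#' missing independently with probability `missing_rate`.
#'
#' @param panel a [genotype_panel()].
#' @param missing_rate per-call missing probability.
#' @param seed integer seed.
#' @return The degraded panel (phase information dropped).
#' @export
degrade_genotypes <- function(panel, missing_rate, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  set.seed(seed, kind = "Mersenne-Twister")
  calls <- panel$calls
  calls[matrix(runif(length(calls)) < missing_rate, nrow(calls))] <- NA_integer_
  genotype_panel(calls, panel$samples, panel$markers)
}
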