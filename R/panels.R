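#' Marker map
#'
#' A per-marker table of genomic coordinates and allele labels, shared by all
#' panel containers. Positions are 1-based bp and must be strictly increasing
#' within each chromosome. The optional `ancestral` column records the
#' outgroup-determined ancestral allele and must match one of the two allele
#' labels where set.
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based bp positions.
#' @param allele1,allele2 single-character allele labels (`allele1 != allele2`).
#' @param ancestral optional character vector; each entry one of the marker's
#'   two alleles, or `NA` when no ancestral call is available.
#' @return A `marker_map` data frame.
#' @export
marker_map <- function(marker_id, chrom, pos, allele1, allele2, ancestral = NA_character_) {
  mm <- data.frame(
    marker_id = as.character(marker_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    allele1 = as.character(allele1),
    allele2 = as.character(allele2),
    ancestral = rep_len(as.character(ancestral), length(marker_id)),
    stringsAsFactors = FALSE
  )
  class(mm) <- c("marker_map", "data.frame")
  validate_marker_map(mm)
  mm
}

validate_marker_map <- function(mm) {
  stopifnot(is.data.frame(mm))
  if (anyDuplicated(mm$marker_id)) stop("duplicated marker_id in marker map")
  if (any(mm$allele1 == mm$allele2)) stop("allele1 must differ from allele2")
  for (ch in unique(mm$chrom)) {
    p <- mm$pos[mm$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chrom ", ch)
  }
  bad <- !is.na(mm$ancestral) & mm$ancestral != mm$allele1 & mm$ancestral != mm$allele2
  if (any(bad)) stop("ancestral allele not among the marker's two alleles for ",
                     sum(bad), " marker(s)")
  invisible(mm)
}

#' Diploid genotype panel
#'
#' Genotypes are coded as counts of `allele2` (0, 1, 2), with `NA` for missing
#' calls. When the source data were phased, the `first_allele` matrix records
#' each sample's first phased allele (0 = allele1, 1 = allele2) so the panel
#' can be lifted to haplotypes with [to_haplotypes()].
#'
#' @param calls integer N x M matrix of allele2 counts in `{0,1,2}`, `NA`
#'   for missing.
#' @param samples character vector of N sample ids.
#' @param markers a [marker_map()] with M rows.
#' @param first_allele optional integer N x M matrix (0/1/`NA`) of first
#'   phased alleles; required only to lift heterozygous calls to haplotypes.
#' @return A `genotype_panel` object.
#' @export
genotype_panel <- function(calls, samples, markers, first_allele = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(nrow(calls) == length(samples), ncol(calls) == nrow(markers))
  if (any(!is.na(calls) & (calls < 0L | calls > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (!is.null(first_allele)) {
    first_allele <- as.matrix(first_allele)
    storage.mode(first_allele) <- "integer"
    stopifnot(identical(dim(first_allele), dim(calls)))
  }
  dimnames(calls) <- list(samples, markers$marker_id)
  structure(list(calls = calls, samples = as.character(samples),
                 markers = markers, first_allele = first_allele),
            class = "genotype_panel")
}

#' Phased haplotype panel
#'
#' A binary 2N x M matrix: 0 = allele1, 1 = allele2, no missing values.
#' Rows `2k - 1` and `2k` are the two phased haplotypes of sample `k`.
#'
#' @param hap integer 2N x M matrix of 0/1.
#' @param samples character vector of N sample ids.
#' @param markers a [marker_map()] with M rows.
#' @return A `haplotype_panel` object.
#' @export
haplotype_panel <- function(hap, samples, markers) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  stopifnot(nrow(hap) == 2L * length(samples), ncol(hap) == nrow(markers))
  if (anyNA(hap) || any(hap != 0L & hap != 1L))
    stop("haplotype matrix must be 0/1 with no missing values")
  dimnames(hap) <- list(paste(rep(samples, each = 2L), 1:2, sep = "_"),
                        markers$marker_id)
  structure(list(hap = hap, samples = as.character(samples), markers = markers),
            class = "haplotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$samples), "samples x", nrow(x$markers),
      "markers;", sprintf("%.1f%% missing\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(if (inherits(x, "polarized_panel")) "polarized_panel:" else "haplotype_panel:",
      nrow(x$hap), "haplotypes x", nrow(x$markers), "markers\n")
  invisible(x)
}

#' Number of samples / markers in a panel
#' @param x a panel object.
#' @return integer count.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname n_samples
#' @export
n_markers <- function(x) nrow(x$markers)

#' Lift a phased genotype panel to haplotypes
#'
#' Requires complete data: the scan stages operate on fully phased panels,
#' and imputation is out of scope for this package.
#'
#' @param panel a [genotype_panel()] with no missing calls and phase
#'   information for every heterozygous call.
#' @return A [haplotype_panel()]; row `2k - 1` carries sample `k`'s first
#'   phased allele at every site.
#' @export
to_haplotypes <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (anyNA(panel$calls))
    stop("scan stages require complete phased input (missing calls present)")
  fa <- panel$first_allele
  if (is.null(fa)) fa <- matrix(NA_integer_, nrow(panel$calls), ncol(panel$calls))
  # homozygous calls phase themselves
  fa[panel$calls == 0L] <- 0L
  fa[panel$calls == 2L] <- 1L
  if (anyNA(fa[panel$calls == 1L]))
    stop("scan stages require complete phased input (unphased heterozygote present)")
  n <- nrow(panel$calls)
  hap <- matrix(0L, 2L * n, ncol(panel$calls))
  hap[seq(1L, 2L * n, by = 2L), ] <- fa
  hap[seq(2L, 2L * n, by = 2L), ] <- panel$calls - fa
  haplotype_panel(hap, panel$samples, panel$markers)
}

#' Re-pair haplotypes into a diploid genotype panel
#'
#' Inverse of [to_haplotypes()] up to phase: genotype = sum of the sample's
#' two haplotype rows. Used by the SHp scan, which is defined on diploid
#' heterozygosity.
#'
#' @param panel a [haplotype_panel()].
#' @return A [genotype_panel()] with phase retained in `first_allele`.
#' @export
as_genotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  odd <- seq(1L, nrow(panel$hap), by = 2L)
  genotype_panel(panel$hap[odd, , drop = FALSE] + panel$hap[odd + 1L, , drop = FALSE],
                 panel$samples, panel$markers,
                 first_allele = panel$hap[odd, , drop = FALSE])
}

#' Subset a panel by marker index or by sample
#'
#' @param panel a genotype or haplotype panel.
#' @param idx integer or logical index into the marker map.
#' @return A panel of the same class restricted to the selected markers.
#' @export
subset_markers <- function(panel, idx) {
  mm <- panel$markers[idx, , drop = FALSE]
  rownames(mm) <- NULL
  class(mm) <- c("marker_map", "data.frame")
  if (inherits(panel, "haplotype_panel")) {
    out <- haplotype_panel(panel$hap[, idx, drop = FALSE], panel$samples, mm)
    if (inherits(panel, "polarized_panel")) {
      out$daf <- panel$daf[idx]
      class(out) <- c("polarized_panel", class(out))
    }
    out
  } else {
    genotype_panel(panel$calls[, idx, drop = FALSE], panel$samples, mm,
                   first_allele = if (!is.null(panel$first_allele))
                     panel$first_allele[, idx, drop = FALSE])
  }
}

#' @rdname subset_markers
#' @param keep character vector of sample ids (genotype panels only).
#' @export
subset_samples <- function(panel, keep) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- match(keep, panel$samples)
  if (anyNA(idx)) stop("unknown sample id(s): ", paste(keep[is.na(idx)], collapse = ", "))
  genotype_panel(panel$calls[idx, , drop = FALSE], panel$samples[idx], panel$markers,
                 first_allele = if (!is.null(panel$first_allele))
                   panel$first_allele[idx, , drop = FALSE])
}
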