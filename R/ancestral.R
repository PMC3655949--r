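#' Pool outgroup genotype panels
#'
#' Stacks per-species outgroup panels (identical marker maps required) into a
#' single pooled panel, the unit on which ancestral alleles are called.
#'
#' @param panels named list of [genotype_panel()] objects, one per outgroup
#'   species.
#' @return An `outgroup_pool`: list with `panels` and the stacked `pooled`
#'   panel.
#' @export
pool_outgroups <- function(panels) {
  stopifnot(length(panels) >= 1L)
  mm <- panels[[1]]$markers
  for (p in panels)
    if (!identical(p$markers$marker_id, mm$marker_id))
      stop("outgroup panels must share an identical marker map")
  pooled <- genotype_panel(do.call(rbind, lapply(panels, `[[`, "calls")),
                           unlist(lapply(panels, `[[`, "samples"), use.names = FALSE),
                           mm)
  structure(list(panels = panels, pooled = pooled), class = "outgroup_pool")
}

#' Call ancestral alleles from pooled outgroups
#'
#' A marker receives an ancestral call if and only if every pooled outgroup
#' sample is genotyped (100% call rate on the pooled panel) and exactly one
#' allele is observed (monomorphic, MAF = 0); the single observed allele is
#' then taken as ancestral. Any second allele -- including a single
#' heterozygous outgroup sample -- counts as polymorphism and blocks the
#' call. Per-species call rates are reported for diagnostics but are not
#' used as filters.
#'
#' @param pool an `outgroup_pool` or a single pooled [genotype_panel()].
#' @return List with `markers` (marker map with `ancestral` filled in) and
#'   `summary` (named vector: `n_total`, `n_fully_typed`, `n_polymorphic`,
#'   `n_called`; always `n_called = n_fully_typed - n_polymorphic`), plus
#'   `species_call_rate` when species panels are available.
#' @export
call_ancestral <- function(pool) {
  panel <- if (inherits(pool, "outgroup_pool")) pool$pooled else pool
  stopifnot(inherits(panel, "genotype_panel"))
  calls <- panel$calls
  fully_typed <- colSums(is.na(calls)) == 0L
  ac2 <- colSums(calls, na.rm = TRUE)                 # allele2 count
  nn <- colSums(!is.na(calls))
  monomorphic <- ac2 == 0L | ac2 == 2L * nn           # exactly one allele seen
  called <- fully_typed & monomorphic & nn > 0L
  anc <- rep(NA_character_, ncol(calls))
  anc[called & ac2 == 0L] <- panel$markers$allele1[called & ac2 == 0L]
  anc[called & ac2 > 0L] <- panel$markers$allele2[called & ac2 > 0L]
  mm <- panel$markers
  mm$ancestral <- anc
  out <- list(markers = mm,
              summary = c(n_total = ncol(calls),
                          n_fully_typed = sum(fully_typed),
                          n_polymorphic = sum(fully_typed & !monomorphic),
                          n_called = sum(called)))
  if (inherits(pool, "outgroup_pool"))
    out$species_call_rate <- vapply(pool$panels,
                                    function(p) mean(!is.na(p$calls)), 0)
  out
}

#' Polarize a haplotype panel into ancestral/derived coding
#'
#' Recodes the binary matrix so that 1 means the derived allele: columns
#' whose ancestral call is `allele2` are bit-flipped; markers without an
#' ancestral call are dropped (counted in attribute `n_dropped`) -- the scan
#' stages use only polarizable markers. The derived allele frequency (DAF)
#' per marker is stored in `$daf`.
#'
#' @param panel a [haplotype_panel()].
#' @param markers optional marker map carrying the `ancestral` column
#'   (defaults to the panel's own map).
#' @return A `polarized_panel` (subclass of `haplotype_panel`) with `$daf`.
#' @export
polarize <- function(panel, markers = panel$markers) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!identical(markers$marker_id, panel$markers$marker_id))
    stop("marker map does not match the panel")
  keep <- which(!is.na(markers$ancestral))
  n_dropped <- n_markers(panel) - length(keep)
  if (length(keep) == 0L) stop("no marker has an ancestral call")
  hap <- panel$hap[, keep, drop = FALSE]
  mm <- markers[keep, , drop = FALSE]
  rownames(mm) <- NULL
  class(mm) <- c("marker_map", "data.frame")
  flip <- mm$ancestral == mm$allele2
  if (any(flip)) hap[, flip] <- 1L - hap[, flip]
  # relabel so allele1 = ancestral, allele2 = derived everywhere; keeps the
  # container invariant (0 = allele1) true and makes polarize idempotent
  derived <- ifelse(flip, mm$allele1, mm$allele2)
  mm$allele1 <- mm$ancestral
  mm$allele2 <- derived
  out <- haplotype_panel(hap, panel$samples, mm)
  out$daf <- unname(colMeans(hap))
  class(out) <- c("polarized_panel", class(out))
  attr(out, "n_dropped") <- n_dropped
  out
}
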