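#' Composite selection-signature scan for one focal population
#'
#' The package's top-level fitting function. Given polarized haplotype
#' panels for two or more populations on a shared marker set, it runs the
#' component tests for the focal population -- iHS and SHp within the
#' population, Rsb and dDAF against every other population -- and combines
#' their P-values into the per-marker meta-SS statistic with Bonferroni
#' thresholding.
#'
#' @param panels named list of [polarize()]d panels on identical markers.
#' @param focal name of the focal population (default: first panel).
#' @param tracks `"all"` (default), `"within"` (iHS + SHp only) or
#'   `"between"` (Rsb + dDAF only) -- the latter two are the sensitivity
#'   variants of the composite.
#' @param policy an [integration_policy()] for the EHH statistics.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param n_bins DAF bins for the iHS standardization.
#' @param two_sided report two-sided combined P-values (sensitivity only).
#' @return A `meta_scan` object: list with `focal`, `tracks` (named list of
#'   `score_track`s), `meta` (a [meta_ss()] result), `weights`, `threshold`
#'   and `call`. Methods: `print`, `summary`, `plot` (Manhattan),
#'   [significant()].
#' @examples
#' sim <- simulate_neutral(sim_config(n_markers = 500, n_haplotypes = 30, seed = 7))
#' pols <- lapply(sim$panels, polarize, markers = sim$markers)
#' fit <- meta_scan(pols, focal = "pop1")
#' print(fit)
#' head(significant(fit))
#' @export
meta_scan <- function(panels, focal = names(panels)[1],
                      tracks = c("all", "within", "between"),
                      policy = integration_policy(), alpha = 0.05,
                      n_bins = 20L, two_sided = FALSE) {
  tracks <- match.arg(tracks)
  stopifnot(is.list(panels), !is.null(names(panels)), focal %in% names(panels))
  if (length(panels) < 2L && tracks != "within")
    stop("between-population tests need at least two panels")
  ids <- panels[[1]]$markers$marker_id
  for (p in panels) {
    stopifnot(inherits(p, "polarized_panel"))
    if (!identical(p$markers$marker_id, ids))
      stop("panels must share identical markers (run intersect_markers/polarize first)")
  }
  others <- setdiff(names(panels), focal)
  scans <- list()
  scans[[focal]] <- ehh_scan(panels[[focal]], policy)
  if (tracks != "within")
    for (o in others) scans[[o]] <- ehh_scan(panels[[o]], policy)
  tr <- list()
  if (tracks != "between") {
    tr$iHS <- scan_ihs(panels[[focal]], policy, n_bins = n_bins,
                       scan = scans[[focal]], pop = focal)
    tr$SHp <- scan_shp(panels[[focal]], pop = focal)
  }
  if (tracks != "within") {
    for (o in others) {
      tr[[paste0("Rsb_", focal, "_vs_", o)]] <-
        scan_rsb(panels[[focal]], panels[[o]], policy,
                 scan_focal = scans[[focal]], scan_other = scans[[o]],
                 pops = c(focal, o))
      tr[[paste0("dDAF_", focal, "_vs_", o)]] <-
        scan_ddaf(panels[[focal]], panels[[o]], pops = c(focal, o))
    }
  }
  w <- stouffer_weights(tr)
  meta <- meta_ss(tr, weights = w, alpha = alpha, two_sided = two_sided)
  structure(list(focal = focal, tracks = tr, weights = setNames(w, names(tr)),
                 meta = meta, threshold = attr(meta, "threshold"),
                 alpha = alpha, n_snp = nrow(meta), call = match.call()),
            class = "meta_scan")
}

#' Significant markers of a scan
#'
#' @param x a `meta_scan` or `meta_result`.
#' @return The rows of the meta result passing the Bonferroni threshold,
#'   ordered by combined P.
#' @export
significant <- function(x) {
  m <- if (inherits(x, "meta_scan")) x$meta else x
  out <- as.data.frame(m)[which(m$significant), , drop = FALSE]
  out <- out[order(out$p_combined), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.meta_scan <- function(x, ...) {
  cat("Composite selection scan (meta-SS)\n")
  cat("  focal population:", x$focal, "\n")
  cat("  markers:", x$n_snp, " tracks:", paste(names(x$tracks), collapse = ", "), "\n")
  cat(sprintf("  Bonferroni threshold: P < %.3g (alpha = %g)\n",
              x$threshold, x$alpha))
  cat("  significant markers:", sum(x$meta$significant, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
summary.meta_scan <- function(object, n_top = 5L, ...) {
  cat("Composite selection scan (meta-SS) --", object$focal, "\n\n")
  cat("Component tracks (weights in parentheses):\n")
  for (nm in names(object$tracks)) {
    tr <- object$tracks[[nm]]
    cat(sprintf("  %-22s (w = %.3g): %d/%d markers scored\n", nm,
                object$weights[[nm]], sum(!is.na(tr$z)), nrow(tr)))
  }
  m <- object$meta
  cat(sprintf("\nmeta-SS: mean = %.3f, var = %.3f over %d markers\n",
              mean(m$S, na.rm = TRUE), stats::var(m$S, na.rm = TRUE),
              sum(!is.na(m$S))))
  cat(sprintf("Bonferroni threshold P < %.3g; %d significant marker(s)\n",
              object$threshold, sum(m$significant, na.rm = TRUE)))
  top <- m[order(m$p_combined), , drop = FALSE]
  top <- utils::head(top[!is.na(top$p_combined), ], n_top)
  cat("\nTop markers:\n")
  print.data.frame(top, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Manhattan plot of the combined P-values
#'
#' @param x a `meta_scan` object.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.meta_scan <- function(x, ...) {
  m <- x$meta
  chroms <- unique(m$chrom)
  offset <- c(0, cumsum(vapply(chroms, function(ch) max(m$pos[m$chrom == ch]), 0)))
  xpos <- m$pos + offset[match(m$chrom, chroms)]
  logp <- -log10(m$p_combined)
  col <- ifelse(match(m$chrom, chroms) %% 2 == 0, "grey40", "grey70")
  col[which(m$significant)] <- "red"
  plot(xpos, logp, pch = 20, cex = 0.5, col = col,
       xlab = "genome position (bp)",
       ylab = expression(-log[10](italic(P)[combined])),
       main = paste("meta-SS scan:", x$focal), ...)
  abline(h = -log10(x$threshold), lty = 2, col = "blue")
  invisible(x)
}

#' @export
plot.ehh_curve <- function(x, ...) {
  core <- attr(x, "core_index")
  plot(x$pos, x$ehh, type = "l", xlab = "position (bp)", ylab = "EHH",
       ylim = c(0, 1), main = paste0("EHH decay (", attr(x, "allele"),
                                     " allele, ", attr(x, "carrier_count"),
                                     " carriers)"), ...)
  abline(v = x$pos[core], lty = 3)
  invisible(x)
}
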