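#' Transform P-values to upper-tail Z-scores
#'
#' `Z = Phi^-1(1 - p)`: small P-values map to large positive Z, so evidence
#' of selection accumulates in the upper tail. P-values outside `(0, 1)` are
#' clamped with a warning: the lower bound is 1e-300, the upper bound the
#' largest double below 1 (1 - 1e-300 is indistinguishable from 1 at machine
#' precision).
#'
#' @param p probabilities.
#' @return Z-scores (strictly decreasing in `p`).
#' @export
p_to_z <- function(p) {
  out_of_range <- !is.na(p) & (p <= 0 | p >= 1)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " p-value(s) outside (0,1) clamped")
    p <- pmin(pmax(p, 1e-300), 1 - .Machine$double.eps / 2)
  }
  qnorm(p, lower.tail = FALSE)
}

#' Weighted Stouffer combination
#'
#' `S = sum(w * z) / sqrt(sum(w^2))` over the non-missing Z-scores; missing
#' tracks simply contribute nothing, with the denominator built from the
#' weights of the present tracks only, so `S` stays standard normal under
#' the null regardless of the missingness pattern. Invariant to track order
#' and to uniform rescaling of the weights.
#'
#' @param z numeric vector of Z-scores (may contain `NA`).
#' @param weights positive weights, recycled to `length(z)`.
#' @return The combined statistic, or `NA` when no track contributes.
#' @export
combine_z <- function(z, weights = 1) {
  w <- rep_len(weights, length(z))
  ok <- !is.na(z)
  if (!any(ok)) return(NA_real_)
  sum(w[ok] * z[ok]) / sqrt(sum(w[ok]^2))
}

#' Combined upper-tail P-value
#'
#' @param S meta-SS statistic(s).
#' @param two_sided use `2 * (1 - Phi(|S|))` instead of the default
#'   upper-tail `1 - Phi(S)` (sensitivity analysis only).
#' @return Probabilities.
#' @export
combined_p <- function(S, two_sided = FALSE) {
  if (two_sided) 2 * pnorm(abs(S), lower.tail = FALSE)
  else pnorm(S, lower.tail = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_snp number of markers tested.
#' @return `alpha / n_snp`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_snp) {
  stopifnot(n_snp >= 1)
  alpha / n_snp
}

#' Stouffer weights for a set of score tracks
#'
#' Within-population tests (iHS, SHp) run once per population and get weight
#' 1; each between-population comparison of a given test gets weight `1/n`,
#' where `n` is the number of comparisons of that test for the focal
#' population -- so each test contributes total weight 1 regardless of how
#' many populations it is compared against.
#'
#' @param tracks list of `score_track` objects for one focal population.
#' @return Numeric vector of weights, one per track.
#' @export
stouffer_weights <- function(tracks) {
  test <- vapply(tracks, attr, "", which = "test_name")
  between <- !is.na(vapply(tracks, attr, "", which = "other_pop"))
  w <- rep(1, length(tracks))
  for (tn in unique(test[between]))
    w[test == tn & between] <- 1 / sum(test == tn & between)
  w
}

#' Meta-analysis of selection signals (meta-SS)
#'
#' Combines the component tracks' P-values into one statistic per marker:
#' each P is transformed to an upper-tail Z with [p_to_z()], weighted per
#' [stouffer_weights()] (or explicit weights) and combined with
#' [combine_z()]; `S` is referred back to the standard normal for a
#' combined P, and markers are flagged significant under the Bonferroni
#' threshold `alpha / n_SNP` (with `n_SNP` the number of markers in the
#' scan).
#'
#' @param tracks list of `score_track` objects on identical markers.
#' @param weights optional explicit weights (default [stouffer_weights()]).
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param two_sided see [combined_p()].
#' @return A `meta_result` data frame (`marker_id`, `chrom`, `pos`, `S`,
#'   `p_combined`, `significant`) with attributes `threshold`, `weights`,
#'   `track_names` and `n_snp`.
#' @export
meta_ss <- function(tracks, weights = NULL, alpha = 0.05, two_sided = FALSE) {
  stopifnot(length(tracks) >= 1L)
  ids <- tracks[[1]]$marker_id
  for (tr in tracks)
    if (!identical(tr$marker_id, ids)) stop("tracks must share identical markers")
  if (is.null(weights)) weights <- stouffer_weights(tracks)
  stopifnot(length(weights) == length(tracks), all(weights > 0))
  zmat <- vapply(tracks, function(tr) p_to_z(tr$p), numeric(length(ids)))
  zmat <- matrix(zmat, nrow = length(ids))
  wmat <- matrix(weights, nrow = length(ids), ncol = length(tracks), byrow = TRUE)
  wmat[is.na(zmat)] <- NA_real_
  num <- rowSums(wmat * zmat, na.rm = TRUE)
  den <- sqrt(rowSums(wmat^2, na.rm = TRUE))
  S <- ifelse(den > 0, num / den, NA_real_)
  p <- combined_p(S, two_sided)
  thr <- bonferroni_threshold(alpha, length(ids))
  res <- data.frame(marker_id = ids, chrom = tracks[[1]]$chrom,
                    pos = tracks[[1]]$pos, S = S, p_combined = p,
                    significant = !is.na(p) & p < thr,
                    stringsAsFactors = FALSE)
  structure(res, class = c("meta_result", "data.frame"), threshold = thr,
            alpha = alpha, weights = weights, n_snp = length(ids),
            track_names = vapply(tracks, function(tr) {
              op <- attr(tr, "other_pop")
              paste0(attr(tr, "test_name"),
                     if (!is.na(op)) paste0("_", attr(tr, "focal_pop"), "_vs_", op))
            }, ""))
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta_result: %d markers, %d significant at P < %.3g (alpha = %g)\n",
              nrow(x), sum(x$significant, na.rm = TRUE), attr(x, "threshold"),
              attr(x, "alpha")))
  cat("tracks:", paste(attr(x, "track_names"), collapse = ", "), "\n")
  invisible(x)
}
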