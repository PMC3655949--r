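#' EHH integration policy
#'
#' Controls how EHH decay curves are integrated into iHH / iES. Integration
#' proceeds from the core outward on each side and stops at the first marker
#' whose EHH drops below `ehh_floor` (that marker is included as the final
#' trapezoid vertex). Under `border_rule = "discard"` the statistic is
#' missing when either side reaches the chromosome end before crossing the
#' floor, or when any inter-marker gap exceeds `max_gap_bp`; under
#' `"truncate"` the side is simply integrated as far as it goes.
#'
#' @param ehh_floor EHH value below which the curve is considered decayed
#'   (default 0.05).
#' @param max_gap_bp largest tolerated gap between consecutive markers
#'   (default 200 kb).
#' @param border_rule `"discard"` (default) or `"truncate"`.
#' @return An `integration_policy` list.
#' @export
integration_policy <- function(ehh_floor = 0.05, max_gap_bp = 200000L,
                               border_rule = c("discard", "truncate")) {
  stopifnot(ehh_floor >= 0, ehh_floor < 1, max_gap_bp > 0)
  structure(list(ehh_floor = ehh_floor, max_gap_bp = as.numeric(max_gap_bp),
                 border_rule = match.arg(border_rule)),
            class = "integration_policy")
}

#' EHH decay curve at one core marker
#'
#' Allele-conditioned EHH: among the haplotypes carrying `allele` at the
#' core, the probability that two randomly drawn carriers are identical over
#' the span from the core to the target marker (pair-count form
#' `sum C(n_h,2) / C(n,2)`). Site EHHS (`allele = "site"`): the same
#' homozygosity over all haplotypes, normalized to 1 at the core so that its
#' integral (iES) is comparable between populations.
#'
#' @param panel a [polarize()]d panel (or any [haplotype_panel()]; then
#'   "derived" means the allele coded 1).
#' @param core marker index (1-based) or marker id.
#' @param allele `"ancestral"`, `"derived"` or `"site"`.
#' @return An `ehh_curve` data frame (`index`, `pos`, `ehh`) with attributes
#'   `core_index`, `allele` and `carrier_count`; `ehh` is `NA` when the
#'   curve is undefined (fewer than two carriers, or zero core
#'   homozygosity).
#' @export
ehh <- function(panel, core, allele = c("derived", "ancestral", "site")) {
  stopifnot(inherits(panel, "haplotype_panel"))
  allele <- match.arg(allele)
  core <- resolve_marker(panel, core)
  mode <- if (allele == "site") 1L else 0L
  av <- if (allele == "derived") 1L else 0L
  vals <- ehh_curve_cpp(panel$hap, core - 1L, mode, av)
  carriers <- if (allele == "site") nrow(panel$hap) else sum(panel$hap[, core] == av)
  structure(data.frame(index = seq_len(n_markers(panel)),
                       pos = panel$markers$pos, ehh = vals),
            class = c("ehh_curve", "data.frame"),
            core_index = core, allele = allele, carrier_count = carriers)
}

resolve_marker <- function(panel, core) {
  if (is.character(core)) {
    i <- match(core, panel$markers$marker_id)
    if (is.na(i)) stop("unknown marker id: ", core)
    return(i)
  }
  stopifnot(core >= 1L, core <= n_markers(panel))
  as.integer(core)
}

#' Integrate an EHH curve (iHH / iES)
#'
#' Trapezoid rule over bp positions under an [integration_policy()]. This is
#' the reference R implementation used on exported curves; the genome scan
#' uses an equivalent C++ path ([ehh_scan()]).
#'
#' @param curve an [ehh()] curve, or a numeric vector of EHH values.
#' @param positions bp positions (taken from the curve when omitted).
#' @param core_index core marker index (taken from the curve when omitted).
#' @param policy an [integration_policy()].
#' @return The integral in bp x EHH units, or `NA` under the discard rule.
#' @export
integrate_ehh <- function(curve, positions = NULL, core_index = NULL,
                          policy = integration_policy()) {
  if (inherits(curve, "ehh_curve")) {
    positions <- curve$pos
    core_index <- attr(curve, "core_index")
    curve <- curve$ehh
  }
  if (anyNA(curve[core_index])) return(NA_real_)
  discard <- policy$border_rule == "discard"
  total <- 0
  for (dir in c(-1L, 1L)) {
    area <- 0
    prev_pos <- positions[core_index]
    prev_e <- curve[core_index]
    t <- core_index + dir
    crossed <- FALSE
    while (t >= 1L && t <= length(curve)) {
      gap <- abs(positions[t] - prev_pos)
      if (gap > policy$max_gap_bp) {
        if (discard) return(NA_real_)
        crossed <- TRUE  # truncate before the gap
        break
      }
      e <- curve[t]
      area <- area + gap * (prev_e + e) / 2
      if (e < policy$ehh_floor) { crossed <- TRUE; break }
      prev_pos <- positions[t]; prev_e <- e
      t <- t + dir
    }
    if (!crossed && discard) return(NA_real_)
    total <- total + area
  }
  total
}

#' Genome-wide EHH integrals
#'
#' Computes, for every marker of a polarized panel, the carrier counts and
#' the integrated EHH for the ancestral allele (iHH_A), the derived allele
#' (iHH_D) and the site (iES), using the C++ kernel.
#'
#' @param panel a [polarize()]d panel.
#' @param policy an [integration_policy()].
#' @return Data frame: `marker_id`, `chrom`, `pos`, `daf`, `n_anc`, `n_der`,
#'   `ihh_a`, `ihh_d`, `ies`.
#' @export
ehh_scan <- function(panel, policy = integration_policy()) {
  stopifnot(inherits(panel, "polarized_panel"))
  m <- ehh_scan_cpp(panel$hap, as.numeric(panel$markers$pos),
                    policy$ehh_floor, policy$max_gap_bp,
                    policy$border_rule == "discard")
  data.frame(marker_id = panel$markers$marker_id, chrom = panel$markers$chrom,
             pos = panel$markers$pos, daf = panel$daf,
             n_anc = as.integer(m[, "n_anc"]), n_der = as.integer(m[, "n_der"]),
             ihh_a = m[, "ihh_a"], ihh_d = m[, "ihh_d"], ies = m[, "ies"],
             stringsAsFactors = FALSE)
}

#' Haplotype bifurcation edge list
#'
#' The data behind a bifurcation diagram: starting from the haplotypes that
#' carry `allele` at the core, identity classes split as the span extends
#' marker by marker. Each split is an edge from the parent class to a child
#' class, annotated with the child's haplotype count and the marker position
#' at which the split is evaluated.
#'
#' @inheritParams ehh
#' @param sides `"both"`, `"left"` or `"right"`.
#' @return Data frame: `side`, `parent_node`, `child_node`,
#'   `haplotype_count`, `position`. Node 0 is the root (all carriers at the
#'   core).
#' @export
bifurcation <- function(panel, core, allele = c("derived", "ancestral"),
                        sides = c("both", "left", "right")) {
  stopifnot(inherits(panel, "haplotype_panel"))
  allele <- match.arg(allele)
  sides <- match.arg(sides)
  core <- resolve_marker(panel, core)
  av <- if (allele == "derived") 1L else 0L
  members <- which(panel$hap[, core] == av)
  if (length(members) < 2L) stop("fewer than two carriers of the ", allele,
                                 " allele at the core")
  edges <- list()
  for (dir in if (sides == "both") c(-1L, 1L) else if (sides == "left") -1L else 1L) {
    id <- rep(0L, length(members))
    next_node <- 1L
    node_of <- c(`0` = 0L)  # class label -> node id
    t <- core + dir
    while (t >= 1L && t <= n_markers(panel)) {
      key <- paste(id, panel$hap[members, t], sep = ".")
      uk <- unique(key)
      newid <- match(key, uk)
      for (k in seq_along(uk)) {
        parent_label <- sub("\\.[01]$", "", uk[k])
        parent_node <- node_of[[parent_label]]
        child_node <- next_node
        next_node <- next_node + 1L
        node_of[[as.character(child_node)]] <- child_node
        edges[[length(edges) + 1L]] <- data.frame(
          side = if (dir < 0) "left" else "right",
          parent_node = parent_node, child_node = child_node,
          haplotype_count = sum(key == uk[k]),
          position = panel$markers$pos[t])
      }
      # relabel classes by their node ids for the next step
      node_ids <- vapply(seq_along(uk), function(k) {
        e <- edges[[length(edges) - length(uk) + k]]; e$child_node
      }, 0)
      node_of <- setNames(as.list(node_ids), as.character(node_ids))
      id <- node_ids[newid]
      if (length(uk) == length(members)) break  # fully resolved
      t <- t + dir
    }
  }
  do.call(rbind, edges)
}
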