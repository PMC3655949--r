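#' Gene set
#'
#' Named genomic intervals used by the three annotation strategies.
#' Intervals are stored 0-based half-open (BED convention); [read_genes()]
#' converts 1-based GFF3 input accordingly. A marker at 1-based position
#' `p` lies in a gene iff `start <= p - 1 < end`, so the first base of a
#' gene is a hit and the base just past the end is not.
#'
#' @param id unique gene ids.
#' @param name gene symbols (defaults to `id`).
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds (`start < end`).
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return A `gene_set` data frame.
#' @export
gene_set <- function(id, name = id, chrom, start, end, strand = "*") {
  gs <- data.frame(id = as.character(id), name = as.character(name),
                   chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(gs$id)) stop("gene ids must be unique")
  if (any(gs$start >= gs$end)) stop("gene intervals must satisfy start < end")
  structure(gs, class = c("gene_set", "data.frame"))
}

genes_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(start = genes$start + 1L, end = genes$end),
                         strand = genes$strand, id = genes$id)
}

markers_granges <- function(markers) {
  GenomicRanges::GRanges(markers$chrom,
                         IRanges::IRanges(start = markers$pos, width = 1L))
}

#' Strategy 1: intragenic significant markers
#'
#' Assigns every significant marker to each gene whose interval contains
#' its position. Markers in no gene are omitted from the result.
#'
#' @param markers data frame with `marker_id`, `chrom`, `pos` (e.g. rows of
#'   a meta result, typically [significant()] ones).
#' @param genes a [gene_set()].
#' @return Data frame `marker_id`, `gene_id`, `gene_name`.
#' @export
intragenic_hits <- function(markers, genes) {
  hits <- GenomicRanges::findOverlaps(markers_granges(markers), genes_granges(genes))
  data.frame(marker_id = markers$marker_id[S4Vectors::queryHits(hits)],
             gene_id = genes$id[S4Vectors::subjectHits(hits)],
             gene_name = genes$name[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Cluster significant markers into peaks
#'
#' Single-linkage clustering by positional gap: consecutive markers on the
#' same chromosome separated by at most `cluster_gap_bp` join the same peak.
#' The top marker of a peak is its minimum combined P.
#'
#' @param markers data frame with `marker_id`, `chrom`, `pos` and
#'   (optionally) `p_combined`.
#' @param cluster_gap_bp linkage gap (default 500 kb).
#' @return A `peak_cluster` data frame: `cluster_id`, `chrom`, `start`,
#'   `end`, `n_markers`, `top_marker`, `top_p`, plus a `members` attribute
#'   (list of marker ids per cluster).
#' @export
cluster_peaks <- function(markers, cluster_gap_bp = 500000L) {
  m <- markers[order(markers$chrom, markers$pos), , drop = FALSE]
  if (nrow(m) == 0L) stop("no markers to cluster")
  new_cluster <- c(TRUE, m$chrom[-1L] != m$chrom[-nrow(m)] |
                     diff(m$pos) > cluster_gap_bp)
  cid <- cumsum(new_cluster)
  p <- if ("p_combined" %in% names(m)) m$p_combined else rep(NA_real_, nrow(m))
  rows <- lapply(split(seq_len(nrow(m)), cid), function(idx) {
    top <- if (all(is.na(p[idx]))) idx[1] else idx[which.min(p[idx])]
    data.frame(chrom = m$chrom[idx[1]], start = min(m$pos[idx]),
               end = max(m$pos[idx]), n_markers = length(idx),
               top_marker = m$marker_id[top], top_p = p[top],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, class = c("peak_cluster", "data.frame"),
            members = unname(lapply(split(m$marker_id, cid), identity)))
}

#' Strategy 2: closest gene to a peak's top marker
#'
#' For each marker, the gene on the same chromosome minimizing the bp
#' distance (0 when intragenic). Ties break toward the lower start
#' coordinate, then the lexicographically smaller id. The distance is
#' signed: negative when the gene lies upstream of the marker (lower
#' coordinates).
#'
#' @param markers data frame with `marker_id`, `chrom`, `pos` (typically the
#'   top markers of [cluster_peaks()]).
#' @param genes a [gene_set()].
#' @return Data frame `marker_id`, `gene_id`, `gene_name`, `distance`
#'   (`NA` gene with `reason` when the chromosome has no gene).
#' @export
closest_gene <- function(markers, genes) {
  res <- lapply(seq_len(nrow(markers)), function(i) {
    g <- genes[genes$chrom == markers$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L)
      return(data.frame(marker_id = markers$marker_id[i], gene_id = NA_character_,
                        gene_name = NA_character_, distance = NA_real_,
                        reason = "no gene on chromosome", stringsAsFactors = FALSE))
    p0 <- markers$pos[i] - 1L  # 0-based marker coordinate
    dist <- ifelse(p0 < g$start, g$start - p0,
                   ifelse(p0 >= g$end, p0 - g$end + 1L, 0L))
    ord <- order(dist, g$start, g$id)
    j <- ord[1]
    signed <- if (dist[j] == 0L) 0 else if (g$end[j] <= p0) -dist[j] else dist[j]
    data.frame(marker_id = markers$marker_id[i], gene_id = g$id[j],
               gene_name = g$name[j], distance = signed, reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Strategy 3: genes in LD windows around peaks
#'
#' Builds a window `[span_start - flank_bp, span_end + flank_bp]` around
#' each peak (floored at position 1) and lists every gene overlapping it by
#' at least 1 bp, to capture genes potentially in linkage disequilibrium
#' with the significant markers.
#'
#' @param clusters a [cluster_peaks()] result.
#' @param genes a [gene_set()].
#' @param flank_bp flank added on each side (default 100 kb).
#' @return List with `windows` (`cluster_id`, `chrom`, `win_start`,
#'   `win_end`, `width`) and `hits` (`cluster_id`, `gene_id`, `gene_name`).
#' @export
ld_window_genes <- function(clusters, genes, flank_bp = 100000L) {
  stopifnot(nrow(clusters) >= 1L)
  win_start <- pmax(clusters$start - flank_bp, 1L)
  win_end <- clusters$end + flank_bp
  wins <- GenomicRanges::GRanges(clusters$chrom,
                                 IRanges::IRanges(start = win_start, end = win_end))
  ov <- GenomicRanges::findOverlaps(wins, genes_granges(genes))
  list(windows = data.frame(cluster_id = clusters$cluster_id,
                            chrom = clusters$chrom, win_start = win_start,
                            win_end = win_end,
                            width = win_end - win_start + 1L,
                            stringsAsFactors = FALSE),
       hits = data.frame(cluster_id = clusters$cluster_id[S4Vectors::queryHits(ov)],
                         gene_id = genes$id[S4Vectors::subjectHits(ov)],
                         gene_name = genes$name[S4Vectors::subjectHits(ov)],
                         stringsAsFactors = FALSE))
}

#' Run an annotation strategy on a scan
#'
#' Convenience wrapper tying [significant()] markers to the three
#' strategies: 1 = intragenic hits, 2 = closest gene per peak top marker,
#' 3 = LD-window gene capture.
#'
#' @param x a `meta_scan` or `meta_result`.
#' @param genes a [gene_set()].
#' @param strategy 1, 2 or 3.
#' @param cluster_gap_bp peak linkage gap for strategies 2 and 3.
#' @param flank_bp window flank for strategy 3.
#' @return Strategy-specific data frame(s); see the individual functions.
#' @export
annotate_scan <- function(x, genes, strategy = 1L, cluster_gap_bp = 500000L,
                          flank_bp = 100000L) {
  sig <- significant(x)
  if (nrow(sig) == 0L) stop("no significant markers to annotate")
  switch(as.character(strategy),
         "1" = intragenic_hits(sig, genes),
         "2" = {
           cl <- cluster_peaks(sig, cluster_gap_bp)
           tops <- sig[match(cl$top_marker, sig$marker_id),
                       c("marker_id", "chrom", "pos")]
           cbind(cluster_id = cl$cluster_id, closest_gene(tops, genes))
         },
         "3" = ld_window_genes(cluster_peaks(sig, cluster_gap_bp), genes, flank_bp),
         stop("strategy must be 1, 2 or 3"))
}

#' Write peak windows or significant markers as BED
#'
#' @param x a `meta_result`/`meta_scan` (significant markers) or the
#'   `windows` element of [ld_window_genes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (inherits(x, "meta_scan") || inherits(x, "meta_result")) {
    sig <- significant(x)
    df <- data.frame(sig$chrom, sig$pos - 1L, sig$pos, sig$marker_id)
  } else {
    df <- data.frame(x$chrom, x$win_start - 1L, x$win_end,
                     paste0("window_", x$cluster_id))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
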