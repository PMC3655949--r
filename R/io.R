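#' Read a VCF of biallelic SNPs into genotype panels
#'
#' Parses genotypes with \pkg{vcfR}. Genotype codes are counts of the VCF ALT
#' allele, so `allele1` = REF and `allele2` = ALT; marker order follows file
#' order. Non-autosomes are kept -- chromosome filtering is the caller's job.
#' Phase separators (`|`) are recorded per call so the panel can later be
#' lifted to haplotypes; they are only required at that later stage.
#'
#' @param path path to a VCF (plain text or gzipped).
#' @param populations optional named character vector mapping sample id to
#'   population label; when given, a named list of per-population panels is
#'   returned.
#' @return A [genotype_panel()], or a named list of them.
#' @export
read_vcf <- function(path, populations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF drops to a vector
  alt <- fix[, "ALT"]
  bad <- grepl(",", alt, fixed = TRUE)
  if (any(bad))
    stop("multi-allelic record at ", fix[which(bad)[1], "CHROM"], ":",
         fix[which(bad)[1], "POS"], " (ALT = ", alt[which(bad)[1]], ")")
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  if (anyDuplicated(key))
    stop("duplicated marker position: ", key[anyDuplicated(key)])
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  mm <- marker_map(ids, fix[, "CHROM"], as.integer(fix[, "POS"]),
                   fix[, "REF"], alt)
  gt <- vcfR::extract.gt(v, element = "GT")       # markers x samples
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1L, dimnames = list(NULL, "sample"))
  samples <- colnames(gt)
  dm <- dim(gt)
  a1 <- substr(gt, 1L, 1L)                        # substr drops dim attributes
  a2 <- substr(gt, 3L, 3L)
  sep <- substr(gt, 2L, 2L)
  tomiss <- is.na(gt) | a1 == "." | a2 == "."
  a1n <- suppressWarnings(as.integer(a1)); a1n[tomiss] <- NA_integer_
  a2n <- suppressWarnings(as.integer(a2)); a2n[tomiss] <- NA_integer_
  calls <- a1n + a2n
  first <- a1n
  first[!is.na(sep) & sep != "|"] <- NA_integer_  # unphased: first allele unknown
  calls <- t(matrix(calls, dm[1], dm[2]))
  first <- t(matrix(first, dm[1], dm[2]))
  panel <- genotype_panel(calls, samples, mm, first_allele = first)
  if (is.null(populations)) return(panel)
  miss <- setdiff(samples, names(populations))
  if (length(miss)) stop("no population label for sample(s): ", paste(miss, collapse = ", "))
  lapply(split(samples, populations[samples]), function(s) subset_samples(panel, s))
}

#' Write a panel as a plain-text VCF
#'
#' @param panel a [genotype_panel()] or [haplotype_panel()].
#' @param path output path.
#' @param phased write `|` separators (haplotype panels are always phased;
#'   genotype panels require phase information when `phased = TRUE`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, phased = inherits(panel, "haplotype_panel")) {
  mm <- panel$markers
  if (inherits(panel, "haplotype_panel")) {
    odd <- seq(1L, nrow(panel$hap), by = 2L)
    g <- matrix(paste0(panel$hap[odd, ], "|", panel$hap[odd + 1L, ]),
                nrow = length(odd))
    samples <- panel$samples
  } else {
    samples <- panel$samples
    calls <- panel$calls
    if (phased) {
      fa <- panel$first_allele
      if (is.null(fa)) fa <- matrix(NA_integer_, nrow(calls), ncol(calls))
      fa[calls == 0L] <- 0L; fa[calls == 2L] <- 1L
      if (anyNA(fa[!is.na(calls) & calls == 1L]))
        stop("phased output requested but phase information is incomplete")
      g <- matrix(paste0(fa, "|", calls - fa), nrow = nrow(calls))
    } else {
      low <- ifelse(calls == 2L, 1L, 0L)
      g <- matrix(paste0(low, "/", ifelse(calls >= 1L, 1L, 0L)), nrow = nrow(calls))
    }
    g[is.na(calls)] <- "./."
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  body <- cbind(mm$chrom, mm$pos, mm$marker_id, mm$allele1, mm$allele2,
                ".", ".", ".", "GT", t(g))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read/write the haplotype-matrix TSV dialect
#'
#' A light fixture format: a `sample` column (sample id, repeated twice per
#' individual, in phase order) followed by one 0/1 column per marker, header
#' row of marker ids. A side-car marker map (columns `marker_id`, `chrom`,
#' `pos`, `allele1`, `allele2`, optional `ancestral`) travels with it.
#'
#' @param panel a [haplotype_panel()].
#' @param path output path for the haplotype matrix.
#' @param map_path output path for the side-car marker map.
#' @return `path`, invisibly (writer); a [haplotype_panel()] (reader).
#' @export
write_hap_tsv <- function(panel, path, map_path = paste0(path, ".map")) {
  df <- data.frame(sample = rep(panel$samples, each = 2L), panel$hap,
                   check.names = FALSE)
  colnames(df) <- c("sample", panel$markers$marker_id)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(panel$markers), map_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hap_tsv
#' @export
read_hap_tsv <- function(path, map_path = paste0(path, ".map")) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  map <- read.table(map_path, header = TRUE, sep = "\t",
                    colClasses = "character")
  mm <- marker_map(map$marker_id, map$chrom, as.integer(map$pos),
                   map$allele1, map$allele2,
                   if ("ancestral" %in% names(map)) map$ancestral else NA)
  hap <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(hap) <- "integer"
  haplotype_panel(hap, df$sample[seq(1L, nrow(df), by = 2L)], mm)
}

#' Read/write ancestral-allele calls as TSV
#'
#' Columns, in order: `marker_id`, `chrom`, `pos`, `ancestral_allele`. The
#' writer emits one row per marker with a call. The reader sets the
#' `ancestral` column of a marker map; a TSV allele that is not one of the
#' marker's two alleles leaves that marker uncalled (unusable for
#' polarization) and is counted in the `n_mismatched` attribute.
#'
#' @param markers a [marker_map()] (reader: map to annotate).
#' @param path TSV path.
#' @return Writer: `path` invisibly. Reader: the marker map with `ancestral`
#'   filled in, with attributes `n_called` and `n_mismatched`.
#' @export
write_ancestral_tsv <- function(markers, path) {
  keep <- !is.na(markers$ancestral)
  write.table(data.frame(marker_id = markers$marker_id[keep],
                         chrom = markers$chrom[keep],
                         pos = markers$pos[keep],
                         ancestral_allele = markers$ancestral[keep]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ancestral_tsv
#' @export
read_ancestral_tsv <- function(path, markers) {
  tab <- read.table(path, header = TRUE, sep = "\t", colClasses = "character")
  stopifnot(all(c("marker_id", "chrom", "pos", "ancestral_allele") %in% names(tab)))
  idx <- match(markers$marker_id, tab$marker_id)
  anc <- tab$ancestral_allele[idx]
  ok <- !is.na(anc) & (anc == markers$allele1 | anc == markers$allele2)
  n_bad <- sum(!is.na(anc) & !ok)
  if (n_bad > 0)
    warning(n_bad, " ancestral call(s) did not match either panel allele; left uncalled")
  markers$ancestral <- ifelse(ok, anc, NA_character_)
  structure(markers, n_called = sum(ok), n_mismatched = n_bad)
}

#' Write a score track or meta result as TSV
#'
#' @param x a `score_track` or `meta_result` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from BED or GFF3
#'
#' Imports via \pkg{rtracklayer} and stores intervals 0-based half-open.
#' For GFF3, only records of type `gene` are kept; the gene id is taken from
#' the `ID` (or `gene_id`) attribute.
#'
#' @param path a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return A [gene_set()].
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$type)) {
    keep <- as.character(md$type) == "gene"
    if (any(keep)) { gr <- gr[keep]; md <- S4Vectors::mcols(gr) }
  }
  id <- if (!is.null(md$ID)) as.character(md$ID)
        else if (!is.null(md$gene_id)) as.character(md$gene_id)
        else if (!is.null(md$name)) as.character(md$name)
        else paste0("gene", seq_along(gr))
  nm <- if (!is.null(md$Name)) as.character(md$Name)
        else if (!is.null(md$name)) as.character(md$name) else id
  gene_set(id = id, name = nm,
           chrom = as.character(GenomicRanges::seqnames(gr)),
           start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
           end = GenomicRanges::end(gr),
           strand = as.character(GenomicRanges::strand(gr)))
}
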