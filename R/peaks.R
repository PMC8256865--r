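#' Construct a peak set from interval coordinates
#'
#' A peak set holds the called peaks of one ChIP assay (e.g. the N-terminal
#' and C-terminal antibodies used to define fusion-protein binding, a
#' transcription factor, or a histone mark). Coordinates follow the BED
#' convention: 0-based, half-open \code{[start, end)}. Internally peaks are
#' stored as a \link[GenomicRanges]{GRanges} object (1-based, closed), so all
#' overlap semantics are inherited from the Bioconductor ranges machinery;
#' a half-open overlap of at least 1 bp corresponds exactly to a non-empty
#' \code{GRanges} overlap.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open. Must satisfy
#'   \code{0 <= start < end}.
#' @param name optional peak identifiers.
#' @param signal optional non-negative tag counts or scores.
#' @param label assay name attached to the set (e.g. \code{"H3K27ac"}).
#' @return A sorted, deduplicated \code{GRanges} with metadata columns
#'   \code{name} and \code{signal} and a \code{label} in its metadata list.
#' @export
peak_set <- function(chrom, start, end, name = NULL, signal = NULL,
                     label = "") {
  if (length(chrom) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr)$label <- label
    return(gr)
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(!nzchar(chrom))) stop("chromosome names must be non-empty")
  if (any(start < 0)) stop("start coordinates must be >= 0")
  if (any(start >= end)) stop("intervals must satisfy start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  if (!is.null(signal)) {
    if (any(signal < 0)) stop("signal must be non-negative")
    S4Vectors::mcols(gr)$signal <- as.numeric(signal)
  }
  gr <- gr[!duplicated(paste(GenomeInfoDb::seqnames(gr),
                             GenomicRanges::start(gr),
                             GenomicRanges::end(gr)))]
  gr <- GenomicRanges::sort(gr)
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Read a BED file of peaks
#'
#' Accepts BED3/BED6 (tab-separated, no header). Coordinates in the file are
#' 0-based half-open and are converted by \pkg{rtracklayer}.
#'
#' @param path file path.
#' @param label assay label to attach.
#' @return A peak-set \code{GRanges} (sorted, deduplicated).
#' @export
read_bed <- function(path, label = basename(path)) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::strand(gr) <- "*"
  keep <- !duplicated(paste(GenomeInfoDb::seqnames(gr),
                            GenomicRanges::start(gr),
                            GenomicRanges::end(gr)))
  gr <- GenomicRanges::sort(gr[keep])
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Write a peak set to BED
#'
#' @param peaks a peak-set \code{GRanges}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_bed <- function(peaks, path) {
  rtracklayer::export(peaks, path, format = "BED")
  invisible(path)
}

#' Intersect two peak sets (>= 1 bp overlap)
#'
#' Returns the peaks of \code{a} that overlap at least one peak of \code{b}
#' by at least 1 bp. The coordinates of \code{a} are retained in full: the
#' operation identifies which peaks of \code{a} are supported by \code{b},
#' it does not trim them to the overlap fragment. It is therefore
#' deliberately asymmetric. This is how a fusion-protein peak set is defined
#' from the two antibody tracks (peaks of one track overlapping the other)
#' and how enhancer-supported peaks are selected.
#'
#' @param a,b peak-set \code{GRanges}.
#' @return the overlapping subset of \code{a}, sorted and deduplicated.
#' @export
intersect_peaks <- function(a, b) {
  # disjoint chromosome sets are a valid no-overlap case, not a mismatch
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  out <- IRanges::subsetByOverlaps(a, b, minoverlap = 1L,
                                   ignore.strand = TRUE)
  S4Vectors::metadata(out)$label <- S4Vectors::metadata(a)$label
  out
}

#' Define enhancers as H3K27ac peaks supported by H3K4me1
#'
#' Operationally an enhancer is an H3K27ac peak overlapping an H3K4me1 peak
#' by at least 1 bp; the H3K27ac coordinates are retained.
#'
#' @param h3k27ac,h3k4me1 peak-set \code{GRanges} for the two marks.
#' @return enhancer peak set (subset of \code{h3k27ac}).
#' @export
define_enhancers <- function(h3k27ac, h3k4me1) {
  out <- intersect_peaks(h3k27ac, h3k4me1)
  S4Vectors::metadata(out)$label <- "enhancer"
  out
}

#' Construct a promoter map
#'
#' One TSS per gene. Coordinates are 0-based base positions.
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome per gene.
#' @param tss 0-based TSS coordinate per gene, \code{>= 0}.
#' @param strand \code{"+"} or \code{"-"} per gene. Strand is carried for
#'   completeness; nearest-promoter distance is strand-agnostic.
#' @return a \code{data.frame} with class \code{"promoter_map"}.
#' @export
promoter_map <- function(gene_id, chrom, tss, strand = "+") {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene ids in a promoter map must be unique")
  tss <- as.numeric(tss)
  if (length(tss) && any(tss < 0)) stop("tss coordinates must be >= 0")
  strand <- rep_len(as.character(strand), length(gene_id))
  if (length(strand) && !all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  out <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                    tss = tss, strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("promoter_map", "data.frame")
  out
}

#' Read a promoter map from TSV
#'
#' Expects a header with columns \code{gene_id}, \code{chrom}, \code{tss},
#' \code{strand}.
#'
#' @param path file path.
#' @return a \code{promoter_map}.
#' @export
read_promoter_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(df)))
    stop("promoter TSV must have columns: ", paste(need, collapse = ", "))
  promoter_map(df$gene_id, df$chrom, df$tss, df$strand)
}

#' Write a promoter map to TSV
#' @param promoters a \code{promoter_map}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_promoter_map <- function(promoters, path) {
  utils::write.table(as.data.frame(promoters), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate peaks to their nearest promoter
#'
#' Each peak is assigned the gene whose TSS is closest to the peak midpoint
#' on the same chromosome (unsigned distance; strand ignored). The midpoint
#' of a 0-based half-open interval is \code{floor((start + end) / 2)}.
#' Equidistant ties are broken by the lexicographically smallest gene id so
#' that annotation is deterministic. Peaks on chromosomes carrying no
#' promoter are reported with \code{NA} gene id rather than raising an
#' error.
#'
#' @param peaks a peak-set \code{GRanges}.
#' @param promoters a \code{promoter_map}.
#' @return a \code{data.frame} with one row per peak: \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{center},
#'   \code{gene_id} (\code{NA} if unannotated) and \code{distance}.
#' @seealso [bound_genes()] for the distinct annotated gene set.
#' @export
annotate_nearest_promoter <- function(peaks, promoters) {
  stopifnot(inherits(promoters, "promoter_map"))
  n <- length(peaks)
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  bed_start <- GenomicRanges::start(peaks) - 1L
  bed_end <- GenomicRanges::end(peaks)
  center <- floor((bed_start + bed_end) / 2)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    pk <- which(chrom == ch)
    pr <- promoters[promoters$chrom == ch, , drop = FALSE]
    if (nrow(pr) == 0L) next
    d <- abs(outer(center[pk], pr$tss, "-"))
    for (i in seq_along(pk)) {
      dmin <- min(d[i, ])
      cand <- pr$gene_id[d[i, ] == dmin]
      gene[pk[i]] <- min(cand)
      dist[pk[i]] <- dmin
    }
  }
  data.frame(chrom = chrom, start = bed_start, end = bed_end,
             center = center, gene_id = gene, distance = dist,
             stringsAsFactors = FALSE)
}

#' Distinct genes bound according to a peak annotation
#'
#' @param annotation output of [annotate_nearest_promoter()].
#' @return sorted character vector of annotated gene ids (unannotated peaks
#'   are dropped).
#' @export
bound_genes <- function(annotation) {
  sort(unique(annotation$gene_id[!is.na(annotation$gene_id)]))
}

#' Spike-in (reference chromatin) scale factor
#'
#' ChIP experiments spiked with foreign chromatin (e.g. fly chromatin in a
#' human IP) allow a between-sample normalization: the target-genome signal
#' is adjusted by how the spike-in : target read ratio changes between the
#' input and the IP. The factor returned is
#' \deqn{\alpha = (spike_{input}/hg_{input}) / (spike_{IP}/hg_{IP})}
#' so that identical spike ratios in input and IP give \eqn{\alpha = 1}
#' (no adjustment), and the adjusted signal is raw IP signal \eqn{\times
#' \alpha}. \eqn{\alpha} is invariant to rescaling all four counts.
#'
#' @param hg_reads_input,spike_reads_input,hg_reads_ip,spike_reads_ip
#'   positive read counts for one input/IP pair.
#' @return positive scalar \eqn{\alpha}.
#' @export
spikein_scale_factor <- function(hg_reads_input, spike_reads_input,
                                 hg_reads_ip, spike_reads_ip) {
  counts <- c(hg_reads_input, spike_reads_input, hg_reads_ip, spike_reads_ip)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("all spike-in read counts must be positive; spike-in unusable")
  (spike_reads_input / hg_reads_input) / (spike_reads_ip / hg_reads_ip)
}

#' Normalize tag counts to tags per ten million
#'
#' @param signal non-negative tag count(s).
#' @param library_total total tags in the library, \code{> 0}.
#' @return \code{signal * 1e7 / library_total}.
#' @export
tags_per_ten_million <- function(signal, library_total) {
  if (length(library_total) != 1L || !is.finite(library_total) ||
      library_total <= 0)
    stop("library_total must be a single positive count")
  if (any(signal < 0)) stop("signal must be non-negative")
  signal * 1e7 / library_total
}
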