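#' Reach of a transcriptional perturbation along the gene body
#'
#' At a given time after a perturbation, RNA polymerase II released from the
#' promoter can have traveled at most `elongation_rate * time_point` into the
#' gene, so gene bodies beyond that distance are still transcribed at
#' baseline. This product is the length threshold defining 3' invariant
#' regions.
#'
#' @param elongation_rate Polymerase elongation rate in kb per minute
#'   (human Pol II is roughly 2-3 kb/min).
#' @param time_point Time since perturbation, minutes.
#' @return Threshold in base pairs.
#' @examples
#' length_threshold(3, 60) # 180000
#' @export
length_threshold <- function(elongation_rate, time_point) {
  if (!is.numeric(elongation_rate) || elongation_rate <= 0)
    stop("elongation_rate must be > 0")
  if (!is.numeric(time_point) || time_point <= 0)
    stop("time_point must be > 0")
  elongation_rate * time_point * 1000
}

#' Gene-model tables
#'
#' A gene model is one transcript: `gene_id`, `transcript_id`, `chrom`,
#' `start`, `end` (0-based half-open, bp), `strand` (+/-), and
#' `total_count`, the reads assigned to the transcript over exons and
#' introns (0 when unknown).
#'
#' `read_gene_models` imports transcripts from a GTF (1-based inclusive,
#' converted) or from a 6-column BED file (name column = transcript id;
#' gene ids taken from the name's prefix before the first `.` if present).
#'
#' @param path GTF (`.gtf`) or BED (`.bed`) annotation.
#' @param counts Optional named numeric vector of per-transcript read counts
#'   (names are transcript ids) used to fill `total_count`.
#' @return A `data.frame` of gene models.
#' @export
read_gene_models <- function(path, counts = NULL) {
  if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 6L) stop("BED annotation needs 6 columns (incl. name and strand)")
    gm <- data.frame(
      gene_id = sub("\\..*$", "", bed[[4L]]),
      transcript_id = bed[[4L]],
      chrom = bed[[1L]], start = bed[[2L]], end = bed[[3L]],
      strand = bed[[6L]], stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- S4Vectors::mcols(gr)
    keep <- md$type == "transcript"
    if (!any(keep)) {
      # fall back to exon spans grouped by transcript
      ex <- gr[md$type == "exon"]
      sp <- split(ex, S4Vectors::mcols(ex)$transcript_id)
      rng <- unlist(range(sp))
      gm <- data.frame(
        gene_id = S4Vectors::mcols(ex)$gene_id[match(names(rng),
                    S4Vectors::mcols(ex)$transcript_id)],
        transcript_id = names(rng),
        chrom = as.character(GenomicRanges::seqnames(rng)),
        start = GenomicRanges::start(rng) - 1L,
        end = GenomicRanges::end(rng),
        strand = as.character(GenomicRanges::strand(rng)),
        stringsAsFactors = FALSE)
    } else {
      tx <- gr[keep]
      gm <- data.frame(
        gene_id = S4Vectors::mcols(tx)$gene_id,
        transcript_id = S4Vectors::mcols(tx)$transcript_id,
        chrom = as.character(GenomicRanges::seqnames(tx)),
        start = GenomicRanges::start(tx) - 1L,
        end = GenomicRanges::end(tx),
        strand = as.character(GenomicRanges::strand(tx)),
        stringsAsFactors = FALSE)
    }
  }
  if (any(!gm$strand %in% c("+", "-")))
    stop("all transcripts must have strand + or -")
  gm$total_count <- if (is.null(counts)) 0
                    else unname(ifelse(is.na(counts[gm$transcript_id]), 0,
                                       counts[gm$transcript_id]))
  rownames(gm) <- NULL
  gm
}

#' Pick the maximally expressed isoform of a gene
#'
#' Ties on `total_count` are broken by longer transcript, then by
#' lexicographically smaller `transcript_id`.
#'
#' @param transcripts A gene-model `data.frame` whose rows all share one
#'   `gene_id` (see [read_gene_models()]).
#' @return The selected single-row gene model.
#' @export
select_max_isoform <- function(transcripts) {
  if (NROW(transcripts) == 0L) stop("empty transcript list")
  if (length(unique(transcripts$gene_id)) != 1L)
    stop("all transcripts must share one gene_id")
  len <- transcripts$end - transcripts$start
  ord <- order(-transcripts$total_count, -len, transcripts$transcript_id)
  transcripts[ord[1L], , drop = FALSE]
}

# Apply select_max_isoform per gene over a whole annotation table.
select_max_isoforms <- function(gene_models) {
  parts <- split(gene_models, gene_models$gene_id)
  out <- do.call(rbind, lapply(parts, select_max_isoform))
  rownames(out) <- NULL
  out
}

#' Select 3' invariant regions under the elongation model
#'
#' For a plus-strand gene `[s, e)` the invariant region is
#' `[s + threshold, e - end_exclusion)`; minus-strand genes are mirrored
#' (`[s + end_exclusion, e - threshold)`). The terminal `end_exclusion`
#' bases are dropped to avoid the characteristic termination-associated
#' pileup at annotated 3' ends. Genes whose region would be shorter than
#' `min_region` are silently dropped (the count is reported via `message`).
#'
#' @param genes Gene-model `data.frame`, one row per gene (after isoform
#'   selection); coordinates 0-based half-open.
#' @param threshold Distance from the annotated gene 5' end that the
#'   perturbation could have reached, bp (see [length_threshold()]).
#' @param end_exclusion Bases excluded from the annotated 3' end (default
#'   500 bp).
#' @param min_region Minimum emitted region length, bp (default 1000).
#' @return A `data.frame` (`gene_id`, `chrom`, `start`, `end`, `strand`;
#'   0-based half-open), sorted by chromosome then start.
#' @export
select_invariant_regions <- function(genes, threshold,
                                     end_exclusion = 500, min_region = 1000) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (end_exclusion < 0) stop("end_exclusion must be >= 0")
  if (min_region < 1) stop("min_region must be >= 1")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$start + threshold, genes$start + end_exclusion)
  end <- ifelse(plus, genes$end - end_exclusion, genes$end - threshold)
  keep <- (end - start) >= min_region
  if (any(!keep))
    message(sprintf("select_invariant_regions: dropped %d gene(s) shorter than threshold + exclusion + min_region",
                    sum(!keep)))
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = start, end = end, strand = genes$strand,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write invariant regions as 6-column BED
#'
#' Coordinates are already 0-based half-open, so they are written as-is.
#'
#' @param regions Output of [select_invariant_regions()].
#' @param path Output BED path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, regions$start, regions$end,
                    regions$gene_id, 0L, regions$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_regions_bed
#' @export
read_regions_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(gene_id = bed[[4L]], chrom = bed[[1L]], start = bed[[2L]],
             end = bed[[3L]], strand = bed[[6L]], stringsAsFactors = FALSE)
}

#' Spike-in sequencing-depth quality control
#'
#' Coverage is total aligned spike-in bases over the spike-in transcriptome
#' length (30 Mb for the Drosophila dm6 transcriptome). Samples at or below
#' the fold threshold (default 10X, strict inequality) are flagged as
#' failing: normalization-factor estimates from shallower spike-ins are
#' markedly less consistent. When per-base totals are unavailable,
#' `aligned_bases` may be approximated as read count times mean read length.
#'
#' @param aligned_bases Total aligned spike-in bases (bp).
#' @param transcriptome_length Spike-in transcriptome length, bp.
#' @param threshold Fold-coverage threshold.
#' @return A `spike_in_depth` list: `aligned_bases`, `transcriptome_length`,
#'   `coverage` (fold), `threshold`, `passes_threshold`.
#' @examples
#' spike_in_coverage(21e6) # 0.7X, fails
#' @export
spike_in_coverage <- function(aligned_bases, transcriptome_length = 30000000,
                              threshold = 10) {
  if (!is.numeric(aligned_bases) || aligned_bases < 0)
    stop("aligned_bases must be >= 0")
  if (!is.numeric(transcriptome_length) || transcriptome_length <= 0)
    stop("transcriptome_length must be > 0")
  cov <- aligned_bases / transcriptome_length
  structure(list(aligned_bases = aligned_bases,
                 transcriptome_length = transcriptome_length,
                 coverage = cov, threshold = threshold,
                 passes_threshold = cov > threshold),
            class = "spike_in_depth")
}

#' @export
print.spike_in_depth <- function(x, ...) {
  cat(sprintf("spike-in coverage %.3gX over %s bp (%s %gX threshold)\n",
              x$coverage, format(x$transcriptome_length, big.mark = ","),
              if (x$passes_threshold) "passes" else "FAILS", x$threshold))
  invisible(x)
}
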