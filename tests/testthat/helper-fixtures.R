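# Shared fixture builders. Everything is generated in code at test time.

# MCMC settings small enough for unit tests; convergence warnings at these
# sizes are expected and silenced at call sites.
quick_mcmc <- function(seed, draws = 1200, burn_in = 400, chains = 2) {
  mcmc_config(draws = draws, burn_in = burn_in, chains = chains, seed = seed)
}

fit_quiet <- function(...) suppressWarnings(fit_vsi(...))

# A synthetic posterior-like object for functions that only need the
# normal summary (mu_mean, mu_sd).
fake_posterior <- function(mu_mean, mu_sd) list(mu_mean = mu_mean, mu_sd = mu_sd)

# Three-gene toy annotation: only gene A (200 kb) is long enough to carry a
# 3' invariant region under the default 180 kb threshold.
write_toy_gtf <- function(path) {
  attr_of <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  rows <- c(
    paste("chr1", "test", "transcript", 1L, 200000L, ".", "+", ".",
          attr_of("geneA", "geneA.t1"), sep = "\t"),
    paste("chr1", "test", "exon", 1L, 200000L, ".", "+", ".",
          attr_of("geneA", "geneA.t1"), sep = "\t"),
    paste("chr1", "test", "transcript", 300001L, 450000L, ".", "-", ".",
          attr_of("geneB", "geneB.t1"), sep = "\t"),
    paste("chr1", "test", "exon", 300001L, 450000L, ".", "-", ".",
          attr_of("geneB", "geneB.t1"), sep = "\t"),
    paste("chr2", "test", "transcript", 1001L, 51000L, ".", "+", ".",
          attr_of("geneC", "geneC.t1"), sep = "\t"),
    paste("chr2", "test", "exon", 1001L, 51000L, ".", "+", ".",
          attr_of("geneC", "geneC.t1"), sep = "\t"))
  writeLines(rows, path)
  path
}

# Write alignments as SAM and convert to an indexed BAM. 'reads' is a
# data.frame with pos (1-based leftmost), strand ("+"/"-"), width.
write_toy_bam <- function(reads, dir, chrom = "chr1", chrom_len = 100000L) {
  sam <- file.path(dir, "toy.sam")
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    w <- reads$width[i]
    paste(sprintf("r%04d", i),
          if (reads$strand[i] == "+") 0L else 16L,
          chrom, reads$pos[i], 60L, sprintf("%dM", w), "*", 0L, 0L,
          paste(rep("A", w), collapse = ""), "*", sep = "\t")
  }, character(1))
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "toy"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# Independent per-read tally used as the counting oracle: 5' end in
# [start, end) (0-based half-open) and strand compatibility.
brute_force_count <- function(reads, start0, end0, region_strand = "+",
                              strandedness = "unstranded") {
  five <- ifelse(reads$strand == "+", reads$pos, reads$pos + reads$width - 1L)
  five0 <- five - 1L
  in_window <- five0 >= start0 & five0 < end0
  ok <- switch(strandedness,
               unstranded = rep(TRUE, nrow(reads)),
               same = reads$strand == region_strand,
               opposite = reads$strand != region_strand)
  sum(in_window & ok)
}
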