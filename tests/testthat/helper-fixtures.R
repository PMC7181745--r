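# In-code fixtures: a hand-built toy genome/annotation and small writers.

# Ten single-exon genes on two contigs, alternating strands, each with
# 5'UTR (20 bp), CDS (60 bp), 3'UTR (120 bp). Gene i on chrA starts at
# 1000*i; genes 6..10 sit on chrB. Minus-strand genes have the 3'UTR at
# the low-coordinate end.
toy_annotation <- function() {
  rows <- list()
  for (i in 1:10) {
    contig <- if (i <= 5) "chrA" else "chrB"
    strand <- if (i %% 2 == 1) "+" else "-"
    s <- 1000L * i
    tx <- c(s, s + 199L)
    if (strand == "+") {
      u5 <- c(s, s + 19L); cds <- c(s + 20L, s + 79L)
      u3 <- c(s + 80L, s + 199L)
    } else {
      u3 <- c(s, s + 119L); cds <- c(s + 120L, s + 179L)
      u5 <- c(s + 180L, s + 199L)
    }
    rows[[i]] <- GenomicRanges::GRanges(
      contig,
      IRanges::IRanges(c(tx[1], u5[1], cds[1], u3[1]),
                       c(tx[2], u5[2], cds[2], u3[2])),
      strand = strand,
      type = c("exon", "5UTR", "CDS", "3UTR"),
      gene_id = sprintf("toy%02d", i))
  }
  gr <- suppressWarnings(do.call(c, rows))
  GenomeInfoDb::seqlengths(gr) <- c(chrA = 20000L, chrB = 20000L)
  gr
}

# One long-format variant row per library, for feeding the filters.
toy_variant <- function(contig, position, ref, alt, libs = c("L1", "L2"),
                        ref_count = 8L, alt_count = 2L) {
  data.frame(contig = contig, position = as.integer(position), ref = ref,
             alt = alt, library = libs, ref_count = ref_count,
             alt_count = alt_count, stringsAsFactors = FALSE)
}

# A PWM count matrix whose consensus is the given sequence.
consensus_pwm_counts <- function(motif, weight = 20) {
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, 4, nchar(motif), dimnames = list(bases, NULL))
  for (i in seq_len(nchar(motif))) m[substr(motif, i, i), i] <- weight
  m
}

# Minimal multi-sample VCF writer for loader tests.
write_test_vcf <- function(path, records, samples = c("S1", "S2"),
                           format = "GT:AD") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Depths\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, vapply(records, function(r) {
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", format,
            r$fields), collapse = "\t")
  }, "")), path)
  path
}

# Small deterministic scenario for fast end-to-end tests.
small_scenario <- function(...) {
  args <- utils::modifyList(list(n_genes = 30, sites_per_gene = 2,
                                 frac_true_sites = 0.15, seed = 7),
                            list(...))
  do.call(tribekit::simulation_scenario, args)
}
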