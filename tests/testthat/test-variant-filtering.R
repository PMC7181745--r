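# VCF loading, strand-consistency and SNP filters, and count assembly.

test_that("VCF loader maps AD fields, splits multiallelics, drops indels", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, list(
    list(chrom = "chr1", pos = 100, ref = "A", alt = "G",
         fields = c("0/1:7,3", "0/0:9,0")),
    list(chrom = "chr1", pos = 200, ref = "A", alt = "G,T",
         fields = c("1/2:4,3,2", "0/1:5,1,0")),
    list(chrom = "chr1", pos = 300, ref = "A", alt = "AT",
         fields = c("0/1:6,2", "0/1:6,2")),
    list(chrom = "chr1", pos = 400, ref = "T", alt = "C",
         fields = c("0/1:5,5", "."))))
  v <- read_variants(path)
  r1 <- v[v$position == 100 & v$library == "S1", ]
  expect_equal(c(r1$ref_count, r1$alt_count), c(7L, 3L))
  # multiallelic record splits into A->G and A->T with per-allele depths
  r2 <- v[v$position == 200 & v$library == "S1", ]
  expect_setequal(r2$alt, c("G", "T"))
  expect_equal(r2$alt_count[r2$alt == "G"], 3L)
  expect_equal(r2$alt_count[r2$alt == "T"], 2L)
  # insertion discarded
  expect_false(300 %in% v$position)
  # missing sample call read as zero coverage
  r4 <- v[v$position == 400 & v$library == "S2", ]
  expect_equal(c(r4$ref_count, r4$alt_count), c(0L, 0L))
})

test_that("VCF without AD in FORMAT is an explicit error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, list(list(chrom = "chr2", pos = 10, ref = "A",
                                 alt = "G", fields = c("0/1", "0/1"))),
                 format = "GT")
  expect_error(read_variants(path), "AD")
})

test_that("strand filter keeps only A->G on + and T->C on - transcripts", {
  ann <- toy_annotation()
  # toy01 chrA + (tx 1000-1199); toy02 chrA - (tx 2000-2199)
  v <- rbind(
    toy_variant("chrA", 1100, "A", "G"),   # + strand 3'UTR -> keep
    toy_variant("chrA", 1150, "T", "C"),   # T->C on + strand -> drop
    toy_variant("chrA", 2050, "T", "C"),   # - strand 3'UTR -> keep
    toy_variant("chrA", 2050, "A", "G"),   # A->G on - strand -> drop
    toy_variant("chrA", 2150, "C", "T"),   # substitution not allowed
    toy_variant("chrA", 500, "A", "G"),    # intergenic -> drop
    toy_variant("chrZ", 1100, "A", "G"))   # unannotated contig -> drop
  out <- suppressMessages(strand_consistent_filter(v, ann))
  expect_setequal(unique(paste(out$contig, out$position)),
                  c("chrA 1100", "chrA 2050"))
  expect_equal(out$strand[out$position == 1100][1], "+")
  expect_equal(out$strand[out$position == 2050][1], "-")
  expect_equal(out$region[out$position == 1100][1], "3UTR")
  expect_true(all(paste(out$ref, out$alt) %in% c("A G", "T C")))
})

test_that("genic regions follow annotation with 3'UTR > CDS > 5'UTR priority", {
  ann <- toy_annotation()
  v <- rbind(toy_variant("chrA", 1010, "A", "G"),  # toy01 5'UTR
             toy_variant("chrA", 1050, "A", "G"),  # toy01 CDS
             toy_variant("chrA", 1100, "A", "G"))  # toy01 3'UTR
  out <- strand_consistent_filter(v, ann)
  reg <- tapply(out$region, out$position, unique)
  expect_equal(as.character(reg[c("1010", "1050", "1100")]),
               c("5UTR", "CDS", "3UTR"))

  # overlap of a + gene 3'UTR and another + gene CDS at one position:
  # 3'UTR wins and sets the primary gene
  extra <- GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(c(1080, 1080, 1090), c(1210, 1210, 1180)),
    strand = "+", type = c("exon", "CDS", "3UTR"), gene_id = "toyX")
  ann2 <- suppressWarnings(c(ann, extra))
  out2 <- strand_consistent_filter(toy_variant("chrA", 1100, "A", "G"), ann2)
  expect_equal(out2$region[1], "3UTR")
  expect_setequal(strsplit(out2$all_genes[1], ",")[[1]], c("toy01", "toyX"))
  # at 1085: toy01 3'UTR vs toyX CDS -> region 3UTR, gene toy01
  out3 <- strand_consistent_filter(toy_variant("chrA", 1085, "A", "G"), ann2)
  expect_equal(out3$gene[1], "toy01")
  expect_equal(out3$region[1], "3UTR")
})

test_that("known-SNP exclusion is exact-position and convention-correct", {
  cand <- rbind(toy_variant("chrA", 1100, "A", "G"),
                toy_variant("chrA", 2050, "T", "C"))
  snp <- data.frame(contig = "chrA", position = 1100)
  out <- suppressMessages(exclude_known_snps(cand, snp))
  expect_setequal(unique(out$position), 2050)
  expect_identical(exclude_known_snps(cand, snp[0, ]), cand)
  off <- data.frame(contig = "chrA", position = 1101)
  expect_identical(exclude_known_snps(cand, off), cand)

  # BED is 0-based half-open: row (chrA, 1099, 1100) names position 1100
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrA\t1099\t1100", bed)
  expect_equal(read_snp_sites(bed)$position, 1100)
})

test_that("filters commute and compose to the hand-enumerated answer", {
  ann <- toy_annotation()
  v <- rbind(toy_variant("chrA", 1100, "A", "G"),
             toy_variant("chrA", 1150, "T", "C"),
             toy_variant("chrA", 2050, "T", "C"),
             toy_variant("chrA", 3085, "A", "G"),
             toy_variant("chrB", 6050, "T", "C"),
             toy_variant("chrB", 7100, "A", "G"))
  snp <- data.frame(contig = c("chrA", "chrB"), position = c(3085, 9999))
  a <- suppressMessages(
    exclude_known_snps(strand_consistent_filter(v, ann), snp))
  b <- suppressMessages(
    strand_consistent_filter(exclude_known_snps(v, snp), ann))
  a2 <- a[order(a$contig, a$position), ]
  b2 <- b[order(b$contig, b$position), ]
  rownames(a2) <- rownames(b2) <- NULL
  expect_identical(a2, b2)
  # hand enumeration: 1100 (+,AG ok), 2050 (-,TC ok), 6050 (toy06 -, TC ok);
  # 1150 TC-on-plus dropped, 3085 SNP-removed, 7100 AG on toy07... toy07 is +
  expect_setequal(paste(a2$contig, a2$position),
                  c("chrA 1100", "chrA 2050", "chrB 6050", "chrB 7100"))
})

test_that("reverse-complement mirror symmetry of the candidate set", {
  # mirror coordinates x -> M + 1 - x, flip strands and complement alleles:
  # the surviving site set must map through the same mirror
  M <- 20000L
  ann <- toy_annotation()
  mirror_ann <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ann),
    IRanges::IRanges(M + 1L - GenomicRanges::end(ann),
                     M + 1L - GenomicRanges::start(ann)),
    strand = ifelse(GenomicRanges::strand(ann) == "+", "-", "+"),
    type = ann$type, gene_id = ann$gene_id)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v <- rbind(toy_variant("chrA", 1100, "A", "G"),
             toy_variant("chrA", 2050, "T", "C"),
             toy_variant("chrA", 1150, "T", "C"))
  vm <- v
  vm$position <- M + 1L - v$position
  vm$ref <- unname(comp[v$ref])
  vm$alt <- unname(comp[v$alt])
  out <- strand_consistent_filter(v, ann)
  outm <- strand_consistent_filter(vm, mirror_ann)
  expect_setequal(M + 1L - outm$position, out$position)
  expect_setequal(outm$region, out$region)
})

test_that("count assembly takes the site union with zero fill", {
  groups <- c(f1 = "fusion", f2 = "fusion", c1 = "ctl")
  cand <- data.frame(
    contig = c("c1", "c1", "c1", "c1", "c2", "c2", "c2"),
    position = c(10, 10, 20, 30, 5, 6, 7),
    strand = "+", gene = "g", region = "3UTR",
    library = c("f1", "f2", "f1", "f2", "c1", "c1", "c1"),
    ref_count = 1:7, alt_count = 7:1, stringsAsFactors = FALSE)
  m <- assemble_count_matrix(cand, groups)
  expect_equal(nrow(m$sites), 6)  # union of disjoint sets: 3 + 3
  expect_equal(m$ref["c1:20:+", "f1"], 3L)
  expect_equal(m$ref["c1:20:+", "f2"], 0L)   # absent library -> (0, 0)
  expect_equal(m$alt["c1:20:+", "f2"], 0L)
  # permutation invariance up to column order
  m2 <- assemble_count_matrix(cand[sample(nrow(cand)), ], groups)
  expect_identical(m$ref, m2$ref)
  expect_identical(m$alt, m2$alt)
  expect_identical(m$sites, m2$sites)
  expect_error(assemble_count_matrix(cand, c(f1 = "fusion")), "missing")
  dup <- c(f1 = "fusion", f1 = "ctl")
  expect_error(assemble_count_matrix(cand[1, ], dup), "unique")
})

test_that("site table writes and reloads exactly", {
  sc <- small_scenario()
  ex <- simulate_counts(sc)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_site_table(ex$counts, path)
  back <- read_site_table(path)
  expect_identical(back$sites, ex$counts$sites)
  expect_identical(back$ref, ex$counts$ref)
  expect_identical(back$alt, ex$counts$alt)
  expect_identical(back$groups, ex$counts$groups)
})

test_that("genic distribution sums to one and flags empty input", {
  s <- data.frame(region = c(rep("3UTR", 94), rep("CDS", 5), "5UTR"))
  d <- classify_genic_distribution(s)
  expect_equal(unname(d["3UTR"]), 0.94)
  expect_equal(sum(d), 1)
  expect_equal(unname(classify_genic_distribution(
    data.frame(region = rep("CDS", 3)))["CDS"]), 1)
  expect_warning(d0 <- classify_genic_distribution(data.frame(region = character(0))),
                 "undefined")
  expect_true(all(is.na(d0)))
})
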