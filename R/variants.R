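# From variant calls to strand-consistent edit-site candidates.
#
# HyperTRIBE editing is A-to-I, read as A->G on the transcribed strand, so
# on the forward genomic strand a bona fide site is an A->G mismatch in a
# plus-strand transcript and a T->C mismatch in a minus-strand transcript.
# Known germline SNPs are removed because they are DNA-level variation.

.REGIONS <- c("3UTR", "CDS", "5UTR", "other")

#' Load biallelic SNVs with per-sample allelic depths from a VCF
#'
#' Splits multiallelic records into one row per alternative allele and
#' discards indels. Returns counts in long format, one row per
#' (variant, library).
#'
#' @param path VCF (v4.x) file; per-sample `AD` fields are required.
#' @return Data frame with columns `contig`, `position` (1-based), `ref`,
#'   `alt`, `library`, `ref_count`, `alt_count`.
#' @export
read_variants <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix  # always a matrix, even for a single record
  if (nrow(fix) == 0) {
    return(data.frame(contig = character(), position = integer(),
                      ref = character(), alt = character(),
                      library = character(), ref_count = integer(),
                      alt_count = integer()))
  }
  fmt <- vcf@gt[, 1]
  if (!all(grepl("(^|:)AD(:|$)", fmt))) {
    bad <- which(!grepl("(^|:)AD(:|$)", fmt))[1]
    stop(sprintf("record %s:%s lacks a per-sample AD (allelic depth) field",
                 fix[bad, "CHROM"], fix[bad, "POS"]))
  }
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (any(is.na(pos))) {
    stop(sprintf("malformed coordinate in VCF record %d",
                 which(is.na(pos))[1]))
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  samples <- colnames(ad)
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (nchar(ref) != 1L || !ref %in% c("A", "C", "G", "T")) next
    ad_i <- ad[i, ]
    absent <- is.na(ad_i) | ad_i == "." # no call: zero coverage
    depths <- lapply(strsplit(ifelse(absent, "", ad_i), ",", fixed = TRUE),
                     function(x) suppressWarnings(as.integer(x)))
    rows <- vector("list", length(alts))
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (nchar(alt) != 1L || !alt %in% c("A", "C", "G", "T")) next
      rc <- vapply(seq_along(depths), function(s) {
        d <- depths[[s]]
        if (absent[s]) return(c(0L, 0L))
        if (length(d) < j + 1L || any(is.na(d[c(1L, j + 1L)]))) {
          stop(sprintf("missing AD values at %s:%d", fix[i, "CHROM"], pos[i]))
        }
        d[c(1L, j + 1L)]
      }, integer(2))
      rows[[j]] <- data.frame(
        contig = unname(fix[i, "CHROM"]), position = pos[i],
        ref = unname(ref), alt = unname(alt), library = samples,
        ref_count = unname(rc[1, ]), alt_count = unname(rc[2, ]),
        stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(), position = integer(),
                      ref = character(), alt = character(),
                      library = character(), ref_count = integer(),
                      alt_count = integer())
  }
  rownames(res) <- NULL
  res
}

#' Read transcript annotation from GTF/GFF
#'
#' Imports gene/exon/UTR/CDS features and normalises feature-type naming
#' (`five_prime_utr`, `5UTR`, `three_prime_utr`, `3UTR`, `CDS`, `exon`).
#'
#' @param path GTF or GFF3 file.
#' @return A [GenomicRanges::GRanges] with metadata columns `type`
#'   (one of `exon`, `CDS`, `5UTR`, `3UTR`) and `gene_id`.
#' @export
read_transcript_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  type_map <- c(exon = "exon", CDS = "CDS",
                five_prime_utr = "5UTR", five_prime_UTR = "5UTR",
                `5UTR` = "5UTR", three_prime_utr = "3UTR",
                three_prime_UTR = "3UTR", `3UTR` = "3UTR")
  keep <- as.character(gr$type) %in% names(type_map)
  gr <- gr[keep]
  gr$type <- unname(type_map[as.character(gr$type)])
  if (is.null(gr$gene_id)) stop("annotation lacks gene_id attributes")
  gr
}

# Region priority used when a position is covered by several features or
# isoforms: 3'UTR first, reflecting where ADAR-fusion editing concentrates.
.region_rank <- function(region) match(region, .REGIONS)

#' Retain strand-consistent edit-site candidates
#'
#' Keeps A->G variants hosted by plus-strand transcripts and T->C variants
#' hosted by minus-strand transcripts (alleles as written on the forward
#' reference strand); everything else is removed. Variants outside any
#' annotated exon are dropped. Each surviving site is annotated with its
#' host gene and genic region; when several isoforms or genes overlap, the
#' region follows the priority 3'UTR > CDS > 5'UTR > other-exonic and the
#' primary gene is the one offering the highest-priority region.
#'
#' @param variants Data frame from [read_variants()].
#' @param annotation [GenomicRanges::GRanges] from
#'   [read_transcript_annotation()].
#' @return `variants` subset to consistent sites, with added columns
#'   `strand`, `gene`, `region`, and `all_genes` (comma-separated list of
#'   every consistent host gene).
#' @export
strand_consistent_filter <- function(variants, annotation) {
  stopifnot(is.data.frame(variants))
  is_ag <- variants$ref == "A" & variants$alt == "G"
  is_tc <- variants$ref == "T" & variants$alt == "C"
  v <- variants[is_ag | is_tc, , drop = FALSE]
  if (nrow(v) == 0) {
    return(cbind(v, strand = character(0), gene = character(0),
                 region = character(0), all_genes = character(0)))
  }
  need <- ifelse(v$ref == "A", "+", "-")
  known <- v$contig %in% GenomeInfoDb::seqlevels(annotation)
  n_unknown <- length(unique(v$contig[!known]))
  if (n_unknown > 0) {
    message(sprintf("dropping variants on %d unannotated contig(s)",
                    n_unknown))
    v <- v[known, , drop = FALSE]
    need <- need[known]
  }
  if (nrow(v) == 0) {
    return(cbind(v, strand = character(0), gene = character(0),
                 region = character(0), all_genes = character(0)))
  }
  vgr <- GenomicRanges::GRanges(
    factor(v$contig, GenomeInfoDb::seqlevels(annotation)),
    IRanges::IRanges(v$position, width = 1), strand = need)
  exons <- annotation[annotation$type == "exon"]
  feats <- annotation[annotation$type != "exon"]
  # strand-aware overlap: the host transcript must lie on the strand the
  # substitution implies
  hit_ex <- GenomicRanges::findOverlaps(vgr, exons, ignore.strand = FALSE)
  if (length(hit_ex) == 0) {
    v <- v[0, , drop = FALSE]
    return(cbind(v, strand = character(0), gene = character(0),
                 region = character(0), all_genes = character(0)))
  }
  hit_ft <- GenomicRanges::findOverlaps(vgr, feats, ignore.strand = FALSE)
  # per (variant, gene): best region among overlapping UTR/CDS features,
  # defaulting to other-exonic when only the exon matches
  ex_df <- data.frame(vi = S4Vectors::queryHits(hit_ex),
                      gene = exons$gene_id[S4Vectors::subjectHits(hit_ex)],
                      region = "other", stringsAsFactors = FALSE)
  ft_df <- data.frame(vi = S4Vectors::queryHits(hit_ft),
                      gene = feats$gene_id[S4Vectors::subjectHits(hit_ft)],
                      region = feats$type[S4Vectors::subjectHits(hit_ft)],
                      stringsAsFactors = FALSE)
  # UTR/CDS features count only where the gene's exon also contains the site
  ft_df <- ft_df[paste(ft_df$vi, ft_df$gene) %in%
                   paste(ex_df$vi, ex_df$gene), , drop = FALSE]
  all_df <- rbind(ex_df, ft_df)
  all_df$rank <- .region_rank(all_df$region)
  ord <- order(all_df$vi, all_df$rank, all_df$gene)
  all_df <- all_df[ord, , drop = FALSE]
  best <- all_df[!duplicated(all_df$vi), , drop = FALSE]
  genes_by_v <- vapply(split(all_df$gene, all_df$vi),
                       function(g) paste(sort(unique(g)), collapse = ","), "")
  keep <- best$vi
  out <- v[keep, , drop = FALSE]
  out$strand <- need[keep]
  out$gene <- best$gene
  out$region <- best$region
  out$all_genes <- unname(genes_by_v[as.character(best$vi)])
  rownames(out) <- NULL
  out
}

#' Read a known-SNP site list from BED or VCF
#'
#' BED intervals (0-based, half-open) are converted to 1-based positions;
#' multi-base intervals contribute every covered position.
#'
#' @param path `.bed` or `.vcf` file; format inferred from the extension.
#' @return Data frame with columns `contig` and `position` (1-based).
#' @export
read_snp_sites <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "bed") {
    if (length(readLines(path, n = 1L)) == 0) {
      return(data.frame(contig = character(), position = integer()))
    }
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    pos <- mapply(function(s, e) seq(s + 1L, e), bed[[2]], bed[[3]],
                  SIMPLIFY = FALSE)
    data.frame(contig = rep(bed[[1]], lengths(pos)),
               position = unlist(pos), stringsAsFactors = FALSE)
  } else if (ext == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    data.frame(contig = fix[, "CHROM"],
               position = as.integer(fix[, "POS"]),
               stringsAsFactors = FALSE)
  } else {
    stop("SNP site list must be a .bed or .vcf file")
  }
}

#' Remove candidates at known SNP positions
#'
#' @param candidates Data frame with `contig` and `position` columns
#'   (1-based), e.g. from [strand_consistent_filter()].
#' @param snp_sites Data frame from [read_snp_sites()] (or any frame with
#'   `contig`, `position`).
#' @return `candidates` without rows whose position appears in `snp_sites`.
#' @export
exclude_known_snps <- function(candidates, snp_sites) {
  stopifnot(is.data.frame(candidates), is.data.frame(snp_sites))
  if (nrow(snp_sites) == 0 || nrow(candidates) == 0) return(candidates)
  key <- paste(candidates$contig, candidates$position)
  snp <- unique(paste(snp_sites$contig, snp_sites$position))
  drop <- key %in% snp
  if (any(drop)) {
    message(sprintf("excluded %d candidate row(s) at known SNP positions",
                    sum(drop)))
  }
  candidates[!drop, , drop = FALSE]
}

#' Assemble the union site-by-library count matrix
#'
#' Combines filtered candidates from all libraries of one experiment:
#' the union of sites across libraries, with a (ref, alt) pair for every
#' library at every site. A library that reported no variant at a site
#' contributes (0, 0); such uncovered libraries are excluded from
#' frequency means downstream rather than read as frequency 0.
#'
#' @param candidates Long data frame (one row per site x library) with
#'   columns `contig`, `position`, `strand`, `gene`, `region`, `library`,
#'   `ref_count`, `alt_count`.
#' @param groups Named character vector, library name -> group label; its
#'   names define the full library set (a library may have zero candidate
#'   rows).
#' @return A [site_counts] object with rows keyed by
#'   (contig, position, strand).
#' @export
assemble_count_matrix <- function(candidates, groups) {
  stopifnot(is.data.frame(candidates))
  libs <- names(groups)
  if (is.null(libs) || anyDuplicated(libs)) {
    stop("'groups' must be a named vector with unique library names")
  }
  if (any(!nzchar(groups)) || any(is.na(groups))) {
    stop("every group label must be non-empty")
  }
  if (nrow(candidates) > 0 && !all(candidates$library %in% libs)) {
    bad <- setdiff(unique(candidates$library), libs)
    stop("candidate libraries missing from 'groups': ",
         paste(bad, collapse = ", "))
  }
  key <- paste(candidates$contig, candidates$position, candidates$strand,
               sep = ":")
  usite <- !duplicated(key)
  sites <- data.frame(contig = candidates$contig[usite],
                      position = candidates$position[usite],
                      strand = candidates$strand[usite],
                      gene = candidates$gene[usite],
                      region = candidates$region[usite],
                      stringsAsFactors = FALSE)
  ukey <- key[usite]
  ord <- order(sites$contig, sites$position, sites$strand)
  sites <- sites[ord, , drop = FALSE]
  ukey <- ukey[ord]
  ref <- alt <- matrix(0L, nrow(sites), length(libs),
                       dimnames = list(ukey, libs))
  ri <- match(key, ukey)
  ci <- match(candidates$library, libs)
  idx <- cbind(ri, ci)
  if (anyDuplicated(idx)) stop("duplicate (site, library) count entries")
  ref[idx] <- as.integer(candidates$ref_count)
  alt[idx] <- as.integer(candidates$alt_count)
  site_counts(sites, ref, alt, groups)
}

#' Genic distribution of edit sites
#'
#' @param sites Data frame with a `region` column (values among `5UTR`,
#'   `CDS`, `3UTR`, `other`).
#' @return Named numeric vector of proportions over the four regions,
#'   summing to 1; all-`NA` with a warning on empty input.
#' @export
classify_genic_distribution <- function(sites) {
  stopifnot(is.data.frame(sites), "region" %in% names(sites))
  if (nrow(sites) == 0) {
    warning("no sites: genic distribution undefined")
    return(stats::setNames(rep(NA_real_, length(.REGIONS)), .REGIONS))
  }
  bad <- setdiff(unique(sites$region), .REGIONS)
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(sites$region, levels = .REGIONS))
  prop <- as.numeric(tab) / nrow(sites)
  stats::setNames(prop, .REGIONS)
}
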