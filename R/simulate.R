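# Fully synthetic HyperTRIBE experiments: transcript models with planted
# motifs, and per-library allele counts drawn from the beta-binomial model,
# so the whole pipeline is testable without sequencing data.

#' Define a simulation scenario
#'
#' Defaults emulate a three-replicate HyperTRIBE experiment: strong editing
#' (mean frequency 0.35) at planted target sites in fusion libraries,
#' near-zero background editing elsewhere and in catalytic-dead/empty-vector
#' controls, negative-binomial read coverage around 100x, and a UAG-repeat
#' motif planted near true sites.
#'
#' @param n_genes Number of genes (one transcript, one contig each).
#' @param sites_per_gene Candidate edit sites per gene.
#' @param frac_true_sites Fraction of sites that are true targets.
#' @param mu_fusion Mean edit frequency at true sites in fusion libraries.
#' @param mu_control Mean edit frequency at true sites in control libraries.
#' @param mu_background Low-level editing at non-target sites (all groups).
#' @param rho Beta-binomial overdispersion shared by all groups.
#' @param coverage_mean,coverage_dispersion Negative-binomial read-depth
#'   model (`mu`, `size`) per site and library, scaled per gene by its
#'   expression factor.
#' @param replicates Named integer vector of libraries per group; the
#'   first name is the fusion group.
#' @param fpkm_scale Expression (fpkm) of a gene with unit expression
#'   factor; per-gene factors are Gamma(4, 4) distributed.
#' @param utr5_len,cds_len,utr3_len,flank_len Transcript geometry (bp).
#' @param utr3_fraction Fraction of sites placed in the 3'UTR (the rest go
#'   mostly to the CDS, occasionally the 5'UTR).
#' @param motif Consensus sequence planted near true sites.
#' @param motif_offset Distance (bp, site to motif start, transcript sense)
#'   at which instances are planted.
#' @param motif_prob Probability that a true site receives a planted motif.
#' @param n_snp_sites Decoy germline SNPs: A->G/T->C sites edited at ~50%
#'   in every group and listed in the known-SNP output.
#' @param seed Default RNG seed used when a generator is called without one.
#' @return A list of class `sim_scenario`.
#' @export
simulation_scenario <- function(n_genes = 500, sites_per_gene = 2,
                                frac_true_sites = 0.1, mu_fusion = 0.35,
                                mu_control = 0.02, mu_background = 0.005,
                                rho = 0.02, coverage_mean = 100,
                                coverage_dispersion = 5,
                                replicates = c(fusion = 3, dcd = 3, mig = 3),
                                fpkm_scale = 20,
                                utr5_len = 100, cds_len = 300,
                                utr3_len = 600, flank_len = 50,
                                utr3_fraction = 0.94,
                                motif = "TAGTAG", motif_offset = 30,
                                motif_prob = 1, n_snp_sites = 0,
                                seed = 42) {
  sc <- as.list(environment())
  probs <- c(sc$frac_true_sites, sc$mu_fusion, sc$mu_control,
             sc$mu_background, sc$rho, sc$utr3_fraction, sc$motif_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(sc$replicates < 1) || is.null(names(sc$replicates))) {
    stop("'replicates' must be a named vector of counts >= 1")
  }
  if (sc$n_genes < 1 || sc$sites_per_gene < 1) stop("need genes and sites")
  if (sc$coverage_mean <= 0) stop("'coverage_mean' must be positive")
  if (is.null(sc$seed)) stop("a seed is mandatory")
  structure(sc, class = "sim_scenario")
}

# Library names and group labels implied by the scenario.
.sim_libraries <- function(scenario) {
  grp <- rep(names(scenario$replicates), scenario$replicates)
  libs <- paste0(grp, ave(seq_along(grp), grp, FUN = seq_along))
  stats::setNames(grp, libs)
}

# Site bookkeeping shared by the count and genome generators: gene ids,
# expression factors, per-site region and truth flags. Assumes the RNG
# is already seeded.
.sim_sites <- function(scenario) {
  sc <- scenario
  genes <- sprintf("g%04d", seq_len(sc$n_genes))
  expr_factor <- stats::rgamma(sc$n_genes, shape = 4, rate = 4)
  n_sites <- sc$n_genes * sc$sites_per_gene
  gene_of <- rep(genes, each = sc$sites_per_gene)
  p_other <- 1 - sc$utr3_fraction
  region <- sample(c("3UTR", "CDS", "5UTR"), n_sites, replace = TRUE,
                   prob = c(sc$utr3_fraction, p_other * 5 / 6, p_other / 6))
  n_true <- round(sc$frac_true_sites * n_sites)
  true_site <- rep(FALSE, n_sites)
  true_site[sample.int(n_sites, n_true)] <- TRUE
  strand <- stats::setNames(sample(c("+", "-"), sc$n_genes, replace = TRUE),
                            genes)
  list(genes = genes, expr_factor = stats::setNames(expr_factor, genes),
       sites = data.frame(gene = gene_of, region = region,
                          true_site = true_site, is_snp = FALSE,
                          stringsAsFactors = FALSE),
       strand = strand)
}

#' Simulate per-site, per-library allele counts
#'
#' For every site and library, read depth is negative-binomial and the
#' edited-read count is beta-binomial: the latent per-library frequency is
#' drawn from the beta distribution of the library's group, then the count
#' is binomial. True sites use `mu_fusion` in fusion libraries and
#' `mu_control` in controls; background sites use `mu_background`
#' everywhere; decoy SNP sites are "edited" at 50% in all groups.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed RNG seed; defaults to the scenario's.
#' @param layout Optional result of [simulate_genome()] run on the same
#'   scenario and seed, so counts attach to its genomic coordinates.
#'   Without it, sites get synthetic coordinates (one contig per gene).
#' @return List: `counts` (a [site_counts]), `truth` (per-site data frame
#'   with `site`, `gene`, `region`, `true_site`, `is_snp`), `expression`
#'   (`gene`, `fpkm`), `target_genes` (genes owning a true site).
#' @export
simulate_counts <- function(scenario, seed = scenario$seed, layout = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  if (is.null(layout)) layout <- simulate_genome(sc, seed = seed)
  meta <- layout$sites
  groups <- .sim_libraries(sc)
  libs <- names(groups)
  set.seed(seed + 1L)
  n_sites <- nrow(meta)
  nlib <- length(libs)
  expr <- layout$expression
  mu_cov <- sc$coverage_mean * expr$factor[match(meta$gene, expr$gene)]
  nmat <- matrix(stats::rnbinom(n_sites * nlib, mu = rep(mu_cov, nlib),
                                size = sc$coverage_dispersion),
                 n_sites, nlib, dimnames = list(NULL, libs))
  if (all(nmat == 0)) stop("degenerate coverage: all libraries empty")
  is_fusion <- groups[libs] == names(sc$replicates)[1]
  mu_mat <- matrix(sc$mu_background, n_sites, nlib)
  mu_mat[meta$true_site, is_fusion] <- sc$mu_fusion
  mu_mat[meta$true_site, !is_fusion] <- sc$mu_control
  mu_mat[meta$is_snp, ] <- 0.5
  sh <- bb_shape(mu_mat, sc$rho)
  p <- matrix(stats::rbeta(n_sites * nlib, sh$alpha, sh$beta), n_sites, nlib)
  kmat <- matrix(stats::rbinom(n_sites * nlib, nmat, p), n_sites, nlib,
                 dimnames = list(NULL, libs))
  storage.mode(nmat) <- "integer"
  storage.mode(kmat) <- "integer"
  counts <- site_counts(
    meta[, c("contig", "position", "strand", "gene", "region")],
    ref = nmat - kmat, alt = kmat, groups = groups)
  truth <- cbind(site = counts$sites$site,
                 meta[, c("gene", "region", "true_site", "is_snp")])
  rownames(truth) <- NULL
  list(counts = counts, truth = truth,
       expression = data.frame(gene = expr$gene, fpkm = expr$fpkm,
                               stringsAsFactors = FALSE),
       target_genes = sort(unique(meta$gene[meta$true_site & !meta$is_snp])))
}

#' Simulate a toy genome, annotation, and planted motifs
#'
#' One contig per gene carrying a single-exon transcript with
#' 5'UTR/CDS/3'UTR structure on a random strand. Edit sites are placed
#' inside the configured regions with the reference base forced to `A`
#' (plus-strand genes) or `T` (minus-strand genes); motif instances are
#' written into the sequence at `motif_offset` from true sites, in
#' transcript sense.
#'
#' @inheritParams simulate_counts
#' @return List: `sequences` (`DNAStringSet`), `annotation` (`GRanges`
#'   with gene/exon/CDS/UTR features), `sites` (data frame with genomic
#'   coordinates, region, truth flags), `motifs` (planted instances:
#'   `contig`, `start`, `end`, `strand`), `snp_sites` (decoy SNP
#'   positions), `expression` (`gene`, `factor`, `fpkm`).
#' @export
simulate_genome <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  min_len <- 2 * sc$flank_len
  if (any(c(sc$utr5_len, sc$cds_len, sc$utr3_len) < 20)) {
    stop("transcript features too short for the requested structure")
  }
  set.seed(seed)
  base <- .sim_sites(sc)
  tx_len <- sc$utr5_len + sc$cds_len + sc$utr3_len
  contig_len <- tx_len + min_len
  seqs <- vapply(seq_len(sc$n_genes), function(i) {
    paste(sample(.BASES, contig_len, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- base$genes
  tx_start <- sc$flank_len + 1L
  tx_end <- sc$flank_len + tx_len
  # feature intervals in contig coordinates; on the minus strand the 3'UTR
  # sits at the left (lower-coordinate) end of the transcript
  feat_bounds <- function(strand) {
    if (strand == "+") {
      list(`5UTR` = c(tx_start, tx_start + sc$utr5_len - 1L),
           CDS = c(tx_start + sc$utr5_len,
                   tx_start + sc$utr5_len + sc$cds_len - 1L),
           `3UTR` = c(tx_end - sc$utr3_len + 1L, tx_end))
    } else {
      list(`3UTR` = c(tx_start, tx_start + sc$utr3_len - 1L),
           CDS = c(tx_start + sc$utr3_len,
                   tx_start + sc$utr3_len + sc$cds_len - 1L),
           `5UTR` = c(tx_end - sc$utr5_len + 1L, tx_end))
    }
  }
  meta <- base$sites
  meta$contig <- meta$gene
  meta$strand <- base$strand[meta$gene]
  motif_len <- nchar(sc$motif)
  # sample site positions per gene, keeping sites and their motif slots
  # from colliding
  meta$position <- NA_integer_
  motifs <- list()
  subst <- function(s, at, what) {
    substr(s, at, at + nchar(what) - 1L) <- what
    s
  }
  for (g in base$genes) {
    rows <- which(meta$gene == g)
    strand <- base$strand[g]
    fb <- feat_bounds(strand)
    taken <- integer(0)
    for (r in rows) {
      b <- fb[[meta$region[r]]]
      ok <- setdiff(seq(b[1], b[2]), unlist(lapply(taken, function(p) {
        (p - 2L * motif_len - sc$motif_offset):(p + 2L * motif_len +
                                                  sc$motif_offset)
      })))
      if (!length(ok)) stop("feature too crowded to place another site")
      pos <- if (length(ok) == 1) ok else sample(ok, 1)
      taken <- c(taken, pos)
      meta$position[r] <- pos
      seqs[g] <- subst(seqs[g], pos, if (strand == "+") "A" else "T")
      plant <- meta$true_site[r] && stats::runif(1) <= sc$motif_prob
      if (plant) {
        if (strand == "+") {
          mstart <- pos + sc$motif_offset
          mseq <- sc$motif
        } else {
          mstart <- pos - sc$motif_offset - motif_len + 1L
          mseq <- .revcomp(sc$motif)
        }
        if (mstart >= 1 && mstart + motif_len - 1L <= contig_len) {
          seqs[g] <- subst(seqs[g], mstart, mseq)
          motifs[[length(motifs) + 1L]] <-
            data.frame(contig = g, start = mstart,
                       end = mstart + motif_len - 1L, strand = strand,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  # decoy germline SNPs: extra strand-consistent positions, listed in the
  # known-SNP output and heterozygous in every group
  if (sc$n_snp_sites > 0) {
    snp_genes <- sample(base$genes, sc$n_snp_sites, replace = TRUE)
    snp <- data.frame(gene = snp_genes, region = "3UTR", true_site = FALSE,
                      is_snp = TRUE, contig = snp_genes,
                      strand = base$strand[snp_genes],
                      position = NA_integer_, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(snp))) {
      fb <- feat_bounds(snp$strand[i])[["3UTR"]]
      repeat {
        pos <- sample(seq(fb[1], fb[2]), 1)
        clash <- any(meta$contig == snp$contig[i] &
                       abs(meta$position - pos) <= motif_len, na.rm = TRUE)
        if (!clash) break
      }
      snp$position[i] <- pos
      seqs[snp$gene[i]] <- subst(seqs[snp$gene[i]], pos,
                                 if (snp$strand[i] == "+") "A" else "T")
      meta <- rbind(meta, snp[i, names(meta)])
    }
  }
  motifs <- if (length(motifs)) do.call(rbind, motifs) else
    data.frame(contig = character(), start = integer(), end = integer(),
               strand = character())
  ann <- lapply(base$genes, function(g) {
    strand <- base$strand[g]
    fb <- feat_bounds(strand)
    GenomicRanges::GRanges(
      g,
      IRanges::IRanges(c(tx_start, tx_start, fb$`5UTR`[1], fb$CDS[1],
                         fb$`3UTR`[1]),
                       c(tx_end, tx_end, fb$`5UTR`[2], fb$CDS[2],
                         fb$`3UTR`[2])),
      strand = strand,
      type = c("gene", "exon", "five_prime_utr", "CDS", "three_prime_utr"),
      gene_id = g, transcript_id = paste0(g, ".t1"))
  })
  ann <- suppressWarnings(do.call(c, ann))
  GenomeInfoDb::seqlengths(ann) <-
    stats::setNames(rep(contig_len, sc$n_genes), base$genes)
  ord <- order(meta$contig, meta$position)
  meta <- meta[ord, c("contig", "position", "strand", "gene", "region",
                      "true_site", "is_snp")]
  rownames(meta) <- NULL
  list(sequences = Biostrings::DNAStringSet(seqs), annotation = ann,
       sites = meta, motifs = motifs,
       snp_sites = meta[meta$is_snp, c("contig", "position")],
       expression = data.frame(gene = base$genes,
                               factor = unname(base$expr_factor),
                               fpkm = sc$fpkm_scale *
                                 unname(base$expr_factor),
                               stringsAsFactors = FALSE))
}

#' Simulate a complete experiment (genome + counts)
#'
#' @inheritParams simulate_counts
#' @return The union of [simulate_genome()] and [simulate_counts()]
#'   outputs, with counts attached to the genome's coordinates.
#' @export
simulate_experiment <- function(scenario, seed = scenario$seed) {
  layout <- simulate_genome(scenario, seed = seed)
  cnt <- simulate_counts(scenario, seed = seed, layout = layout)
  c(layout[c("sequences", "annotation", "motifs", "snp_sites")], cnt)
}

#' Write simulated counts as a multi-sample VCF
#'
#' Produces one record per site with the strand-implied alleles (`A->G` on
#' plus-strand transcripts, `T->C` on minus) and per-sample `AD` fields
#' matching the simulated counts, so the file round-trips through
#' [read_variants()] and [assemble_count_matrix()].
#'
#' @param counts A [site_counts] object.
#' @param path Output `.vcf` path.
#' @param contig_lengths Optional named lengths for `##contig` headers.
#' @param zero_policy `"record"` writes `AD` for every library;
#'   `"omit"` writes `.` for libraries with no reads at the site (both
#'   load back identically).
#' @return `path`, invisibly.
#' @export
write_fixture_vcf <- function(counts, path, contig_lengths = NULL,
                              zero_policy = c("record", "omit")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(counts, "site_counts"))
  s <- counts$sites
  if (!is.null(contig_lengths)) {
    bad <- s$position > contig_lengths[s$contig]
    if (any(bad, na.rm = TRUE) || any(is.na(bad))) {
      stop("site coordinate outside its declared contig length")
    }
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=tribekit-simulation",
           if (!is.null(contig_lengths)) {
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     contig_lengths)
           },
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", counts$libraries), collapse = "\t"))
  ref_allele <- ifelse(s$strand == "+", "A", "T")
  alt_allele <- ifelse(s$strand == "+", "G", "C")
  fields <- matrix(paste(counts$ref, counts$alt, sep = ","),
                   nrow(s), length(counts$libraries))
  if (zero_policy == "omit") {
    fields[counts$ref + counts$alt == 0] <- "."
  }
  body <- paste(s$contig, s$position, ".", ref_allele, alt_allele, ".",
                "PASS", ".", "AD",
                apply(fields, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulation fixtures to a directory
#'
#' Emits `genome.fa`, `annotation.gtf`, `variants.vcf`, `snps.bed`,
#' `motifs.bed`, `groups.yaml`, `truth.tsv`, and `expression.tsv`.
#'
#' @param experiment Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(experiment$sequences, p("genome.fa"))
  rtracklayer::export(experiment$annotation, p("annotation.gtf"),
                      format = "gtf")
  write_fixture_vcf(experiment$counts, p("variants.vcf"),
                    contig_lengths = stats::setNames(
                      Biostrings::width(experiment$sequences),
                      names(experiment$sequences)))
  snp <- experiment$snp_sites
  if (nrow(snp)) {
    utils::write.table(
      data.frame(snp$contig, snp$position - 1L, snp$position),
      p("snps.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  } else {
    file.create(p("snps.bed"))
  }
  if (nrow(experiment$motifs)) {
    utils::write.table(
      data.frame(experiment$motifs$contig, experiment$motifs$start - 1L,
                 experiment$motifs$end, ".", 0, experiment$motifs$strand),
      p("motifs.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  yaml::write_yaml(as.list(experiment$counts$groups), p("groups.yaml"))
  utils::write.table(experiment$truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(experiment$expression, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Planted-structure benchmark for clustering-window selection
#'
#' Builds a sequence landscape with the geometry the window-selection test
#' exploits: every strongly (significantly) edited site has a motif
#' instance wholly inside `[site - inner, site + inner]`, while weakly
#' (non-significantly) edited background sites flank the motif-anchored
#' binding footprint at a fixed edge distance `outer > inner`. Enrichment
#' around true sites is then significant exactly for half-widths below
#' `outer`, so [select_cluster_window()] should return a width between the
#' planted scale `inner` and `inner + motif length`.
#'
#' @param n_true,n_background Numbers of strongly and weakly edited sites.
#' @param motif Planted consensus sequence.
#' @param inner True-site clustering scale (bp): the motif start is placed
#'   `inner - motif length + 1` bp downstream so the instance ends exactly
#'   `inner` bp from the site.
#' @param outer Edge distance (bp) from each background site to the motif
#'   it flanks; must exceed `inner`.
#' @param seed RNG seed.
#' @return List: `significant_sites`, `background_sites` (data frames with
#'   `contig`, `position`), `sequences` (named character), `pwm_counts`
#'   (4 x L matrix for [motif_pwm()]), and `inner`/`outer` echoes.
#' @export
simulate_window_benchmark <- function(n_true = 60, n_background = 60,
                                      motif = "TAGTAG", inner = 15,
                                      outer = 18, seed = 1) {
  L <- nchar(motif)
  if (outer <= inner) stop("'outer' must exceed 'inner'")
  if (inner < L) stop("'inner' must be at least the motif length")
  set.seed(seed)
  spacing <- 400L
  n_anchor <- max(n_true, n_background)
  seq_len_total <- (n_anchor + 1L) * spacing
  s <- paste(sample(.BASES, seq_len_total, replace = TRUE), collapse = "")
  subst <- function(x, at, what) {
    substr(x, at, at + nchar(what) - 1L) <- what
    x
  }
  anchors <- spacing * seq_len(n_anchor)        # motif start positions
  for (a in anchors) s <- subst(s, a, motif)
  # true site: motif occupies [site + inner - L + 1, site + inner]
  true_pos <- anchors - (inner - L + 1L)
  # background site: edge distance to the motif is exactly `outer`
  bg_pos <- anchors + L - 1L + outer
  seqs <- stats::setNames(s, "synthetic_utr_pool")
  counts <- matrix(0, 4, L, dimnames = list(.BASES, NULL))
  for (i in seq_len(L)) counts[substr(motif, i, i), i] <- 20
  list(significant_sites = data.frame(contig = "synthetic_utr_pool",
                                      position = true_pos[seq_len(n_true)]),
       background_sites = data.frame(contig = "synthetic_utr_pool",
                                     position = bg_pos[seq_len(n_background)]),
       sequences = seqs, pwm_counts = counts, inner = inner, outer = outer)
}
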