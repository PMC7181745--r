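# Config-driven orchestration: filter -> count assembly -> beta-binomial
# tests -> FDR -> target calling -> clustering-window selection -> motif
# distances, with a machine-readable JSON report.

.PIPELINE_DEFAULTS <- list(
  fusion_group = "fusion",
  fdr = 0.05,
  fpkm_min = 5,
  difffreq_min = 0.1,
  motif_fraction = 0.9,
  cluster_width = "auto",
  widths = 1:50,
  alpha = 0.01,
  seed = 1,
  n_background_windows = 200
)

#' Validate a pipeline configuration
#'
#' Checks paths, thresholds, and group definitions, injects defaults, and
#' aggregates every problem into one error message.
#'
#' @param config Named list, or path to a YAML file with the same fields:
#'   `vcf`, `gtf`, `groups` (library -> group label) are required;
#'   `snps`, `fasta`, `pwm`, `expression`, `outdir` are optional inputs;
#'   tunables are `fusion_group`, `fdr` (number or preset name `MOLM13`,
#'   `LSC`, `LSK`, `HSPC`), `fpkm_min`, `difffreq_min`, `motif_fraction`,
#'   `cluster_width` (bp or `"auto"`), `widths`, `alpha`, `seed`,
#'   `n_background_windows`.
#' @return The validated config with defaults filled in and `fdr` resolved
#'   to a number.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, config)
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  for (f in c("vcf", "gtf")) {
    need(!is.null(cfg[[f]]) && file.exists(cfg[[f]]),
         sprintf("required input '%s' missing or not found", f))
  }
  for (f in c("snps", "fasta", "pwm", "expression")) {
    if (!is.null(cfg[[f]])) {
      need(file.exists(cfg[[f]]), sprintf("input '%s' not found: %s",
                                          f, cfg[[f]]))
    }
  }
  cfg$groups <- unlist(cfg$groups)
  need(length(cfg$groups) > 0 && !is.null(names(cfg$groups)) &&
         all(nzchar(names(cfg$groups))),
       "'groups' must map library names to group labels")
  need(anyDuplicated(names(cfg$groups)) == 0, "duplicate library names")
  if (length(cfg$groups)) {
    need(cfg$fusion_group %in% cfg$groups,
         sprintf("fusion group '%s' has no libraries", cfg$fusion_group))
  }
  cfg$fdr <- tryCatch(fdr_preset(cfg$fdr), error = function(e) {
    errs <<- c(errs, conditionMessage(e)); NA_real_
  })
  need(is.numeric(cfg$fpkm_min) && cfg$fpkm_min >= 0,
       "'fpkm_min' must be >= 0")
  need(is.numeric(cfg$difffreq_min) && cfg$difffreq_min >= 0 &&
         cfg$difffreq_min <= 1, "'difffreq_min' must lie in [0, 1]")
  need(is.numeric(cfg$motif_fraction) && cfg$motif_fraction > 0 &&
         cfg$motif_fraction <= 1, "'motif_fraction' must lie in (0, 1]")
  need(identical(cfg$cluster_width, "auto") ||
         (is.numeric(cfg$cluster_width) && cfg$cluster_width >= 0),
       "'cluster_width' must be \"auto\" or a nonnegative number")
  need(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
       "'alpha' must lie in (0, 1)")
  need(is.numeric(cfg$seed) && length(cfg$seed) == 1,
       "'seed' must be a single number")
  if (length(errs)) {
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  }
  cfg
}

#' Run the full target-identification pipeline
#'
#' Stages: load variants, strand-consistency filter, known-SNP exclusion,
#' count-matrix assembly, per-site beta-binomial differential-editing test
#' with BH FDR, gene-level target calling (when an expression table is
#' given), and — when sequences and a PWM are given — clustering-window
#' selection by motif enrichment, edit-site clustering, and site-to-motif
#' distances. Artifacts are written under `outdir` and a JSON report
#' summarises every stage.
#'
#' @param config See [validate_config()].
#' @return The run report (a list), invisibly; written to
#'   `<outdir>/report.json` when `outdir` is set.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  t0 <- Sys.time()
  out <- function(f) if (is.null(cfg$outdir)) NULL else file.path(cfg$outdir, f)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  }
  report <- list(package = "tribekit",
                 version = as.character(utils::packageVersion("tribekit")),
                 seed = cfg$seed,
                 config = cfg[setdiff(names(cfg), "groups")],
                 stages = list())
  stage <- function(name, expr) {
    t <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t, units = "secs")))
    res
  }

  variants <- stage("load_variants", read_variants(cfg$vcf))
  ann <- stage("read_annotation", read_transcript_annotation(cfg$gtf))
  cand <- stage("strand_filter", strand_consistent_filter(variants, ann))
  n_before_snp <- length(unique(paste(cand$contig, cand$position)))
  if (!is.null(cfg$snps)) {
    cand <- stage("exclude_snps",
                  exclude_known_snps(cand, read_snp_sites(cfg$snps)))
  }
  counts <- stage("assemble_counts", assemble_count_matrix(cand, cfg$groups))
  if (!is.null(out("sites.tsv"))) write_site_table(counts, out("sites.tsv"))
  results <- stage("test_editing",
                   test_editing(counts, fusion = cfg$fusion_group))
  if (!is.null(out("results.tsv"))) {
    utils::write.table(results, out("results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  sig <- call_significant_sites(results, cfg$fdr)
  report$stages$variants <- list(n_variant_rows = nrow(variants))
  report$stages$filtering <- list(
    n_candidate_sites = n_before_snp,
    n_sites_after_snp_filter = nrow(counts$sites))
  report$stages$testing <- list(
    n_tested_sites = nrow(results),
    n_significant_sites = nrow(sig),
    fdr_threshold = cfg$fdr,
    genic_distribution = as.list(classify_genic_distribution(sig)))

  if (!is.null(cfg$expression)) {
    expr <- utils::read.table(cfg$expression, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    targets <- stage("call_targets",
                     call_targets(results, expr, fpkm_min = cfg$fpkm_min,
                                  difffreq_min = cfg$difffreq_min,
                                  fdr_threshold = cfg$fdr))
    if (!is.null(out("targets.tsv"))) {
      utils::write.table(targets, out("targets.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    report$stages$targets <- list(
      n_target_genes = nrow(targets),
      fpkm_min = cfg$fpkm_min, difffreq_min = cfg$difffreq_min)
  }

  if (!is.null(cfg$fasta) && !is.null(cfg$pwm) && nrow(sig) > 0) {
    seqs <- Biostrings::readDNAStringSet(cfg$fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    pwm <- read_pwm(cfg$pwm)
    nonsig <- results[results$fdr >= cfg$fdr, , drop = FALSE]
    motif_report <- stage("motif_analysis", {
      win <- if (nrow(nonsig) > 0) {
        select_cluster_window(sig, nonsig, pwm, seqs, widths = cfg$widths,
                              alpha = cfg$alpha,
                              fraction = cfg$motif_fraction)
      } else {
        list(half_width = NA_integer_)
      }
      cw <- if (identical(cfg$cluster_width, "auto")) {
        win$half_width
      } else {
        cfg$cluster_width
      }
      cl <- if (!is.na(cw)) cluster_edit_sites(sig, cw) else NULL
      occ <- call_motif_occurrences(seqs, pwm,
                                    fraction = cfg$motif_fraction)
      dist <- distance_to_nearest(sig, occurrence_midpoints(occ))
      if (!is.null(out("motif_distances.tsv"))) {
        utils::write.table(
          data.frame(site = sig$site, distance = dist),
          out("motif_distances.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
      }
      list(selected_half_width = win$half_width,
           cluster_half_width = if (is.null(cl)) NA else cw,
           n_clusters = if (is.null(cl)) NA else length(cl$sizes),
           singleton_fraction = if (is.null(cl)) NA else
             cl$singleton_fraction,
           n_motif_occurrences = nrow(occ),
           median_distance_to_motif = stats::median(dist, na.rm = TRUE))
    })
    report$stages$motif <- motif_report
  }

  report$elapsed_seconds <- as.numeric(Sys.time() - t0, units = "secs")
  if (!is.null(out("report.json"))) {
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
  }
  invisible(report)
}
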