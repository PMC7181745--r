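# PWM scoring, occurrence calling, distances, windows, and clustering.

test_that("PWM construction applies the sampling correction", {
  counts <- consensus_pwm_counts("AC", weight = 10)
  pwm <- motif_pwm(counts, pseudocount = 0.5)
  expect_equal(colSums(pwm$prob), c(1, 1))
  expect_equal(unname(pwm$prob["A", 1]), 10.5 / 12)
  expect_equal(unname(pwm$prob["C", 1]), 0.5 / 12)
  expect_equal(pwm$consensus, "AC")
  expect_error(motif_pwm(counts[, 0, drop = FALSE]), "empty")
  expect_error(motif_pwm(matrix(1, 3, 4)), "4")
  # U rows accepted as T
  cu <- counts; rownames(cu) <- c("A", "C", "G", "U")
  expect_equal(motif_pwm(cu)$prob, pwm$prob)
})

test_that("scoring matches the symbolic hand expansion on a 2-column PWM", {
  # single fixed base per column, count w, pseudocount c, uniform background:
  # consensus column log-odds = log(((w + c)/(w + 4c)) / 0.25)
  w <- 10; cc <- 0.5
  pwm <- motif_pwm(consensus_pwm_counts("AC", weight = w), pseudocount = cc)
  hand_hit <- log(((w + cc) / (w + 4 * cc)) / 0.25)
  hand_miss <- log((cc / (w + 4 * cc)) / 0.25)
  s <- score_sequence("GACT", pwm)
  expect_equal(s[2], 2 * hand_hit)            # "AC": both columns hit
  expect_equal(pwm$max_score, 2 * hand_hit)   # consensus attains the max
  expect_equal(s[1], 2 * hand_miss)           # "GA": both columns miss
  expect_equal(s[3], hand_miss + hand_miss)   # "CT": both miss
  # translation equivariance: prepending bases shifts offsets
  s2 <- score_sequence("TTGACT", pwm)
  expect_equal(s2[3:5], s)
  # N voids every window containing it
  sn <- score_sequence("ANCA", pwm)
  expect_true(is.infinite(sn[1]) && is.infinite(sn[2]))
  expect_error(score_sequence("A", pwm), "shorter")
})

test_that("occurrence calling is inclusive at the threshold and monotone", {
  pwm <- motif_pwm(consensus_pwm_counts("TAGTAG"))
  seqs <- c(s1 = "GGGGTAGTAGGGGG", s2 = "CCCCCCCCCCCC")
  occ <- call_motif_occurrences(seqs, pwm, fraction = 0.9)
  expect_equal(occ$seqname, "s1")
  expect_equal(occ$start, 5)
  expect_equal(occ$end, 10)
  expect_equal(occ$score_frac, 1)
  # exact-threshold inclusivity: fraction = observed rescaled score
  sc <- score_sequence("TAGTAC", pwm)  # one mismatch
  fr <- (sc - pwm$min_score) / (pwm$max_score - pwm$min_score)
  occ_at <- call_motif_occurrences(c(x = "TAGTAC"), pwm, fraction = fr)
  expect_equal(nrow(occ_at), 1)
  occ_above <- call_motif_occurrences(c(x = "TAGTAC"), pwm,
                                      fraction = fr + 1e-9)
  expect_equal(nrow(occ_above), 0)
  # monotone: higher fraction yields a subset
  lo <- call_motif_occurrences(seqs, pwm, fraction = 0.5)
  hi <- call_motif_occurrences(seqs, pwm, fraction = 0.95)
  expect_true(all(paste(hi$seqname, hi$start) %in%
                    paste(lo$seqname, lo$start)))
  # overlapping qualifying offsets are all reported
  occ2 <- call_motif_occurrences(c(r = "TAGTAGTAG"), pwm, fraction = 0.9)
  expect_equal(occ2$start, c(1, 4))
  # reverse-strand scanning reports forward coordinates
  occ3 <- call_motif_occurrences(
    c(m = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("GGTAGTAGGG")))), pwm, both_strands = TRUE)
  expect_equal(occ3$strand, "-")
  expect_equal(occ3$start, 3)
  expect_error(call_motif_occurrences(seqs, pwm, fraction = 0), "fraction")
})

test_that("raw-score mode thresholds on unscaled log-odds", {
  pwm <- motif_pwm(consensus_pwm_counts("TAGTAG"))
  occ <- call_motif_occurrences(c(s = "TAGTAG"), pwm, mode = "raw")
  expect_equal(nrow(occ), 1)
  occ2 <- call_motif_occurrences(c(s = "TAGTAC"), pwm, mode = "raw")
  expect_equal(nrow(occ2), 0)  # one mismatch falls far below 0.9 * max
})

test_that("distance to nearest feature handles points and intervals", {
  expect_equal(distance_to_nearest(50, c(30, 90)), 20)
  expect_equal(distance_to_nearest(50, 50), 0)
  peaks <- data.frame(contig = ".", start = 40, end = 60)
  expect_equal(distance_to_nearest(50, peaks), 0)    # inside the peak
  expect_equal(distance_to_nearest(65, peaks), 5)    # to the nearest edge
  expect_equal(distance_to_nearest(39, peaks), 1)
  # per-contig separation and missing-feature NA
  sites <- data.frame(contig = c("c1", "c2"), position = c(10, 10))
  feats <- data.frame(contig = "c1", start = 13, end = 13)
  expect_equal(distance_to_nearest(sites, feats), c(3, NA))
  expect_true(all(is.na(distance_to_nearest(sites, feats[0, ]))))
  # reflection symmetry
  set.seed(91)
  s <- sample(1000, 20); f <- sample(1000, 10)
  expect_equal(distance_to_nearest(s, f),
               distance_to_nearest(1001 - s, 1001 - f))
})

test_that("window extraction truncates at ends and merges overlaps", {
  seqs <- c(c1 = paste(rep("A", 500), collapse = ""))
  w <- extract_site_windows(data.frame(contig = "c1",
                                       position = c(150, 200)), seqs)
  expect_equal(nrow(w), 1)                    # overlapping windows merge
  expect_equal(c(w$start, w$end), c(50, 300))
  expect_equal(w$n_sites, 2)
  w2 <- extract_site_windows(data.frame(contig = "c1", position = 20), seqs)
  expect_equal(c(w2$start, w2$end), c(1, 120))  # truncated at the 5' end
  w3 <- extract_site_windows(data.frame(contig = "c1",
                                        position = c(110, 380)), seqs)
  expect_equal(nrow(w3), 2)
  expect_equal(w3$end - w3$start + 1, c(201, 201))
  expect_error(extract_site_windows(data.frame(contig = "c1",
                                               position = 600), seqs),
               "outside")
  expect_error(extract_site_windows(data.frame(contig = "cX",
                                               position = 1), seqs),
               "unknown sequence")
})

test_that("background windows are 201 bp, in-UTR, and target-disjoint", {
  utr3 <- data.frame(contig = c("u1", "u2"), start = c(1, 1),
                     end = c(1000, 600))
  targets <- data.frame(contig = "u1", start = 300, end = 500)
  bg <- sample_background_windows(utr3, targets, n = 50, seed = 5)
  expect_equal(nrow(bg), 50)
  expect_true(all(bg$end - bg$start + 1 == 201))
  tg <- GenomicRanges::GRanges(targets$contig,
                               IRanges::IRanges(targets$start, targets$end))
  bgg <- GenomicRanges::GRanges(bg$contig,
                                IRanges::IRanges(bg$start, bg$end))
  expect_equal(sum(GenomicRanges::countOverlaps(bgg, tg)), 0)
  u3 <- GenomicRanges::GRanges(utr3$contig,
                               IRanges::IRanges(utr3$start, utr3$end))
  expect_true(all(GenomicRanges::countOverlaps(
    bgg, u3, type = "within") > 0))
  # determinism under the seed
  bg2 <- sample_background_windows(utr3, targets, n = 50, seed = 5)
  expect_identical(bg, bg2)
  # excluding all UTR space is an error reporting achievable n
  all_t <- data.frame(contig = c("u1", "u2"), start = 1, end = c(1000, 600))
  expect_error(sample_background_windows(utr3, all_t, n = 5, seed = 1),
               "insufficient")
  expect_error(sample_background_windows(utr3, targets, n = 1e6, seed = 1),
               "available")
})

test_that("Fisher's exact test matches full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2)), 1)  # zero margin
  set.seed(101)
  for (i in 1:300) {
    tab <- matrix(rpois(4, 5), 2)
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(fisher_exact_2x2(tab, alt),
                   fisher_enumeration_oracle(tab, alt), tolerance = 1e-9,
                   info = paste(c(tab, alt), collapse = ","))
    }
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("site clustering chains within the half-width", {
  s <- data.frame(contig = "c", position = c(100, 110, 130))
  cl <- cluster_edit_sites(s, 17)
  expect_equal(cl$assignments$cluster, c(1, 1, 2))
  expect_equal(sort(cl$sizes), c(1, 2))
  far <- data.frame(contig = "c", position = c(1, 100, 200))
  expect_equal(cluster_edit_sites(far, 17)$singleton_fraction, 1)
  # contig and strand boundaries break chains
  s2 <- data.frame(contig = c("c", "c", "d"), strand = c("+", "-", "+"),
                   position = c(100, 105, 100))
  expect_equal(max(cluster_edit_sites(s2, 17)$assignments$cluster), 3)
  # idempotence: clustering one representative per cluster changes nothing
  reps <- tapply(cl$assignments$position, cl$assignments$cluster, min)
  cl2 <- cluster_edit_sites(data.frame(contig = "c", position = as.numeric(reps)),
                            17)
  expect_equal(cl2$singleton_fraction, 1)
  expect_error(cluster_edit_sites(s, -1), "nonnegative")
})

test_that("window selection recovers the planted clustering scale", {
  b <- simulate_window_benchmark(n_true = 40, n_background = 40, seed = 3)
  sel <- select_cluster_window(b$significant_sites, b$background_sites,
                               motif_pwm(b$pwm_counts), b$sequences,
                               widths = 1:50)
  expect_true(sel$half_width >= b$inner &&
                sel$half_width <= b$inner + nchar("TAGTAG"))
  # perfectly separated toy table is significant
  expect_lt(fisher_exact_2x2(matrix(c(20, 0, 0, 20), 2, byrow = TRUE),
                             "greater"), 1e-6)
  # identical motif rates: explicit no-selection result
  flat <- data.frame(contig = "synthetic_utr_pool",
                     position = b$background_sites$position)
  sel0 <- select_cluster_window(flat, flat, motif_pwm(b$pwm_counts),
                                b$sequences, widths = c(5, 10))
  expect_true(is.na(sel0$half_width))
})

test_that("planted motif distances peak at the planted offset", {
  sc <- small_scenario(motif_offset = 30)
  ex <- simulate_experiment(sc)
  pwm <- motif_pwm(consensus_pwm_counts(sc$motif))
  occ <- call_motif_occurrences(ex$sequences, pwm, both_strands = TRUE)
  tr <- ex$counts$sites[ex$truth$true_site, ]
  d <- distance_to_nearest(tr[, c("contig", "position")],
                           data.frame(contig = occ$seqname,
                                      start = occ$start, end = occ$end))
  mode_d <- as.integer(names(which.max(table(d))))
  expect_equal(mode_d, 30)
})
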