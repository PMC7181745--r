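# PWM motif scanning, site-to-motif distances, and edit-site clustering.
#
# The motif model is a position count/weight matrix scored as log-odds
# against a background nucleotide distribution, with a pseudo-mass
# (sampling) correction so no column probability is zero. An occurrence is
# an offset whose score reaches 90% of the maximum attainable score; since
# log-odds can be negative, the default applies the rule on the score
# linearly rescaled so that the minimum attainable score maps to 0 and the
# maximum to itself (raw log-odds mode is available).

.BASES <- c("A", "C", "G", "T")

#' Build a motif model from a position count matrix
#'
#' @param counts 4 x L numeric matrix of per-position nucleotide counts
#'   (or probabilities, which are treated as counts), rows named
#'   `A`, `C`, `G`, `T` (`U` accepted for `T`).
#' @param background Named background nucleotide probabilities (sum 1);
#'   default uniform.
#' @param pseudocount Sampling-correction mass added to every cell of a
#'   column before normalising, so that no probability is zero; default 0.5.
#' @return Object of class `motif_pwm`: `prob` (corrected probabilities),
#'   `log_odds`, `background`, `length`, `max_score`, `min_score`,
#'   `consensus`.
#' @export
motif_pwm <- function(counts, background = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25),
                      pseudocount = 0.5) {
  stopifnot(is.matrix(counts), nrow(counts) == 4)
  if (ncol(counts) < 1) stop("empty PWM")
  rn <- toupper(rownames(counts))
  rn[rn == "U"] <- "T"
  if (!setequal(rn, .BASES)) stop("PWM rows must be named A, C, G, T/U")
  counts <- counts[match(.BASES, rn), , drop = FALSE]
  rownames(counts) <- .BASES
  if (any(counts < 0) || any(!is.finite(counts))) stop("invalid PWM counts")
  if (pseudocount <= 0) stop("'pseudocount' must be positive")
  bg <- background[.BASES]
  if (any(is.na(bg)) || any(bg <= 0) || abs(sum(bg) - 1) > 1e-6) {
    stop("'background' must be positive probabilities over A, C, G, T")
  }
  prob <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount,
                "/")
  lo <- log(prob) - log(bg)
  structure(list(prob = prob, log_odds = lo, background = bg,
                 length = ncol(prob),
                 max_score = sum(apply(lo, 2, max)),
                 min_score = sum(apply(lo, 2, min)),
                 consensus = paste(.BASES[apply(lo, 2, which.max)],
                                   collapse = "")),
            class = "motif_pwm")
}

#' @method print motif_pwm
#' @export
print.motif_pwm <- function(x, ...) {
  cat(sprintf("motif_pwm: length %d, consensus %s, score range [%.3f, %.3f]\n",
              x$length, x$consensus, x$min_score, x$max_score))
  invisible(x)
}

#' Read a PWM from a plain-text matrix file
#'
#' Accepts a 4 x L tab- or space-separated count/probability matrix with a
#' leading base column (`A`/`C`/`G`/`T`/`U`, JASPAR-style brackets
#' tolerated), optionally preceded by a `>` header line.
#'
#' @param path File path.
#' @param ... Passed to [motif_pwm()].
#' @return A `motif_pwm` object.
#' @export
read_pwm <- function(path, ...) {
  lines <- readLines(path)
  lines <- trimws(gsub("[][]", " ", lines))
  lines <- lines[nzchar(lines) & !startsWith(lines, ">") &
                   !startsWith(lines, "#")]
  if (length(lines) != 4) stop("PWM file must have 4 matrix rows")
  toks <- strsplit(lines, "[ \t]+")
  base <- toupper(vapply(toks, `[`, "", 1))
  vals <- lapply(toks, function(x) as.numeric(x[-1]))
  if (length(unique(lengths(vals))) != 1) stop("ragged PWM rows")
  m <- do.call(rbind, vals)
  rownames(m) <- base
  motif_pwm(m, ...)
}

# Integer-encode a sequence (N and anything non-ACGT -> NA).
.encode_seq <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "")[[1]], .BASES)
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Coerce sequences to a character vector without losing names.
.as_seqs <- function(x) {
  nms <- names(x)
  x <- as.character(x)
  names(x) <- nms
  x
}

#' Score every offset of a sequence against a PWM
#'
#' The score at an offset is the summed log-odds of the window's bases
#' under the corrected PWM probabilities versus the background. Offsets
#' containing `N` (or any non-ACGT base) score `-Inf`.
#'
#' @param sequence Character string (or `DNAString`) over A/C/G/T/N.
#' @param pwm A [motif_pwm()].
#' @return Numeric vector of length `nchar(sequence) - L + 1`; offset `i`
#'   scores the window starting at position `i` (1-based).
#' @export
score_sequence <- function(sequence, pwm) {
  stopifnot(inherits(pwm, "motif_pwm"))
  x <- .encode_seq(sequence)
  L <- pwm$length
  n_off <- length(x) - L + 1L
  if (n_off < 1) stop("sequence shorter than the motif")
  s <- numeric(n_off)
  for (i in seq_len(L)) {
    col <- unname(pwm$log_odds[, i])[x[i:(i + n_off - 1L)]]
    col[is.na(col)] <- -Inf
    s <- s + col
  }
  s
}

#' Call motif occurrences at a score threshold
#'
#' An offset is an occurrence when its score reaches `fraction` (default
#' 0.9) of the maximum attainable score. In the default `"rescaled"` mode
#' the rule is applied to `(score - min_score) / (max_score - min_score)`,
#' which is well defined for negative log-odds; `"raw"` mode compares
#' `score >= fraction * max_score` directly. The threshold is inclusive
#' and overlapping occurrences are all reported.
#'
#' @param sequences Named character vector (or `DNAStringSet`) of
#'   sequences to scan.
#' @param pwm A [motif_pwm()].
#' @param fraction Score fraction in (0, 1], default 0.9.
#' @param mode `"rescaled"` (default) or `"raw"`.
#' @param both_strands Also scan the reverse complement (genome-space
#'   scanning); transcript-space scanning keeps the default `FALSE`.
#' @return Data frame: `seqname`, `start`, `end` (1-based inclusive,
#'   forward-strand coordinates), `strand`, `score`, `score_frac`.
#' @export
call_motif_occurrences <- function(sequences, pwm, fraction = 0.9,
                                   mode = c("rescaled", "raw"),
                                   both_strands = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(pwm, "motif_pwm"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("'fraction' must lie in (0, 1]")
  }
  seqs <- .as_seqs(sequences)
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  L <- pwm$length
  span <- pwm$max_score - pwm$min_score
  frac_of <- function(s) {
    if (mode == "rescaled") (s - pwm$min_score) / span else s / pwm$max_score
  }
  one <- function(seq, nm, strand) {
    if (nchar(seq) < L) return(NULL)
    sc <- score_sequence(seq, pwm)
    fr <- frac_of(sc)
    hit <- which(is.finite(sc) & fr >= fraction)
    if (!length(hit)) return(NULL)
    start <- if (strand == "+") hit else nchar(seq) - (hit + L - 1L) + 1L
    data.frame(seqname = nm, start = start, end = start + L - 1L,
               strand = strand, score = sc[hit], score_frac = fr[hit],
               stringsAsFactors = FALSE)
  }
  out <- lapply(names(seqs), function(nm) {
    fwd <- one(seqs[[nm]], nm, "+")
    rev <- if (both_strands) one(.revcomp(seqs[[nm]]), nm, "-") else NULL
    rbind(fwd, rev)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), score_frac = numeric())
  }
  out <- out[order(out$seqname, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distance from each site to its nearest feature
#'
#' Features may be points (motif occurrence midpoints) or intervals (e.g.
#' CLIP peaks); the distance is to the nearest point of the feature, 0
#' when the site falls inside an interval.
#'
#' @param sites Data frame with `contig` and `position`, or a bare numeric
#'   vector of positions (single unnamed contig).
#' @param features Data frame with `contig`, `start`, `end` (1-based
#'   inclusive; use `start == end` for points), or a bare numeric vector
#'   of point positions.
#' @return Numeric vector, one distance per site; `NA` where the site's
#'   contig has no feature.
#' @export
distance_to_nearest <- function(sites, features) {
  if (is.numeric(sites)) {
    sites <- data.frame(contig = ".", position = sites)
  }
  if (is.numeric(features)) {
    features <- data.frame(contig = ".", start = features, end = features)
  }
  stopifnot(all(c("contig", "position") %in% names(sites)),
            all(c("contig", "start", "end") %in% names(features)))
  if (nrow(features) == 0) return(rep(NA_real_, nrow(sites)))
  if (any(features$end < features$start)) stop("feature end < start")
  lev <- union(unique(sites$contig), unique(features$contig))
  sgr <- GenomicRanges::GRanges(
    factor(sites$contig, lev),
    IRanges::IRanges(sites$position, width = 1))
  fgr <- GenomicRanges::GRanges(
    factor(features$contig, lev),
    IRanges::IRanges(features$start, features$end))
  # gap-based nearest, converted to arithmetic point distance (+1 when the
  # site does not overlap the feature)
  hits <- GenomicRanges::distanceToNearest(sgr, fgr, ignore.strand = TRUE)
  d <- rep(NA_real_, nrow(sites))
  qi <- S4Vectors::queryHits(hits)
  gap <- S4Vectors::mcols(hits)$distance
  ov <- GenomicRanges::countOverlaps(sgr, fgr, ignore.strand = TRUE) > 0
  d[qi] <- ifelse(ov[qi], 0, gap + 1)
  d
}

#' Midpoints of motif occurrences
#'
#' Convenience anchor for site-to-motif distances: the occurrence's centre
#' (rounded down for even motif lengths).
#'
#' @param occurrences Data frame from [call_motif_occurrences()].
#' @return Data frame with `contig`, `start`, `end` all at the midpoint,
#'   suitable for [distance_to_nearest()].
#' @export
occurrence_midpoints <- function(occurrences) {
  mid <- floor((occurrences$start + occurrences$end) / 2)
  data.frame(contig = occurrences$seqname, start = mid, end = mid,
             stringsAsFactors = FALSE)
}

#' Extract (and merge) sequence windows around edit sites
#'
#' Takes the `[position - half_width, position + half_width]` window around
#' each site, truncates at sequence ends, and merges overlapping or
#' book-ended windows into single stretches, recording the contributing
#' sites.
#'
#' @param sites Data frame with `contig` and `position` (1-based).
#' @param sequences Named character vector or `DNAStringSet` keyed by
#'   contig.
#' @param half_width Window half-width in bp; default 100 (201 bp windows).
#' @return Data frame: `contig`, `start`, `end`, `n_sites`, `sites`
#'   (comma-separated positions), `sequence`.
#' @export
extract_site_windows <- function(sites, sequences, half_width = 100) {
  stopifnot(all(c("contig", "position") %in% names(sites)), half_width >= 0)
  seqs <- .as_seqs(sequences)
  bad <- !sites$contig %in% names(seqs)
  if (any(bad)) {
    stop("site(s) on unknown sequence: ",
         paste(unique(sites$contig[bad]), collapse = ", "))
  }
  len <- nchar(seqs)[sites$contig]
  off <- sites$position < 1 | sites$position > len
  if (any(off)) {
    i <- which(off)[1]
    stop(sprintf("site %s:%d lies outside its sequence (length %d)",
                 sites$contig[i], sites$position[i], len[i]))
  }
  gr <- GenomicRanges::GRanges(
    sites$contig,
    IRanges::IRanges(pmax(1L, sites$position - half_width),
                     pmin(len, sites$position + half_width)))
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  ctg <- as.character(GenomicRanges::seqnames(red))
  st <- GenomicRanges::start(red)
  en <- GenomicRanges::end(red)
  data.frame(
    contig = ctg, start = st, end = en,
    n_sites = lengths(revmap),
    sites = vapply(revmap, function(i) {
      paste(sort(sites$position[i]), collapse = ",")
    }, ""),
    sequence = substr(seqs[ctg], st, en),
    stringsAsFactors = FALSE)
}

#' Sample background windows from 3'UTR space
#'
#' Draws fixed-width windows uniformly from the 3'UTR intervals after
#' removing any position covered by the target window pool, so sampled
#' windows can never overlap a target window. Sampling is without
#' replacement over all eligible start positions.
#'
#' @param utr3 Data frame with `contig`, `start`, `end` (1-based
#'   inclusive) of 3'UTR intervals, or a `GRanges`.
#' @param target_windows Data frame with `contig`, `start`, `end` of
#'   windows to exclude (e.g. from [extract_site_windows()]); may be empty.
#' @param n Number of windows to draw.
#' @param width Window width in bp, default 201.
#' @param seed Mandatory RNG seed for reproducibility.
#' @param sequences Optional named sequences; when given, a `sequence`
#'   column is added.
#' @return Data frame: `contig`, `start`, `end` (and `sequence`).
#' @export
sample_background_windows <- function(utr3, target_windows, n, width = 201,
                                      seed, sequences = NULL) {
  if (missing(seed)) stop("'seed' is required")
  as_gr <- function(x) {
    if (methods::is(x, "GRanges")) return(GenomicRanges::granges(x))
    if (nrow(x) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(x$contig, IRanges::IRanges(x$start, x$end))
  }
  eligible <- GenomicRanges::setdiff(GenomicRanges::reduce(as_gr(utr3)),
                                     as_gr(target_windows),
                                     ignore.strand = TRUE)
  starts_per <- pmax(0L, GenomicRanges::width(eligible) - width + 1L)
  total <- sum(starts_per)
  if (total < n) {
    stop(sprintf(
      "insufficient eligible 3'UTR space: %d start position(s) available, %d requested",
      total, n))
  }
  set.seed(seed)
  pick <- sort(sample.int(total, n))
  cum <- cumsum(starts_per)
  iv <- findInterval(pick - 1L, cum) + 1L
  offset <- pick - c(0L, cum)[iv] - 1L
  ctg <- as.character(GenomicRanges::seqnames(eligible))[iv]
  st <- GenomicRanges::start(eligible)[iv] + offset
  out <- data.frame(contig = ctg, start = st, end = st + width - 1L,
                    stringsAsFactors = FALSE)
  if (!is.null(sequences)) {
    seqs <- .as_seqs(sequences)
    out$sequence <- substr(seqs[out$contig], out$start, out$end)
  }
  rownames(out) <- NULL
  out
}

#' Fisher's exact test on a 2x2 table
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param alternative `"two.sided"`, `"greater"`, or `"less"` (on the odds
#'   ratio of the first cell).
#' @return The exact p-value.
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0) || any(table != round(table))) {
    stop("table entries must be nonnegative integers")
  }
  stats::fisher.test(table, alternative = alternative)$p.value
}

#' Choose the edit-site clustering window by motif enrichment
#'
#' For each candidate half-width `W`, classifies every significantly
#' edited ("true") and non-significant ("background") site by whether at
#' least one motif occurrence overlaps its `[position - W, position + W]`
#' window, and tests enrichment in true sites with a one-sided Fisher's
#' exact test. Returns the largest `W` whose p-value is below `alpha`.
#'
#' @param significant_sites,background_sites Data frames with `contig`,
#'   `position` columns.
#' @param pwm A [motif_pwm()].
#' @param sequences Named sequences keyed by contig.
#' @param widths Candidate half-widths (bp), ascending; default 1..50.
#' @param alpha Significance level, default 0.01.
#' @param fraction,mode Occurrence-calling parameters, see
#'   [call_motif_occurrences()].
#' @return List: `half_width` (chosen `W`, or `NA` when no width is
#'   significant) and `table` (per-width contingency counts and p-values).
#' @export
select_cluster_window <- function(significant_sites, background_sites, pwm,
                                  sequences, widths = 1:50, alpha = 0.01,
                                  fraction = 0.9, mode = "rescaled") {
  stopifnot(nrow(significant_sites) > 0, nrow(background_sites) > 0,
            !is.unsorted(widths), all(widths >= 0))
  seqs <- .as_seqs(sequences)
  occ <- call_motif_occurrences(seqs, pwm, fraction = fraction, mode = mode)
  # nearest-occurrence distance per site, measured edge-to-edge, so a site
  # window of half-width W contains an occurrence iff the distance <= W
  site_gap <- function(sites) {
    d <- distance_to_nearest(sites,
                             occ[, c("seqname", "start", "end")] |>
                               stats::setNames(c("contig", "start", "end")))
    d[is.na(d)] <- Inf
    d
  }
  d_true <- site_gap(significant_sites)
  d_bg <- site_gap(background_sites)
  rows <- lapply(widths, function(w) {
    a <- sum(d_true <= w); b <- length(d_true) - a
    c <- sum(d_bg <= w); d <- length(d_bg) - c
    p <- fisher_exact_2x2(matrix(c(a, b, c, d), 2, byrow = TRUE),
                          alternative = "greater")
    data.frame(half_width = w, true_with = a, true_without = b,
               background_with = c, background_without = d, p_value = p)
  })
  tab <- do.call(rbind, rows)
  sig <- tab$half_width[tab$p_value < alpha]
  list(half_width = if (length(sig)) max(sig) else NA_integer_, table = tab)
}

#' Cluster nearby edit sites by single-linkage chaining
#'
#' Consecutive sites on the same contig and strand whose positions differ
#' by at most `half_width` join the same cluster.
#'
#' @param sites Data frame with `contig`, `position`, and optionally
#'   `strand` columns.
#' @param half_width Maximum chaining distance in bp (>= 0).
#' @return List: `assignments` (`sites` plus a `cluster` id column),
#'   `sizes` (table of cluster sizes), `singleton_fraction`.
#' @export
cluster_edit_sites <- function(sites, half_width) {
  stopifnot(all(c("contig", "position") %in% names(sites)))
  if (!is.numeric(half_width) || half_width < 0) {
    stop("'half_width' must be a nonnegative number")
  }
  strand <- if ("strand" %in% names(sites)) sites$strand else "."
  key <- paste(sites$contig, strand)
  ord <- order(key, sites$position)
  pos <- sites$position[ord]
  newc <- c(TRUE, diff(pos) > half_width | key[ord][-1] != key[ord][-length(ord)])
  cl <- cumsum(newc)
  out <- sites
  out$cluster <- NA_integer_
  out$cluster[ord] <- cl
  sizes <- table(cl)
  list(assignments = out, sizes = as.integer(sizes),
       singleton_fraction = mean(sizes == 1))
}
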