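# SiteCountMatrix: per-site, per-library (ref, alt) read counts with group
# labels, the interchange object between variant filtering and testing.

#' Construct a site-by-library count container
#'
#' @param sites Data frame with columns `contig`, `position` (1-based),
#'   `strand`, `gene`, `region`; one row per edit-site candidate.
#' @param ref,alt Integer matrices (sites x libraries) of reads supporting
#'   the reference (A/T) and alternative (G/C) alleles. A library without
#'   coverage at a site contributes `(0, 0)`.
#' @param groups Named character vector mapping each library (column) name
#'   to its group label (e.g. `fusion`, `dcd`, `mig`, or a cell type).
#' @return An object of class `site_counts`.
#' @export
site_counts <- function(sites, ref, alt, groups) {
  stopifnot(is.data.frame(sites), is.matrix(ref), is.matrix(alt))
  req <- c("contig", "position", "strand", "gene", "region")
  if (!all(req %in% names(sites))) {
    stop("'sites' must have columns: ", paste(req, collapse = ", "))
  }
  if (!identical(dim(ref), dim(alt))) stop("'ref' and 'alt' dims differ")
  if (nrow(ref) != nrow(sites)) stop("count rows must match 'sites'")
  if (is.null(colnames(ref)) || !identical(colnames(ref), colnames(alt))) {
    stop("'ref' and 'alt' must share library column names")
  }
  if (anyDuplicated(colnames(ref))) stop("duplicate library names")
  if (any(ref < 0) || any(alt < 0)) stop("negative read counts")
  libs <- colnames(ref)
  if (!all(libs %in% names(groups))) {
    stop("every library needs a group label in 'groups'")
  }
  groups <- groups[libs]
  if (any(!nzchar(groups)) || any(is.na(groups))) stop("empty group label")
  key <- paste(sites$contig, sites$position, sites$strand, sep = ":")
  if (anyDuplicated(key)) stop("duplicate (contig, position, strand) rows")
  sites <- cbind(site = key, sites, stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  rownames(ref) <- rownames(alt) <- key
  storage.mode(ref) <- "integer"
  storage.mode(alt) <- "integer"
  structure(list(sites = sites, ref = ref, alt = alt,
                 libraries = libs, groups = groups),
            class = "site_counts")
}

#' @method print site_counts
#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf("site_counts: %d sites x %d libraries\n",
              nrow(x$sites), length(x$libraries)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.site_counts <- function(x) c(nrow(x$sites), length(x$libraries))

#' Subset a site_counts object by site rows
#'
#' @param x A `site_counts` object.
#' @param i Row index (logical, integer, or site keys).
#' @param ... Unused.
#' @export
`[.site_counts` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sites$site)
  site_counts(x$sites[i, setdiff(names(x$sites), "site"), drop = FALSE],
              x$ref[i, , drop = FALSE], x$alt[i, , drop = FALSE], x$groups)
}

#' Write a site count table
#'
#' Tab-separated with header
#' `contig position strand gene region <lib>_ref <lib>_alt ...` and a
#' leading comment line recording the group labels and the 1-based
#' inclusive coordinate convention.
#'
#' @param counts A [site_counts] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(counts, path) {
  stopifnot(inherits(counts, "site_counts"))
  cols <- as.vector(rbind(paste0(counts$libraries, "_ref"),
                          paste0(counts$libraries, "_alt")))
  m <- matrix(0L, nrow(counts$sites), 2 * length(counts$libraries),
              dimnames = list(NULL, cols))
  m[, seq(1, ncol(m), 2)] <- counts$ref
  m[, seq(2, ncol(m), 2)] <- counts$alt
  df <- cbind(counts$sites[, c("contig", "position", "strand",
                               "gene", "region")], m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# coordinates: 1-based inclusive; groups: %s",
                     paste(sprintf("%s=%s", counts$libraries, counts$groups),
                           collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a site count table written by [write_site_table()]
#'
#' @param path File path.
#' @return A [site_counts] object.
#' @export
read_site_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#")) stop("missing site-table header comment")
  gspec <- sub(".*groups: ", "", first)
  pairs <- strsplit(strsplit(gspec, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  groups <- vapply(pairs, `[`, "", 2)
  names(groups) <- vapply(pairs, `[`, "", 1)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  libs <- names(groups)
  ref <- as.matrix(df[, paste0(libs, "_ref"), drop = FALSE])
  alt <- as.matrix(df[, paste0(libs, "_alt"), drop = FALSE])
  colnames(ref) <- colnames(alt) <- libs
  site_counts(df[, c("contig", "position", "strand", "gene", "region")],
              ref, alt, groups)
}
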