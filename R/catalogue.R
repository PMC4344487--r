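# Non-redundant per-TF binding sites and the cross-TF CRM/singleton
# catalogue.  Merging uses >= 1 bp overlap under 0-based half-open
# semantics: book-ended features (end == next start) are NOT merged.

#' Merge one TF's peaks into non-redundant binding sites
#'
#' The non-redundant sites are the connected components of the >= 1 bp
#' overlap relation over all of the TF's peaks (across datasets).  Each
#' component's interval spans `[min start, max end)`; its summit is the
#' arithmetic mean of the member summits, rounded half-up.
#'
#' @param peaks A peaks data.frame; all dataset labels must carry the same
#'   TF name (or supply `tf` when peaks carry no labels).
#' @param tf Optional TF name override.
#' @return A sites data.frame: `chrom`, `start`, `end`, `tf`, `summit`,
#'   `n_members`, plus list-columns `member_summits` and `source_datasets`,
#'   sorted by `(chrom, start)`.
#' @export
merge_tf_peaks <- function(peaks, tf = NULL) {
  .check_intervals(peaks, "merge_tf_peaks")
  if (is.null(tf)) {
    tfs <- unique(.label_tf(unique(peaks$dataset)))
    if (length(tfs) > 1L) {
      stop("input error: peaks from multiple TFs (",
           paste(tfs, collapse = ", "), ")", call. = FALSE)
    }
    tf <- if (length(tfs)) tfs else NA_character_
  }
  if (nrow(peaks) == 0L) return(.empty_sites())
  comp <- .overlap_components(peaks)
  out <- comp$regions
  out$tf <- tf
  out$member_summits <- lapply(comp$members, function(i) peaks$summit[i])
  out$source_datasets <- lapply(comp$members, function(i) peaks$dataset[i])
  out$summit <- as.integer(.round_half_up(
    vapply(out$member_summits, mean, 0)))
  # contained members make this a no-op; kept for determinism
  out$summit <- pmax(out$start, pmin(out$summit, out$end - 1L))
  out$n_members <- lengths(out$member_summits)
  rownames(out) <- NULL
  out[c("chrom", "start", "end", "tf", "summit", "n_members",
        "member_summits", "source_datasets")]
}

.empty_sites <- function() {
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), tf = character(0),
                    summit = integer(0), n_members = integer(0),
                    stringsAsFactors = FALSE)
  out$member_summits <- list()
  out$source_datasets <- list()
  out
}

# Connected components of the >= 1 bp overlap relation; returns merged
# intervals (sorted) and the member row indices of each component.
.overlap_components <- function(df) {
  gr <- .as_granges(df)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  ord <- order(as.character(GenomicRanges::seqnames(red)),
               IRanges::start(red))
  red <- red[ord]
  regions <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = IRanges::start(red) - 1L,
    end = IRanges::end(red),
    stringsAsFactors = FALSE)
  list(regions = regions,
       members = as.list(S4Vectors::mcols(red)$revmap))
}

#' Build the CRM/singleton catalogue
#'
#' Merges the non-redundant sites of all TFs by >= 1 bp overlap; each
#' resulting region carries the union of member TF names.  Regions bound by
#' two or more distinct TFs are CRMs, regions bound by one TF singletons.
#'
#' @param sites A sites data.frame (rows from [merge_tf_peaks()] over all
#'   TFs, concatenated), or any interval data.frame with a `tf` column.
#' @return A catalogue data.frame: `chrom`, `start`, `end`, `tf_set`
#'   (list-column, sorted), `n_tfs`, `n_sites` (member site count), `kind`,
#'   sorted by `(chrom, start)`.
#' @export
build_crms <- function(sites) {
  .check_intervals(sites, "build_crms")
  stopifnot("tf" %in% names(sites))
  if (nrow(sites) == 0L) return(.empty_catalogue())
  comp <- .overlap_components(sites)
  out <- comp$regions
  out$tf_set <- lapply(comp$members, function(i) sort(unique(sites$tf[i])))
  out$n_tfs <- lengths(out$tf_set)
  out$n_sites <- lengths(comp$members)
  out$kind <- ifelse(out$n_tfs >= 2L, "crm", "singleton")
  rownames(out) <- NULL
  out
}

#' Binding-complexity distribution
#'
#' Histogram of catalogue regions by the number of distinct bound TFs,
#' mapped into bins.  `bin_spec` gives the lower edge of every bin; a bin
#' runs up to the next edge (the last bin is open-ended).  The default
#' `c(1:15, 50)` reproduces the grouping 1, 2, ..., 14, 15-49, 50+.
#'
#' @param regions A catalogue data.frame.
#' @param bin_spec Increasing integer vector of bin lower edges starting
#'   at 1.
#' @return data.frame `bin` (label), `lower`, `count`, `proportion`.
#' @export
complexity_distribution <- function(regions, bin_spec = c(1:15, 50L)) {
  stopifnot(all(diff(bin_spec) > 0), bin_spec[1] == 1L)
  n_tfs <- if ("n_tfs" %in% names(regions)) regions$n_tfs else {
    lengths(regions$tf_set)
  }
  edges <- c(bin_spec, Inf)
  labels <- vapply(seq_along(bin_spec), function(i) {
    lo <- bin_spec[i]; hi <- edges[i + 1] - 1
    if (is.infinite(hi)) paste0(lo, "+")
    else if (hi == lo) as.character(lo)
    else paste0(lo, "-", hi)
  }, "")
  idx <- findInterval(n_tfs, bin_spec)
  count <- vapply(seq_along(bin_spec), function(i) sum(idx == i), 0L)
  total <- sum(count)
  data.frame(bin = labels, lower = bin_spec, count = count,
             proportion = if (total > 0) count / total else rep(0, length(count)),
             stringsAsFactors = FALSE)
}

#' Summit displacement statistics
#'
#' Mean and median of `|site summit - member summit|` over every
#' (site, member-peak) pair of a non-redundant site set; quantifies how far
#' individual dataset summits sit from the averaged summit.
#'
#' @param sites A sites data.frame from [merge_tf_peaks()] (non-empty).
#' @return List with `mean`, `median` and `n_pairs`.
#' @export
summit_displacement_stats <- function(sites) {
  if (nrow(sites) == 0L) stop("empty input", call. = FALSE)
  d <- abs(unlist(Map(function(m, s) m - s, sites$member_summits,
                      sites$summit)))
  list(mean = mean(d), median = stats::median(d), n_pairs = length(d))
}
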