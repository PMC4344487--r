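# Hypergeometric TF enrichment of catalogue regions in user-supplied query
# region sets (e.g. gained/lost variant enhancer loci).

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for X hypergeometric with `K` marked regions among `N`, `n`
#' drawn: `sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n)`.  Computed in
#' log space (via [stats::phyper()]), stable for `N` up to 1e7.
#'
#' @param k Observed overlap count (vectorised).
#' @param K Regions containing the TF.
#' @param n Regions hit by the query set.
#' @param N Universe size.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(k < 0 | k > pmin(K, n)) || any(K > N) || any(n > N) ||
      any(c(k, K, n, N) != floor(c(k, K, n, N)))) {
    stop("domain error: need integers 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

.catalogue_tf_index <- function(catalogue) {
  tfs <- unlist(catalogue$tf_set)
  data.frame(tf = tfs,
             region = rep(seq_len(nrow(catalogue)),
                          lengths(catalogue$tf_set)),
             stringsAsFactors = FALSE)
}

#' TF enrichment in query regions
#'
#' The universe is the full catalogue (CRMs and singletons; `N` regions).
#' A catalogue region is "hit" when it overlaps the query set: by >= 1 bp
#' (`mode = "bp1"`) or with a placement-null overlap p-value at most `alpha`
#' (`mode = "placement"`, see [interval_overlap_pvalue()]).  Each TF is then
#' tested for over-representation of its regions (`K` of `N`) among the hit
#' regions (`k` of `n`) with the upper-tail hypergeometric test, followed by
#' multiple-testing correction across TFs.
#'
#' @param catalogue A non-empty catalogue data.frame.
#' @param query_regions A non-empty interval data.frame.
#' @param mode Overlap mode, `"bp1"` (default) or `"placement"`.
#' @param alpha Significance threshold for `mode = "placement"`.
#' @param correction `"BH"` (default), `"bonferroni"` or `"none"`.
#' @param domain Optional domain for `mode = "placement"`; default padded
#'   union of the catalogue.
#' @return data.frame (one row per TF, ranked by p-value, ties broken by
#'   descending fold then TF name): `tf`, `N`, `K`, `n`, `k`, `fold`
#'   (`(k/n)/(K/N)`), `p_value`, `q_value`, `rank`.
#' @export
tf_enrichment <- function(catalogue, query_regions,
                          mode = c("bp1", "placement"), alpha = 0.05,
                          correction = c("BH", "bonferroni", "none"),
                          domain = NULL) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  stopifnot(nrow(catalogue) > 0L, nrow(query_regions) > 0L)
  .check_intervals(catalogue, "catalogue")
  .check_intervals(query_regions, "query_regions")
  N <- nrow(catalogue)
  if (mode == "bp1") {
    hit <- suppressWarnings(
      GenomicRanges::countOverlaps(.as_granges(catalogue),
                                   .as_granges(query_regions))) > 0
  } else {
    if (is.null(domain)) domain <- colocalization_domain(catalogue)
    p <- .pn_pvalues(catalogue$chrom, catalogue$start, catalogue$end,
                     .pn_intervals(query_regions), .pn_intervals(domain))
    hit <- !is.na(p) & p <= alpha
  }
  n <- sum(hit)
  if (n == 0L) warning("zero hit regions: all p-values are 1", call. = FALSE)
  idx <- .catalogue_tf_index(catalogue)
  tfs <- sort(unique(idx$tf))
  K <- vapply(tfs, function(tf) sum(idx$tf == tf), 0L)
  k <- vapply(tfs, function(tf) sum(hit[idx$region[idx$tf == tf]]), 0L)
  p <- hypergeom_upper_tail(k, K, n, N)
  fold <- if (n > 0L) (k / n) / (K / N) else rep(NA_real_, length(tfs))
  q <- stats::p.adjust(p, method = if (correction == "none") "none"
                       else correction)
  out <- data.frame(tf = tfs, N = N, K = K, n = n, k = k, fold = fold,
                    p_value = p, q_value = q, stringsAsFactors = FALSE)
  ord <- order(out$p_value, -out$fold, out$tf)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Gained/lost enrichment report
#'
#' Runs [tf_enrichment()] independently on two query sets (e.g. gained and
#' lost variant enhancer loci) and summarises the catalogue coverage of each
#' set (percentage of query regions overlapping >= 1 catalogue region).
#'
#' @param catalogue A catalogue data.frame.
#' @param gained,lost Non-empty interval data.frames.
#' @param ... Passed to [tf_enrichment()].
#' @return List with `gained`, `lost` (ranked enrichment tables) and
#'   `coverage` (named percentages).
#' @export
gained_lost_report <- function(catalogue, gained, lost, ...) {
  stopifnot(nrow(gained) > 0L, nrow(lost) > 0L)
  coverage <- function(q) {
    100 * mean(suppressWarnings(
      GenomicRanges::countOverlaps(.as_granges(q),
                                   .as_granges(catalogue))) > 0)
  }
  list(gained = tf_enrichment(catalogue, gained, ...),
       lost = tf_enrichment(catalogue, lost, ...),
       coverage = c(gained = coverage(gained), lost = coverage(lost)))
}
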