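# CRM saturation analysis: how the number of discovered CRMs grows as TFs
# are added to the catalogue.

#' CRM count for a TF subset
#'
#' Number of multi-TF regions obtained when the catalogue is rebuilt from
#' the sites of `tf_subset` only.  Single-TF subsets therefore give 0.
#'
#' @param sites A sites data.frame with a `tf` column.
#' @param tf_subset Non-empty character vector of TFs present in `sites`.
#' @param include_singletons Count all regions instead of CRMs only.
#' @return Integer count.
#' @export
crm_count_for_subset <- function(sites, tf_subset,
                                 include_singletons = FALSE) {
  stopifnot(length(tf_subset) >= 1L)
  unknown <- setdiff(tf_subset, unique(sites$tf))
  if (length(unknown)) {
    stop("unknown TF(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cat <- build_crms(sites[sites$tf %in% tf_subset, , drop = FALSE])
  if (include_singletons) nrow(cat) else sum(cat$kind == "crm")
}

#' CRM saturation curve
#'
#' For each panel size, draws `replicates` uniform random TF subsets without
#' replacement (each from its own seeded substream, so adding sizes or
#' replicates never reshuffles existing ones), rebuilds the catalogue and
#' counts CRMs.  Medians across replicates are smoothed with lowess
#' (tricube-weighted local linear regression, 2 robustness iterations).
#'
#' @param sites A sites data.frame with a `tf` column.
#' @param sizes Strictly increasing panel sizes, each in
#'   `[2, number of TFs]`.
#' @param replicates Replicates per size.
#' @param seed Master seed.
#' @param lowess_fraction Lowess smoother span.
#' @param include_singletons Count all regions instead of CRMs only.
#' @return List of class `saturation_curve`: `points` (data.frame `n_tfs`,
#'   `q1`, `median`, `q3`, `smoothed_median`), `replicate_counts` (long
#'   data.frame `n_tfs`, `replicate`, `count`), `replicates`, `seed`,
#'   `lowess_fraction`.
#' @export
saturation_curve <- function(sites, sizes, replicates = 100L, seed = 1L,
                             lowess_fraction = 0.3,
                             include_singletons = FALSE) {
  tfs <- sort(unique(sites$tf))
  stopifnot(length(sizes) >= 1L, all(diff(sizes) > 0), replicates >= 1L)
  if (any(sizes < 2L) || any(sizes > length(tfs))) {
    stop("sizes must lie in [2, ", length(tfs), "]", call. = FALSE)
  }
  long <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    size <- sizes[i]
    counts <- vapply(seq_len(replicates), function(rep) {
      subset <- .with_seed(
        .substream_seed(seed, sprintf("saturation:%d:%d", size, rep)),
        sample(tfs, size))
      crm_count_for_subset(sites, subset, include_singletons)
    }, 0L)
    long[[i]] <- data.frame(n_tfs = size, replicate = seq_len(replicates),
                            count = counts)
  }
  long <- do.call(rbind, long)
  agg <- lapply(split(long$count, long$n_tfs), function(x) {
    stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  })
  points <- data.frame(
    n_tfs = sizes,
    q1 = vapply(as.character(sizes), function(s) agg[[s]][1], 0),
    median = vapply(as.character(sizes), function(s) agg[[s]][2], 0),
    q3 = vapply(as.character(sizes), function(s) agg[[s]][3], 0))
  points$smoothed_median <- if (length(sizes) >= 3L) {
    stats::lowess(points$n_tfs, points$median, f = lowess_fraction,
                  iter = 2)$y
  } else points$median
  structure(list(points = points, replicate_counts = long,
                 replicates = replicates, seed = seed,
                 lowess_fraction = lowess_fraction),
            class = "saturation_curve")
}
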