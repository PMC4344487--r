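# Dataset quality control: strand cross-correlation profile, NSC/RSC, FRiP,
# the 0-5 quality score and the retention gate.

#' Strand cross-correlation profile
#'
#' For each strand shift `d` in `0:max_shift`, computes the Pearson
#' correlation between the per-base plus-strand 5'-read count vector and the
#' minus-strand count vector shifted left by `d` (restricted to the
#' overlapping part of the chromosome), per chromosome, then combines
#' chromosomes by length-weighted averaging.  The fragment-length peak is
#' located as the argmax of the profile outside the phantom-peak exclusion
#' zone `read_length +/- exclusion_halfwidth` (the artefactual maximum at
#' shift = read length); the background level is the minimum of the profile.
#'
#' @param reads A [read_positions()] object; both strands must be non-empty
#'   on at least one chromosome.
#' @param max_shift Maximum shift tested (bp); must be at least
#'   `read_length + 50`.
#' @param chrom_lengths Optional named vector of chromosome lengths; when
#'   omitted, each chromosome's length is inferred as `max(position) + 1`.
#' @param exclusion_halfwidth Half-width of the phantom-peak exclusion zone
#'   around the read length (bp).
#' @return An object of class `cc_profile`: list with `shifts`, `values`,
#'   `read_length`, `fragment_peak_shift`, `cc_fragment`, `cc_read_length`,
#'   `cc_min`.
#' @export
cross_correlation_profile <- function(reads, max_shift = 500L,
                                      chrom_lengths = NULL,
                                      exclusion_halfwidth = 10L) {
  stopifnot(inherits(reads, "read_positions"))
  rl <- reads$read_length
  if (max_shift < rl + 50L) {
    stop("max_shift must be >= read_length + 50", call. = FALSE)
  }
  chroms <- intersect(names(reads$plus), names(reads$minus))
  if (length(chroms) == 0L) {
    stop("insufficient reads: need both strands on >= 1 chromosome",
         call. = FALSE)
  }
  shifts <- 0:max_shift
  acc <- numeric(length(shifts))
  wtot <- 0
  for (chrom in chroms) {
    px <- reads$plus[[chrom]]
    py <- reads$minus[[chrom]]
    L <- if (!is.null(chrom_lengths)) as.numeric(chrom_lengths[[chrom]]) else {
      max(px[length(px)], py[length(py)]) + 1
    }
    if (L <= max_shift + 1) {
      stop("chromosome '", chrom, "' shorter than max_shift", call. = FALSE)
    }
    acc <- acc + L * .cc_one_chrom(px, py, L, max_shift)
    wtot <- wtot + L
  }
  values <- acc / wtot
  zone <- abs(shifts - rl) <= exclusion_halfwidth
  cand <- which(!zone)
  peak <- cand[which.max(values[cand])]
  structure(list(shifts = shifts, values = values, read_length = rl,
                 fragment_peak_shift = shifts[peak],
                 cc_fragment = values[peak],
                 cc_read_length = values[shifts == rl],
                 cc_min = min(values)),
            class = "cc_profile")
}

# Per-chromosome sparse cross-correlation: for each shift d, Pearson r of
# plus counts over [0, L-1-d] against minus counts over [d, L-1].
.cc_one_chrom <- function(px, py, L, max_shift) {
  rx <- rle(px); ux <- rx$values; cx <- as.numeric(rx$lengths)
  ry <- rle(py); uy <- ry$values; cy <- as.numeric(ry$lengths)
  d_vec <- 0:max_shift

  # cross term: counts of position pairs at each difference uy - ux
  lo <- findInterval(ux - 0.5, uy) + 1L
  hi <- findInterval(ux + max_shift + 0.5, uy)
  n_i <- hi - lo + 1L
  keep <- n_i > 0L
  Sxy <- numeric(max_shift + 1L)
  if (any(keep)) {
    i_rep <- rep(which(keep), n_i[keep])
    j_idx <- sequence(n_i[keep], from = lo[keep])
    t <- rowsum(cx[i_rep] * cy[j_idx], uy[j_idx] - ux[i_rep])
    Sxy[as.integer(rownames(t)) + 1L] <- t
  }

  cumx <- cumsum(cx); cumx2 <- cumsum(cx^2)
  cumy <- cumsum(cy); cumy2 <- cumsum(cy^2)
  at <- function(cs, i) ifelse(i >= 1L, cs[pmax(i, 1L)], 0)
  ix <- findInterval(L - 1 - d_vec, ux)
  Sx <- at(cumx, ix); Sxx <- at(cumx2, ix)
  iy <- findInterval(d_vec - 0.5, uy)
  Sy <- cumy[length(cumy)] - at(cumy, iy)
  Syy <- cumy2[length(cumy2)] - at(cumy2, iy)

  n <- L - d_vec
  num <- n * Sxy - Sx * Sy
  den2 <- (n * Sxx - Sx^2) * (n * Syy - Sy^2)
  r <- ifelse(den2 > 0, num / sqrt(pmax(den2, 0)), 0)
  r
}

#' NSC and RSC from a cross-correlation profile
#'
#' The normalized strand coefficient is the ratio of the fragment-length
#' cross-correlation to the background (minimum) cross-correlation; the
#' relative strand coefficient compares the background-subtracted
#' fragment-length and read-length ("phantom peak") cross-correlations:
#' `nsc = cc_fragment / cc_min`,
#' `rsc = (cc_fragment - cc_min) / (cc_read_length - cc_min)`.
#'
#' @param profile A `cc_profile` from [cross_correlation_profile()].
#' @return List with elements `nsc` and `rsc`.
#' @export
cc_metrics <- function(profile) {
  stopifnot(inherits(profile, "cc_profile"))
  if (profile$cc_read_length == profile$cc_min) {
    stop("rsc undefined: cc_read_length equals cc_min", call. = FALSE)
  }
  list(nsc = profile$cc_fragment / profile$cc_min,
       rsc = (profile$cc_fragment - profile$cc_min) /
         (profile$cc_read_length - profile$cc_min))
}

#' Fraction of reads in peaks (FRiP)
#'
#' Fraction of all 5' read positions (both strands) falling inside the union
#' of the peak intervals.
#'
#' @param reads A [read_positions()] object with at least one read.
#' @param peaks A peaks data.frame (may be empty, giving 0).
#' @return A fraction in `[0, 1]`.
#' @export
frip <- function(reads, peaks) {
  stopifnot(inherits(reads, "read_positions"))
  total <- sum(lengths(reads$plus)) + sum(lengths(reads$minus))
  if (total == 0L) stop("undefined FRiP: zero reads", call. = FALSE)
  if (nrow(peaks) == 0L) return(0)
  .check_intervals(peaks, "frip")
  merged <- lapply(split(peaks[c("start", "end")], peaks$chrom), function(p) {
    ir <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  inside <- 0L
  for (strand in list(reads$plus, reads$minus)) {
    for (chrom in names(strand)) {
      m <- merged[[chrom]]
      if (is.null(m)) next
      pos <- strand[[chrom]]
      idx <- findInterval(pos, m$start)
      ok <- idx >= 1L
      ok[ok] <- pos[ok] < m$end[idx[ok]]
      inside <- inside + sum(ok)
    }
  }
  inside / total
}

#' Dataset quality score (0-5)
#'
#' The basal score (0-4) counts the NSC and RSC thresholds attained (two
#' thresholds each: NSC 1.05 and 1.10; RSC 0.8 and 1.0, attained means
#' `>=`), incremented by one when FRiP is at least 1%.
#'
#' @param nsc,rsc,frip Quality metrics; `rsc = NA` (undefined) contributes 0.
#' @param nsc_thresholds,rsc_thresholds,frip_threshold Threshold settings.
#' @return Integer score in 0-5.
#' @export
quality_score <- function(nsc, rsc, frip,
                          nsc_thresholds = c(1.05, 1.10),
                          rsc_thresholds = c(0.8, 1.0),
                          frip_threshold = 0.01) {
  stopifnot(.is_fraction(frip))
  s <- sum(nsc >= nsc_thresholds)
  if (!is.na(rsc)) s <- s + sum(rsc >= rsc_thresholds)
  as.integer(s + (frip >= frip_threshold))
}

#' Dataset retention gate
#'
#' A dataset is retained iff its quality score is at least 2 and it has at
#' least 100 peaks; datasets with score <= 1 or fewer than 100 peaks are
#' discarded.
#'
#' @param score Quality score (0-5).
#' @param n_peaks Number of called peaks.
#' @param min_score,min_peaks Gate settings.
#' @return Logical.
#' @export
retention_decision <- function(score, n_peaks, min_score = 2L,
                               min_peaks = 100L) {
  stopifnot(score >= 0, score <= 5, n_peaks >= 0)
  score >= min_score && n_peaks >= min_peaks
}

#' Full QC report for one dataset
#'
#' Computes the cross-correlation profile, NSC/RSC, FRiP, quality score and
#' retention flag.  An undefined RSC (degenerate profile) is reported as
#' `NA` and contributes 0 to the score.
#'
#' @param reads A [read_positions()] object.
#' @param peaks The dataset's peaks data.frame.
#' @param max_shift,chrom_lengths Passed to [cross_correlation_profile()].
#' @return One-row data.frame: `dataset`, `nsc`, `rsc`, `frip`, `n_peaks`,
#'   `fragment_peak_shift`, `score`, `retained`.
#' @export
qc_report <- function(reads, peaks, max_shift = 500L, chrom_lengths = NULL) {
  profile <- cross_correlation_profile(reads, max_shift, chrom_lengths)
  metrics <- tryCatch(cc_metrics(profile),
                      error = function(e) list(nsc = profile$cc_fragment /
                                                 profile$cc_min, rsc = NA_real_))
  fr <- frip(reads, peaks)
  score <- quality_score(metrics$nsc, metrics$rsc, fr)
  dataset <- if (nrow(peaks)) unique(peaks$dataset)[1] else NA_character_
  data.frame(dataset = dataset, nsc = metrics$nsc, rsc = metrics$rsc,
             frip = fr, n_peaks = nrow(peaks),
             fragment_peak_shift = profile$fragment_peak_shift,
             score = score,
             retained = retention_decision(score, nrow(peaks)),
             stringsAsFactors = FALSE)
}
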