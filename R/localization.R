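# Genomic-category assignment, TSS-proximity profiling, recovery of external
# element sets, and summit-centred conservation aggregation.

# Per-chromosome sorted non-overlapping interval list membership test.
.point_in <- function(by_chrom, chrom, pos) {
  out <- logical(length(pos))
  for (cn in unique(chrom)) {
    iv <- by_chrom[[cn]]
    if (is.null(iv) || nrow(iv) == 0L) next
    sel <- chrom == cn
    idx <- findInterval(pos[sel], iv$start)
    ok <- idx >= 1L
    ok[ok] <- pos[sel][ok] < iv$end[idx[ok]]
    out[sel] <- ok
  }
  out
}

.merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(list())
  df <- df[df$start < df$end, , drop = FALSE]
  lapply(split(df[c("start", "end")], df$chrom), function(p) {
    ir <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
    data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
}

# Build the six strand-aware category interval sets from gene models.
.category_features <- function(annotation, promoter_upstream = 3000L) {
  n <- nrow(annotation)
  promoter <- utr5 <- utr3 <- exon <- intron <-
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  add <- function(acc, chrom, s, e) {
    keep <- s < e
    if (!any(keep)) return(acc)
    rbind(acc, data.frame(chrom = chrom, start = pmax(0L, s[keep]),
                          end = e[keep], stringsAsFactors = FALSE))
  }
  clip <- function(es, ee, a, b) {
    s <- pmax(es, a); e <- pmin(ee, b)
    list(s = s[s < e], e = e[s < e])
  }
  for (i in seq_len(n)) {
    chrom <- annotation$chrom[i]
    plus <- annotation$strand[i] == "+"
    ts <- annotation$tx_start[i]; te <- annotation$tx_end[i]
    cs <- annotation$cds_start[i]; ce <- annotation$cds_end[i]
    es <- annotation$exon_starts[[i]]; ee <- annotation$exon_ends[[i]]
    promoter <- if (plus) add(promoter, chrom, ts - promoter_upstream, ts)
    else add(promoter, chrom, te, te + promoter_upstream)
    coding <- cs < ce
    if (coding) {
      u5 <- if (plus) clip(es, ee, ts, cs) else clip(es, ee, ce, te)
      u3 <- if (plus) clip(es, ee, ce, te) else clip(es, ee, ts, cs)
      cd <- clip(es, ee, cs, ce)
      utr5 <- add(utr5, chrom, u5$s, u5$e)
      utr3 <- add(utr3, chrom, u3$s, u3$e)
      exon <- add(exon, chrom, cd$s, cd$e)
    } else {
      exon <- add(exon, chrom, es, ee)  # non-coding: exons, no UTRs
    }
    # introns: transcript minus exons
    if (length(es) > 1L) {
      intron <- add(intron, chrom, ee[-length(ee)], es[-1])
    }
  }
  lapply(list(promoter = promoter, utr5 = utr5, utr3 = utr3,
              exon = exon, intron = intron), .merge_intervals)
}

#' Assign genomic categories to regions
#'
#' Each region is classified by its midpoint base
#' (`start + (end - start) %/% 2`) into exactly one of `promoter`, `utr5`,
#' `utr3`, `exon` (CDS), `intron` or `intergenic`, tested in that precedence
#' order.  The promoter is the `promoter_upstream` bp window immediately
#' upstream of the TSS, strand-aware.
#'
#' @param regions An interval data.frame.
#' @param annotation An annotation data.frame.
#' @param promoter_upstream Promoter window size upstream of the TSS (bp).
#' @return Character vector of categories, one per region.
#' @export
assign_category <- function(regions, annotation, promoter_upstream = 3000L) {
  .check_intervals(regions, "assign_category")
  feats <- .category_features(annotation, promoter_upstream)
  mid <- regions$start + (regions$end - regions$start) %/% 2L
  out <- rep("intergenic", nrow(regions))
  todo <- rep(TRUE, nrow(regions))
  for (cat in c("promoter", "utr5", "utr3", "exon", "intron")) {
    if (!any(todo)) break
    hit <- todo & .point_in(feats[[cat]], regions$chrom, mid)
    out[hit] <- cat
    todo <- todo & !hit
  }
  out
}

#' Category proportion table
#'
#' @param regions An interval data.frame.
#' @param annotation An annotation data.frame.
#' @param promoter_upstream Promoter window (bp).
#' @return data.frame `category`, `count`, `percent` (sums to 100).
#' @export
category_table <- function(regions, annotation, promoter_upstream = 3000L) {
  cats <- c("promoter", "utr5", "utr3", "exon", "intron", "intergenic")
  call <- factor(assign_category(regions, annotation, promoter_upstream),
                 levels = cats)
  count <- as.vector(table(call))
  data.frame(category = cats, count = count,
             percent = if (sum(count)) 100 * count / sum(count) else
               rep(0, length(cats)),
             stringsAsFactors = FALSE)
}

# Signed strand-oriented distance from positions to the nearest TSS
# (upstream of the gene = negative).  NA when the chromosome has no TSS.
.signed_tss_distance <- function(chrom, pos, tss) {
  out <- rep(NA_real_, length(pos))
  for (cn in unique(chrom)) {
    t <- tss[tss$chrom == cn, , drop = FALSE]
    sel <- which(chrom == cn)
    if (nrow(t) == 0L) next
    o <- order(t$pos)
    tp <- t$pos[o]; tstr <- t$strand[o]
    idx <- findInterval(pos[sel], tp)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(tp))
    dlo <- abs(pos[sel] - tp[lo])
    dhi <- abs(pos[sel] - tp[hi])
    pick <- ifelse(idx < 1L, hi, ifelse(idx >= length(tp), lo,
                                        ifelse(dlo <= dhi, lo, hi)))
    d <- pos[sel] - tp[pick]
    out[sel] <- ifelse(tstr[pick] == "+", d, -d)
  }
  out
}

#' CRM density around TSSs by binding complexity
#'
#' Bins the strand-oriented distance from each region midpoint to its
#' nearest TSS (upstream negative) into `bin_width` bp bins spanning
#' `+/- window`, separately per binding-complexity bin, and normalises each
#' complexity bin's counts to a density summing to 1.
#'
#' @param regions A catalogue data.frame (needs `n_tfs` or `tf_set`).
#' @param annotation An annotation data.frame with at least one gene.
#' @param window Half-window around the TSS (bp).
#' @param bin_width Position bin width (bp); must divide `2 * window`.
#' @param bin_spec Complexity bin lower edges (see
#'   [complexity_distribution()]).
#' @return List of class `tss_profile`: `density` (complexity bin x position
#'   bin matrix, rows summing to 1), `counts`, `bin_mid` (bin centres),
#'   `n_regions` per complexity bin (regions within the window).
#' @export
tss_profile <- function(regions, annotation, window = 2500L, bin_width = 50L,
                        bin_spec = c(1:15, 50L)) {
  stopifnot(window > 0, (2L * window) %% bin_width == 0L)
  if (nrow(annotation) == 0L) stop("no TSS in annotation", call. = FALSE)
  tss <- annotation_tss(annotation)
  mid <- regions$start + (regions$end - regions$start) %/% 2L
  d <- .signed_tss_distance(regions$chrom, mid, tss)
  n_tfs <- if ("n_tfs" %in% names(regions)) regions$n_tfs else {
    lengths(regions$tf_set)
  }
  cbin <- findInterval(n_tfs, bin_spec)
  labels <- complexity_distribution(
    data.frame(n_tfs = bin_spec), bin_spec)$bin
  nbins <- (2L * window) %/% bin_width
  keep <- !is.na(d) & d >= -window & d < window
  pbin <- (d[keep] + window) %/% bin_width + 1L
  counts <- matrix(0L, nrow = length(bin_spec), ncol = nbins,
                   dimnames = list(labels, NULL))
  for (j in seq_along(pbin)) {
    counts[cbin[keep][j], pbin[j]] <- counts[cbin[keep][j], pbin[j]] + 1L
  }
  totals <- rowSums(counts)
  density <- counts / ifelse(totals > 0, totals, 1)
  structure(list(density = density, counts = counts,
                 bin_mid = seq(-window + bin_width / 2, window, bin_width),
                 n_regions = totals),
            class = "tss_profile")
}

#' Recovery of an external element set by the catalogue
#'
#' Percentage of elements overlapped by at least 1 bp by at least one
#' catalogue region.
#'
#' @param catalogue A catalogue data.frame.
#' @param elements A non-empty interval data.frame.
#' @param crm_only Restrict the catalogue to CRMs.
#' @return Percentage in `[0, 100]`.
#' @export
resource_recovery <- function(catalogue, elements, crm_only = FALSE) {
  if (nrow(elements) == 0L) stop("empty element list", call. = FALSE)
  .check_intervals(elements, "resource_recovery")
  if (crm_only) catalogue <- catalogue[catalogue$kind == "crm", , drop = FALSE]
  if (nrow(catalogue) == 0L) return(0)
  # disjoint chromosome sets are legitimate (zero overlap), not a warning
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(.as_granges(elements),
                                 .as_granges(catalogue)))
  100 * mean(hits > 0)
}

#' Summit-centred conservation profile
#'
#' For each TF, the mean track value at every offset in
#' `-half_window .. +half_window` from the site summits, over the sites
#' where the track has a value at that base; absent bases are excluded from
#' numerator and denominator.
#'
#' @param sites A sites data.frame with `tf`, `chrom` and `summit` columns.
#' @param track A [score_track()].
#' @param half_window Half-window around the summit (bp).
#' @return List of class `conservation_profile`, one element per TF with
#'   `offsets`, `mean` (NA where no site is covered) and `coverage` counts.
#' @export
conservation_profile <- function(sites, track, half_window = 1000L) {
  stopifnot(inherits(track, "score_track"), nrow(sites) >= 1L)
  offsets <- seq.int(-half_window, half_window)
  out <- lapply(split(sites, sites$tf), function(s) {
    sums <- numeric(length(offsets))
    cov <- integer(length(offsets))
    for (cn in unique(s$chrom)) {
      summits <- s$summit[s$chrom == cn]
      pos <- rep(summits, each = length(offsets)) + offsets
      v <- matrix(track_values(track, cn, pos), nrow = length(offsets))
      sums <- sums + rowSums(v, na.rm = TRUE)
      cov <- cov + rowSums(!is.na(v))
    }
    if (all(cov == 0L)) {
      warning("conservation track absent over every window for TF ",
              s$tf[1], call. = FALSE)
    }
    list(offsets = offsets,
         mean = ifelse(cov > 0L, sums / pmax(cov, 1L), NA_real_),
         coverage = cov)
  })
  structure(out, class = "conservation_profile")
}
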