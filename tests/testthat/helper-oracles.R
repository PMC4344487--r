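# Independent reference implementations used as oracles.  These deliberately
# use brute-force algorithms, not the package's code paths.

# Connected components of the >=1 bp overlap relation by breadth-first
# search over the all-pairs adjacency.
oracle_overlap_components <- function(df) {
  n <- nrow(df)
  comp <- rep(NA_integer_, n)
  adj <- vector("list", n)
  for (cn in unique(df$chrom)) {
    idx <- which(df$chrom == cn)
    for (i in idx) {
      adj[[i]] <- idx[df$start[idx] < df$end[i] & df$start[i] < df$end[idx]]
    }
  }
  nc <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nc <- nc + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- nc
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

# Merged regions + membership from the oracle components, sorted like the
# package output.
oracle_merge <- function(df) {
  comp <- oracle_overlap_components(df)
  regions <- do.call(rbind, lapply(split(seq_len(nrow(df)), comp), function(i) {
    data.frame(chrom = df$chrom[i[1]], start = min(df$start[i]),
               end = max(df$end[i]), n = length(i),
               stringsAsFactors = FALSE)
  }))
  regions[order(regions$chrom, regions$start), , drop = FALSE]
}

# Dense-vector strand cross-correlation, length-weighted across chromosomes.
oracle_cc_profile <- function(reads, chrom_lengths, max_shift) {
  chroms <- intersect(names(reads$plus), names(reads$minus))
  vapply(0:max_shift, function(d) {
    num <- 0
    den <- 0
    for (cn in chroms) {
      L <- chrom_lengths[[cn]]
      x <- tabulate(reads$plus[[cn]] + 1L, L)
      y <- tabulate(reads$minus[[cn]] + 1L, L)
      r <- suppressWarnings(stats::cor(x[1:(L - d)], y[(1 + d):L]))
      if (is.na(r)) r <- 0
      num <- num + L * r
      den <- den + L
    }
    num / den
  }, 0)
}

# Exhaustive placement-null p-value: enumerate every valid start position.
# Closest-base distance: 0 iff the intervals share a base, gap + 1 otherwise.
oracle_placement_pvalue <- function(query, refs, dom) {
  qlen <- query$end - query$start
  dmin_for <- function(chrom, starts) {
    d <- rep(Inf, length(starts))
    for (i in which(refs$chrom == chrom)) {
      di <- pmax(refs$start[i] - (starts + qlen) + 1,
                 starts - refs$end[i] + 1)
      d <- pmin(d, pmax(di, 0))
    }
    d
  }
  dobs <- dmin_for(query$chrom, query$start)
  tot <- 0
  fav <- 0
  for (k in seq_len(nrow(dom))) {
    if (dom$end[k] - dom$start[k] < qlen) next
    starts <- dom$start[k]:(dom$end[k] - qlen)
    tot <- tot + length(starts)
    fav <- fav + sum(dmin_for(dom$chrom[k], starts) <= dobs)
  }
  fav / tot
}

# Upper-tail hypergeometric by direct combinatorial summation.
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Per-base genomic category of a single position, looping over genes with
# explicit windows (promoter > utr5 > utr3 > exon > intron > intergenic).
oracle_category <- function(chrom, pos, ann, promoter_upstream = 3000) {
  in_any <- function(p, s, e) any(p >= s & p < e)
  hit <- function(cat_fun) {
    for (i in seq_len(nrow(ann))) {
      if (ann$chrom[i] != chrom) next
      if (cat_fun(i)) return(TRUE)
    }
    FALSE
  }
  exonic <- function(i, p, a, b) {
    es <- pmax(ann$exon_starts[[i]], a)
    ee <- pmin(ann$exon_ends[[i]], b)
    any(p >= es & p < ee)
  }
  plus <- function(i) ann$strand[i] == "+"
  if (hit(function(i) {
    if (plus(i)) in_any(pos, ann$tx_start[i] - promoter_upstream, ann$tx_start[i])
    else in_any(pos, ann$tx_end[i], ann$tx_end[i] + promoter_upstream)
  })) return("promoter")
  coding <- function(i) ann$cds_start[i] < ann$cds_end[i]
  if (hit(function(i) coding(i) && (
    if (plus(i)) exonic(i, pos, ann$tx_start[i], ann$cds_start[i])
    else exonic(i, pos, ann$cds_end[i], ann$tx_end[i])))) return("utr5")
  if (hit(function(i) coding(i) && (
    if (plus(i)) exonic(i, pos, ann$cds_end[i], ann$tx_end[i])
    else exonic(i, pos, ann$tx_start[i], ann$cds_start[i])))) return("utr3")
  if (hit(function(i) {
    if (coding(i)) exonic(i, pos, ann$cds_start[i], ann$cds_end[i])
    else exonic(i, pos, ann$tx_start[i], ann$tx_end[i])
  })) return("exon")
  if (hit(function(i) in_any(pos, ann$tx_start[i], ann$tx_end[i])))
    return("intron")
  "intergenic"
}
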