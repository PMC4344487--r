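# TF co-localization: placement-null interval overlap significance, the
# asymmetric percentage matrix, IQR-outlier specificity calls and the
# partitioned co-localization network.
#
# The placement null re-places the query interval uniformly at every start
# position that keeps it wholly inside one domain segment, and scores how
# unusual it is to land as close to the reference set as observed.  Distance
# between intervals is the closest-base distance: 0 iff the intervals share
# at least one base, 1 for book-ended intervals, gap + 1 in general.

# Merged, sorted per-chromosome interval lists.
.pn_intervals <- function(df) {
  .check_intervals(df)
  .merge_intervals(df)
}

# Total number of valid placements of a length-q interval in the domain.
.pn_total <- function(segs, q) {
  tot <- 0
  for (s in segs) tot <- tot + sum(pmax(0, (s$end - s$start) - q + 1))
  tot
}

# Closest-base distance from each query to the nearest reference interval
# on the same chromosome (Inf when the chromosome has no reference).
.pn_dobs <- function(refs, chrom, start, end) {
  out <- rep(Inf, length(start))
  for (cn in unique(chrom)) {
    r <- refs[[cn]]
    if (is.null(r) || nrow(r) == 0L) next
    sel <- which(chrom == cn)
    a <- r$start; b <- r$end
    j <- findInterval(start[sel], a)
    dist_to <- function(i, s, e) {
      ok <- i >= 1L & i <= length(a)
      ii <- pmax(pmin(i, length(a)), 1L)
      d <- pmax(0, pmax(a[ii] - e + 1, s - b[ii] + 1))
      d[!ok] <- Inf
      d
    }
    out[sel] <- pmin(dist_to(j, start[sel], end[sel]),
                     dist_to(j + 1L, start[sel], end[sel]))
  }
  out
}

# Number of placements of a length-q interval (wholly inside a segment)
# whose distance to the nearest reference is <= d.
.pn_favorable <- function(refs, segs, q, d) {
  if (!is.finite(d)) return(.pn_total(segs, q))
  fav <- 0
  for (cn in names(refs)) {
    r <- refs[[cn]]
    s <- segs[[cn]]
    if (is.null(s) || nrow(s) == 0L || nrow(r) == 0L) next
    # allowed start positions near each reference: [a - q + 1 - d, b - 1 + d]
    lo <- r$start - q + 1 - d
    hi <- r$end - 1 + d
    # union of the sorted allowed intervals
    keep_new <- c(TRUE, lo[-1] > cummax(hi)[-length(hi)] + 1)
    grp <- cumsum(keep_new)
    ulo <- lo[keep_new]
    uhi <- vapply(split(hi, grp), max, 0)
    # valid start positions per segment: [start, end - q], prefix coverage
    A <- s$start; B <- s$end - q
    ok <- B >= A
    A <- A[ok]; B <- B[ok]
    if (length(A) == 0L) next
    cumlen <- cumsum(B - A + 1)
    cov_upto <- function(x) {
      j <- findInterval(x, A)
      res <- numeric(length(x))
      pos <- j >= 1L
      jj <- pmax(j, 1L)
      res[pos] <- (if (length(cumlen) > 1L) c(0, cumlen[-length(cumlen)])
                   else 0)[jj][pos] +
        pmax(0, pmin(x[pos], B[jj][pos]) - A[jj][pos] + 1)
      res
    }
    fav <- fav + sum(cov_upto(uhi) - cov_upto(ulo - 1))
  }
  fav
}

# Batch placement-null p-values for many queries against one reference set.
.pn_pvalues <- function(qchrom, qstart, qend, refs, segs) {
  qlen <- qend - qstart
  d <- .pn_dobs(refs, qchrom, qstart, qend)
  p <- rep(NA_real_, length(qlen))
  totals <- new.env(parent = emptyenv())
  total_for <- function(q) {
    key <- as.character(q)
    if (is.null(totals[[key]])) totals[[key]] <- .pn_total(segs, q)
    totals[[key]]
  }
  key <- paste(qlen, d)
  for (k in unique(key)) {
    idx <- which(key == k)
    q <- qlen[idx[1]]
    tot <- total_for(q)
    if (tot == 0) next  # no valid placement for this length
    p[idx] <- min(1, .pn_favorable(refs, segs, q, d[idx[1]]) / tot)
  }
  p
}

#' Co-localization analysis domain
#'
#' The union of the given regions padded by `margin` bp on each side,
#' merged; placements of the overlap null are restricted to these segments.
#'
#' @param regions An interval data.frame.
#' @param margin Padding (bp).
#' @param chrom_lengths Optional named vector to clip the padded segments.
#' @return An interval data.frame `chrom`, `start`, `end`.
#' @export
colocalization_domain <- function(regions, margin = 10000L,
                                  chrom_lengths = NULL) {
  .check_intervals(regions, "colocalization_domain")
  df <- data.frame(chrom = regions$chrom,
                   start = pmax(0L, regions$start - as.integer(margin)),
                   end = regions$end + as.integer(margin),
                   stringsAsFactors = FALSE)
  if (!is.null(chrom_lengths)) {
    df$end <- pmin(df$end, as.integer(chrom_lengths[df$chrom]))
  }
  merged <- .merge_intervals(df)
  do.call(rbind, lapply(names(merged), function(cn) {
    data.frame(chrom = cn, start = merged[[cn]]$start,
               end = merged[[cn]]$end, stringsAsFactors = FALSE)
  }))
}

#' Placement-null overlap p-value for one query interval
#'
#' Let `d_obs` be the closest-base distance from the query to the nearest
#' reference interval (0 when overlapping by >= 1 bp).  The p-value is the
#' fraction of all placements of an interval of the query's length, wholly
#' inside one domain segment, whose distance to the reference set is at
#' most `d_obs`.  The observed placement always counts, so `p` is in
#' `(0, 1]`, and `p` increases with `d_obs`.
#'
#' @param query A 1-row interval data.frame (or list with `chrom`, `start`,
#'   `end`); must itself be a valid placement within the domain.
#' @param reference A non-empty interval data.frame.
#' @param domain An interval data.frame of domain segments (see
#'   [colocalization_domain()]).
#' @return p-value in `(0, 1]`.
#' @export
interval_overlap_pvalue <- function(query, reference, domain) {
  if (nrow(reference) == 0L) stop("empty reference set", call. = FALSE)
  query <- as.data.frame(query)
  stopifnot(nrow(query) == 1L)
  refs <- .pn_intervals(reference)
  segs <- .pn_intervals(domain)
  q <- query$end - query$start
  s <- segs[[query$chrom]]
  inside <- !is.null(s) && any(query$start >= s$start & query$end <= s$end)
  if (!inside) {
    stop("no-placement error: query is not contained in a domain segment",
         call. = FALSE)
  }
  p <- .pn_pvalues(query$chrom, query$start, query$end, refs, segs)
  if (is.na(p)) stop("no-placement error: query longer than every domain segment",
                     call. = FALSE)
  p
}

#' Percentage of query sites significantly overlapping a reference set
#'
#' Each query site receives a placement-null overlap p-value against the
#' reference sites; the result is the percentage with `p <= alpha`.
#' Queries that are not contained in any domain segment are skipped with a
#' warning (shrinking the denominator).
#'
#' @param query_sites,reference_sites Non-empty interval data.frames.
#' @param domain Domain segments; default: padded union of both site sets.
#' @param alpha Significance threshold.
#' @param margin Padding used when `domain` is NULL.
#' @return Percentage in `[0, 100]`.
#' @export
significant_overlap_fraction <- function(query_sites, reference_sites,
                                         domain = NULL, alpha = 0.05,
                                         margin = 10000L) {
  stopifnot(nrow(query_sites) > 0L, nrow(reference_sites) > 0L)
  if (is.null(domain)) {
    both <- rbind(query_sites[c("chrom", "start", "end")],
                  reference_sites[c("chrom", "start", "end")])
    domain <- colocalization_domain(both, margin)
  }
  refs <- .pn_intervals(reference_sites)
  segs <- .pn_intervals(domain)
  p <- .pn_pvalues(query_sites$chrom, query_sites$start, query_sites$end,
                   refs, segs)
  if (anyNA(p)) {
    warning(sum(is.na(p)), " query site(s) without a valid placement skipped",
            call. = FALSE)
    p <- p[!is.na(p)]
  }
  if (length(p) == 0L) stop("no placeable query sites", call. = FALSE)
  100 * mean(p <= alpha)
}

#' Pairwise significant-overlap percentage matrix
#'
#' Every TF is used both as query and as reference: entry `[q, r]` is the
#' percentage of TF `q`'s sites significantly overlapping TF `r`'s sites
#' under the placement null.  The matrix is asymmetric; the diagonal is NA.
#'
#' @param sites A sites data.frame with a `tf` column (>= 2 TFs).
#' @param domain Domain segments; default: padded union of all sites.
#' @param alpha Significance threshold per site.
#' @param margin Padding used when `domain` is NULL.
#' @return Numeric matrix with TF row/column names.
#' @export
pairwise_matrix <- function(sites, domain = NULL, alpha = 0.05,
                            margin = 10000L) {
  .check_intervals(sites, "pairwise_matrix")
  tfs <- sort(unique(sites$tf))
  if (length(tfs) < 2L) stop("need >= 2 TFs", call. = FALSE)
  if (is.null(domain)) domain <- colocalization_domain(sites, margin)
  segs <- .pn_intervals(domain)
  by_tf <- split(sites[c("chrom", "start", "end")], sites$tf)
  refs_by_tf <- lapply(by_tf, .pn_intervals)
  P <- matrix(NA_real_, length(tfs), length(tfs),
              dimnames = list(query = tfs, reference = tfs))
  for (qtf in tfs) {
    qs <- by_tf[[qtf]]
    for (rtf in tfs) {
      if (rtf == qtf) next
      p <- .pn_pvalues(qs$chrom, qs$start, qs$end, refs_by_tf[[rtf]], segs)
      p <- p[!is.na(p)]
      if (length(p) == 0L) {
        warning("TF ", qtf, ": no placeable sites", call. = FALSE)
        next
      }
      P[qtf, rtf] <- 100 * mean(p <= alpha)
    }
  }
  P
}

#' IQR-outlier specificity calls
#'
#' For each query TF's row of overlap percentages, partners exceeding
#' `Q3 + 1.5 * IQR` are moderately specific and partners exceeding
#' `Q3 + 3 * IQR` strongly specific (strict `>`, quartiles by linear
#' interpolation, type 7).  Strong calls subsume moderate.  Rows with fewer
#' than 4 finite entries yield no calls (with a warning).
#'
#' @param matrix Percentage matrix from [pairwise_matrix()].
#' @param moderate,strong IQR multipliers for the two fences.
#' @return data.frame `query`, `partner`, `level` (`"moderate"`/`"strong"`),
#'   `percentage`.
#' @export
specificity_outliers <- function(matrix, moderate = 1.5, strong = 3.0) {
  tfs <- rownames(matrix)
  calls <- list()
  for (qtf in tfs) {
    row <- matrix[qtf, setdiff(tfs, qtf)]
    row <- row[is.finite(row)]
    if (length(row) < 4L) {
      warning("TF ", qtf, ": fewer than 4 finite percentages, no calls",
              call. = FALSE)
      next
    }
    q3 <- stats::quantile(row, 0.75, names = FALSE, type = 7)
    iqr <- q3 - stats::quantile(row, 0.25, names = FALSE, type = 7)
    mod <- row > q3 + moderate * iqr
    str <- row > q3 + strong * iqr
    if (any(mod)) {
      calls[[qtf]] <- data.frame(
        query = qtf, partner = names(row)[mod],
        level = ifelse(str[mod], "strong", "moderate"),
        percentage = unname(row[mod]), stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0L) {
    return(data.frame(query = character(0), partner = character(0),
                      level = character(0), percentage = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Build and partition the co-localization network
#'
#' Nodes are the TFs appearing in at least one specificity call; directed
#' calls are collapsed into undirected edges (keeping the stronger level
#' when both directions call), weighted 2 for strong and 1 for moderate,
#' coloured by the larger of the two directed percentages.  Communities are
#' found by weighted Louvain modularity maximisation at the given
#' resolution, after a seeded random relabelling of the nodes (the
#' "randomize" behaviour of interactive tools, pinned for reproducibility).
#'
#' @param calls Specificity calls from [specificity_outliers()] (non-empty).
#' @param matrix Optional percentage matrix used for edge colour values.
#' @param resolution Louvain resolution parameter.
#' @param seed Seed for the node relabelling and community detection.
#' @return List of class `co_network`: `nodes` (tf, degree, community),
#'   `edges` (tf_a, tf_b, level, weight, colour_value), `modularity`,
#'   `resolution`, `seed`, and the `igraph` object `graph`.
#' @export
build_and_partition_network <- function(calls, matrix = NULL,
                                        resolution = 0.51, seed = 1L) {
  if (nrow(calls) == 0L) stop("empty call list", call. = FALSE)
  a <- pmin(calls$query, calls$partner)
  b <- pmax(calls$query, calls$partner)
  key <- paste(a, b, sep = "\r")
  lvl <- tapply(calls$level == "strong", key, any)
  pct <- tapply(calls$percentage, key, max)
  if (!is.null(matrix)) {
    pct <- vapply(strsplit(names(lvl), "\r"), function(p) {
      max(matrix[p[1], p[2]], matrix[p[2], p[1]], na.rm = TRUE)
    }, 0)
  }
  edges <- data.frame(
    tf_a = vapply(strsplit(names(lvl), "\r"), `[[`, "", 1L),
    tf_b = vapply(strsplit(names(lvl), "\r"), `[[`, "", 2L),
    level = ifelse(lvl, "strong", "moderate"),
    weight = ifelse(lvl, 2, 1),
    colour_value = unname(pct), stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$tf_a, edges$tf_b)))
  g <- igraph::graph_from_data_frame(
    edges[c("tf_a", "tf_b", "weight")], directed = FALSE,
    vertices = data.frame(name = nodes))
  memb <- .with_seed(seed, {
    perm <- sample(igraph::vcount(g))
    g2 <- igraph::permute(g, perm)
    comm <- igraph::cluster_louvain(g2, weights = igraph::E(g2)$weight,
                                    resolution = resolution)
    m <- igraph::membership(comm)
    m[nodes]  # by preserved vertex names
  })
  structure(list(
    nodes = data.frame(tf = nodes,
                       degree = unname(igraph::degree(g)[nodes]),
                       community = as.integer(unname(memb)),
                       stringsAsFactors = FALSE),
    edges = edges,
    modularity = igraph::modularity(g, as.integer(memb[nodes]),
                                    weights = igraph::E(g)$weight,
                                    resolution = resolution),
    resolution = resolution, seed = seed, graph = g),
    class = "co_network")
}
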