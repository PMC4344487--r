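test_that("the placement-null p-value matches hand enumeration", {
  dom <- intervals_df("c", 0, 1000)
  ref <- intervals_df("c", 500, 510)
  # overlapping query of length 8: 17 of 993 placements overlap the reference
  expect_equal(interval_overlap_pvalue(intervals_df("c", 500, 508), ref, dom),
               17 / 993)
  # reference covering the whole domain: every placement overlaps
  expect_equal(interval_overlap_pvalue(intervals_df("c", 100, 150),
                                       intervals_df("c", 0, 1000), dom), 1)
  # p grows with the distance to the reference
  p_at <- vapply(c(0, 50, 150, 300), function(gap) {
    interval_overlap_pvalue(intervals_df("c", 520 + gap, 540 + gap), ref, dom)
  }, 0)
  expect_true(all(diff(p_at) > 0))
  expect_error(interval_overlap_pvalue(intervals_df("c", 0, 8),
                                       intervals_df(character(0), integer(0),
                                                    integer(0)), dom),
               "empty reference")
  expect_error(interval_overlap_pvalue(intervals_df("c", 990, 1010), ref, dom),
               "no-placement")
})

test_that("the p-value equals exhaustive enumeration on random instances", {
  set.seed(19)
  for (trial in 1:20) {
    nseg <- sample(1:3, 1)
    b <- sort(sample(0:4000, 2 * nseg))
    dom <- intervals_df("c", b[seq(1, by = 2, length.out = nseg)],
                        b[seq(2, by = 2, length.out = nseg)])
    dom <- dom[dom$end - dom$start >= 80, , drop = FALSE]
    if (nrow(dom) == 0) next
    refs <- do.call(rbind, lapply(seq_len(sample(1:4, 1)), function(i) {
      k <- sample(nrow(dom), 1)
      s <- sample(dom$start[k]:(dom$end[k] - 10), 1)
      intervals_df("c", s, s + sample(5:50, 1))
    }))
    k <- sample(nrow(dom), 1)
    qlen <- sample(5:40, 1)
    s <- sample(dom$start[k]:(dom$end[k] - qlen), 1)
    q <- intervals_df("c", s, s + qlen)
    expect_equal(interval_overlap_pvalue(q, refs, dom),
                 oracle_placement_pvalue(q, refs, dom), tolerance = 1e-12)
  }
})

test_that("uniformly placed queries are calibrated at alpha", {
  fracs <- vapply(1:5, function(seed) {
    set.seed(seed)
    dom <- intervals_df("c", 0, 2e5)
    s <- sort(sample.int(2e5 - 100, 60))
    refs <- intervals_df("c", s, s + 50)
    qs <- sample.int(2e5 - 30, 300) - 1L
    queries <- intervals_df("c", qs, qs + 30)
    significant_overlap_fraction(queries, refs, dom, alpha = 0.05) / 100
  }, 0)
  expect_gt(mean(fracs), 0.02)
  expect_lt(mean(fracs), 0.08)
})

test_that("identical sparse sets overlap significantly; saturated ones do not", {
  set.seed(8)
  s <- sort(sample.int(5e5, 40)) * 1L
  sites <- intervals_df("c", s, s + 200)
  dom <- colocalization_domain(sites, margin = 10000)
  expect_gt(significant_overlap_fraction(sites, sites, dom), 90)

  # reference so dense that overlap is uninformative: p = 1 everywhere
  dense_dom <- intervals_df("c", 0, 10000)
  dense_ref <- intervals_df("c", 0, 10000)
  q <- intervals_df("c", c(100, 5000), c(200, 5100))
  expect_equal(significant_overlap_fraction(q, dense_ref, dense_dom), 0)
})

test_that("the pairwise matrix is asymmetric and matches per-pair recomputation", {
  set.seed(12)
  # TF A's sites are a small subset of TF B's (sparse) sites
  sB <- sort(sample(seq(0, 199000, 1000), 12)) * 1L
  B <- sites_df("c", sB, sB + 100, "B")
  A <- B[sample(12, 4), ]
  A$tf <- "A"
  sC <- sort(sample.int(195000, 8))
  C <- sites_df("c", sC, sC + 100, "C")
  sD <- sort(sample.int(195000, 9))
  D <- sites_df("c", sD, sD + 90, "D")
  sites <- rbind(A, B, C, D)
  P <- pairwise_matrix(sites, alpha = 0.05)
  expect_true(all(is.na(diag(P))))
  expect_gt(P["A", "B"], P["B", "A"])

  dom <- colocalization_domain(sites, 10000)
  by_tf <- split(sites, sites$tf)
  for (qtf in names(by_tf)) for (rtf in names(by_tf)) {
    if (qtf == rtf) next
    want <- 100 * mean(vapply(seq_len(nrow(by_tf[[qtf]])), function(i) {
      oracle_placement_pvalue(by_tf[[qtf]][i, ], by_tf[[rtf]], dom)
    }, 0) <= 0.05)
    expect_equal(P[qtf, rtf], want, tolerance = 1e-12)
  }
})

test_that("IQR fences call outliers per query row", {
  tfs <- paste0("T", 1:7)
  M <- matrix(5, 7, 7, dimnames = list(tfs, tfs))
  diag(M) <- NA
  M["T1", "T7"] <- 80
  calls <- specificity_outliers(M)
  one <- calls[calls$query == "T1", ]
  expect_equal(one$partner, "T7")
  expect_equal(one$level, "strong")  # Q3 = 5, IQR = 0, strict >

  allsame <- matrix(10, 6, 6, dimnames = list(tfs[1:6], tfs[1:6]))
  diag(allsame) <- NA
  expect_equal(nrow(specificity_outliers(allsame)), 0)

  # quartile arithmetic under the type-7 convention
  row <- c(10, 12, 14, 16, 40)
  M2 <- matrix(NA_real_, 6, 6, dimnames = list(tfs[1:6], tfs[1:6]))
  M2["T1", 2:6] <- row
  M2[2:6, ] <- 1  # give other rows enough finite entries
  diag(M2) <- NA
  calls2 <- specificity_outliers(M2)
  c1 <- calls2[calls2$query == "T1", ]
  expect_equal(c1$partner, "T6")
  expect_equal(c1$percentage, 40)
  expect_equal(c1$level, "strong")  # 40 > 16 + 3 * 6

  # shifting a whole row preserves the calls
  M3 <- M2
  M3["T1", 2:6] <- row + 7
  expect_equal(specificity_outliers(M3)[1, c("partner", "level")],
               c1[, c("partner", "level")])

  small <- matrix(c(NA, 1, 2, NA), 2, 2,
                  dimnames = list(tfs[1:2], tfs[1:2]))
  # one warning per too-short row
  expect_warning(expect_warning(specificity_outliers(small), "fewer than 4"),
                 "fewer than 4")
})

test_that("the co-localization network is built, weighted and partitioned", {
  calls <- data.frame(
    query = c("A", "B", "C", "D", "E", "F"),
    partner = c("B", "C", "A", "E", "F", "D"),
    level = "strong", percentage = 50, stringsAsFactors = FALSE)
  net <- build_and_partition_network(calls, seed = 7)
  expect_equal(sort(net$nodes$tf), LETTERS[1:6])
  expect_true(all(net$edges$weight == 2))
  expect_true(all(net$nodes$degree >= 1))
  # two disjoint triangles give two communities
  comm <- split(net$nodes$tf, net$nodes$community)
  expect_equal(sort(unname(vapply(comm, paste, "", collapse = ""))),
               c("ABC", "DEF"))
  # determinism for a fixed seed
  net2 <- build_and_partition_network(calls, seed = 7)
  expect_identical(net$nodes, net2$nodes)
  # partition at least as modular as the trivial one
  expect_gte(net$modularity,
             igraph::modularity(net$graph, rep(1, 6),
                                weights = igraph::E(net$graph)$weight,
                                resolution = net$resolution))
  expect_error(build_and_partition_network(calls[0, ]), "empty")
})

test_that("calls collapse directions keeping the stronger level", {
  calls <- data.frame(
    query = c("A", "B", "A", "C"),
    partner = c("B", "A", "C", "A"),
    level = c("moderate", "strong", "moderate", "moderate"),
    percentage = c(30, 45, 20, 25), stringsAsFactors = FALSE)
  net <- build_and_partition_network(calls, seed = 1)
  ab <- net$edges[net$edges$tf_a == "A" & net$edges$tf_b == "B", ]
  expect_equal(ab$level, "strong")
  expect_equal(ab$weight, 2)
  expect_equal(ab$colour_value, 45)
  expect_equal(nrow(net$edges), 2)
})

test_that("planted co-binding blocks are recovered by calls plus Louvain", {
  skip_if_not_installed("mclust")
  cfg <- sim_config(seed = 42, chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                    n_genes = 0, n_tfs = 30, n_modules = 300,
                    singleton_rate = 0.2)   # default blocks of 5
  truth <- plant_regulatory_sites(cfg, empty_annotation())
  sites <- sites_from_truth(truth)
  P <- pairwise_matrix(sites, alpha = 0.05)
  calls <- specificity_outliers(P)
  expect_gt(nrow(calls), 0)
  net <- build_and_partition_network(calls, P, resolution = 0.51, seed = 42)
  blocks <- rep(names(cfg$community_blocks),
                lengths(cfg$community_blocks))
  names(blocks) <- unlist(cfg$community_blocks)
  ari <- mclust::adjustedRandIndex(net$nodes$community,
                                   blocks[net$nodes$tf])
  expect_gte(ari, 0.8)
})
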