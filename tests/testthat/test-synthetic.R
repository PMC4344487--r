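test_that("the generator is fully deterministic given the config", {
  cfg <- sim_config(seed = 9, chrom_lengths = c(chr1 = 1e6), n_genes = 20,
                    n_tfs = 6, n_modules = 40)
  ann1 <- simulate_genome_annotation(cfg)
  ann2 <- simulate_genome_annotation(cfg)
  expect_identical(ann1, ann2)
  t1 <- plant_regulatory_sites(cfg, ann1)
  t2 <- plant_regulatory_sites(cfg, ann2)
  expect_identical(t1, t2)
  expect_identical(simulate_peak_datasets(cfg, t1),
                   simulate_peak_datasets(cfg, t2))
  expect_identical(simulate_reads(cfg, t1), simulate_reads(cfg, t2))
  # per-dataset substreams: dropping datasets does not change the others
  cfg2 <- sim_config(seed = 9, chrom_lengths = c(chr1 = 1e6), n_genes = 20,
                     n_tfs = 6, n_modules = 40, datasets_per_tf = 2)
  d3 <- simulate_peak_datasets(cfg, t1)
  d2 <- simulate_peak_datasets(cfg2, t1)
  expect_identical(d2[names(d2)], d3[names(d2)])
})

test_that("gene models respect strand and gene count settings", {
  cfg <- sim_config(seed = 2, chrom_lengths = c(chrA = 8e5), n_genes = 25)
  ann <- simulate_genome_annotation(cfg)
  expect_equal(nrow(ann), 25)
  expect_silent(validate_annotation(ann))
  tss <- annotation_tss(ann)
  minus <- ann$strand == "-"
  expect_equal(tss$pos[minus], ann$tx_end[minus] - 1L)
  expect_equal(tss$pos[!minus], ann$tx_start[!minus])
  # genes never overlap
  ov <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(ann$chrom,
                           IRanges::IRanges(ann$tx_start + 1L, ann$tx_end)))
  expect_equal(length(ov), nrow(ann))  # self-hits only

  empty <- simulate_genome_annotation(
    sim_config(seed = 2, chrom_lengths = c(chrA = 8e5), n_genes = 0))
  expect_equal(nrow(empty), 0)
  expect_error(simulate_genome_annotation(
    sim_config(seed = 2, chrom_lengths = c(chrA = 500), n_genes = 3)),
    "config error")
})

test_that("planted sites follow the block co-binding model", {
  blocks <- list(B1 = c("TF01", "TF02", "TF03"), B2 = c("TF04", "TF05"))
  cfg <- sim_config(seed = 4, chrom_lengths = c(chr1 = 4e6), n_genes = 30,
                    n_tfs = 5, community_blocks = blocks, n_modules = 200,
                    singleton_rate = 0, min_site_gap = 200)
  ann <- simulate_genome_annotation(cfg)
  truth <- plant_regulatory_sites(cfg, ann)
  expect_equal(nrow(truth), 200)
  expect_true(all(truth$n_tfs >= 2))
  expect_true(all(truth$kind == "crm"))
  # sites never overlap
  expect_equal(nrow(build_crms(cbind(truth[c("chrom", "start", "end")],
                                     tf = "x"))), nrow(truth))
  # block purity of the module TF sets
  purity <- mapply(function(set, bl) {
    mean(set %in% blocks[[bl]])
  }, truth$tf_set, truth$block_id)
  expect_gt(mean(purity), 0.9)

  none <- plant_regulatory_sites(
    sim_config(seed = 4, chrom_lengths = c(chr1 = 4e6), n_tfs = 5,
               community_blocks = blocks, n_modules = 0,
               singleton_rate = 0), ann)
  expect_equal(nrow(none), 0)
})

test_that("singleton rate controls the fraction of single-TF truth sites", {
  cfg <- sim_config(seed = 6, chrom_lengths = c(chr1 = 4e6), n_genes = 0,
                    n_tfs = 10, n_modules = 120, singleton_rate = 0.25)
  truth <- plant_regulatory_sites(cfg, empty_annotation())
  expect_equal(sum(truth$kind == "singleton"), 40)  # 120 * 0.25/0.75
  expect_equal(mean(truth$kind == "singleton"), 0.25)
})

test_that("noise-free datasets reproduce the truth exactly", {
  cfg <- noise_free_config()
  ann <- simulate_genome_annotation(cfg)
  truth <- plant_regulatory_sites(cfg, ann)
  ds <- simulate_peak_datasets(cfg, truth)
  tf <- "TF03"
  labs <- grep(paste0(".", tf, "."), names(ds), fixed = TRUE, value = TRUE)
  expect_length(labs, cfg$datasets_per_tf)
  has_tf <- vapply(truth$tf_set, function(s) tf %in% s, TRUE)
  for (lab in labs) {
    p <- ds[[lab]][order(ds[[lab]]$chrom, ds[[lab]]$start), ]
    tr <- truth[has_tf, ]
    tr <- tr[order(tr$chrom, tr$start), ]
    expect_equal(p$start, tr$start)
    expect_equal(p$end, tr$end)
    expect_equal(p$summit, tr$summit)
  }
})

test_that("sensitivity zero leaves only the noise peaks", {
  cfg <- sim_config(seed = 12, chrom_lengths = c(chr1 = 1e6), n_genes = 0,
                    n_tfs = 2, n_modules = 30, sensitivity = 0,
                    noise_peaks_per_dataset = 5)
  truth <- plant_regulatory_sites(cfg, empty_annotation())
  ds <- simulate_peak_datasets(cfg, truth)
  expect_true(all(vapply(ds, nrow, 1L) == 5L))
  expect_true(all(unlist(lapply(ds, function(d) d$origin)) == "noise"))
})

test_that("summit jitter has the configured spread across datasets", {
  cfg <- sim_config(seed = 8, chrom_lengths = c(chr1 = 4e6), n_genes = 0,
                    n_tfs = 2, community_blocks = list(B = c("TF01", "TF02")),
                    within_block_prob = 1, n_modules = 100,
                    singleton_rate = 0, datasets_per_tf = 14,
                    summit_jitter_sd = 10, peak_width_sd = 0,
                    sensitivity = 1, noise_peaks_per_dataset = 0)
  truth <- plant_regulatory_sites(cfg, empty_annotation())
  ds <- simulate_peak_datasets(cfg, truth)
  sites <- sites_from_datasets(ds)
  expect_true(all(sites$n_members == 14))
  sds <- vapply(sites$member_summits, stats::sd, 0)
  expect_gt(mean(sds), 7)
  expect_lt(mean(sds), 13)
})

test_that("read simulation follows the fragment model", {
  cfg <- sim_config(seed = 3, chrom_lengths = c(chr1 = 1e6), n_genes = 0,
                    n_tfs = 2, n_modules = 40, read_scatter_sd = 0,
                    background_read_fraction = 0, reads_per_site = 20,
                    fragment_length = 200)
  truth <- plant_regulatory_sites(cfg, empty_annotation())
  reads <- simulate_reads(cfg, truth)
  # with zero scatter every minus 5' sits fragment_length - 1 right of a
  # plus 5' from the same site
  plus_all <- sort(unique(reads$plus$chr1))
  minus_all <- sort(unique(reads$minus$chr1))
  expect_equal(plus_all + 199L, minus_all)

  # pure background is uniform (chi-square GOF)
  cfgb <- sim_config(seed = 31, chrom_lengths = c(chr1 = 1e6), n_genes = 0,
                     n_tfs = 2, n_modules = 50,
                     background_read_fraction = 1, reads_per_site = 200)
  truthb <- plant_regulatory_sites(cfgb, empty_annotation())
  rb <- simulate_reads(cfgb, truthb)
  pos <- c(rb$plus$chr1, rb$minus$chr1)
  expect_gte(length(pos), 10000)
  counts <- table(cut(pos, seq(0, 1e6, length.out = 21)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # no sites, no background: empty
  cfg0 <- sim_config(seed = 3, chrom_lengths = c(chr1 = 1e6), n_tfs = 2,
                     n_modules = 0, singleton_rate = 0,
                     background_read_fraction = 0)
  empty <- simulate_reads(cfg0, plant_regulatory_sites(cfg0,
                                                       empty_annotation()))
  expect_equal(sum(lengths(empty$plus)) + sum(lengths(empty$minus)), 0L)
})

test_that("query regions are spiked as configured", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(chr1 = 4e6), n_genes = 0,
                    n_tfs = 6, n_modules = 100)
  truth <- plant_regulatory_sites(cfg, empty_annotation())
  q <- simulate_query_regions(cfg, truth, "TF01", 200, 0.5)
  expect_equal(sum(q$provenance == "spiked"), 100)
  expect_equal(sum(q$provenance == "background"), 100)

  q1 <- simulate_query_regions(cfg, truth, c("TF01", "TF02"), 40, 1)
  has_e <- vapply(truth$tf_set, function(s) any(c("TF01", "TF02") %in% s), TRUE)
  ov <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(q1$chrom, IRanges::IRanges(q1$start + 1L, q1$end)),
    GenomicRanges::GRanges(truth$chrom[has_e],
                           IRanges::IRanges(truth$start[has_e] + 1L,
                                            truth$end[has_e])))
  expect_true(all(ov >= 1))

  truth_no <- truth
  truth_no$tf_set <- lapply(truth_no$tf_set, function(s) setdiff(s, "TF06"))
  keep <- lengths(truth_no$tf_set) > 0
  expect_error(simulate_query_regions(cfg, truth_no[keep, ], "TF06", 10, 1),
               "generation error")
})
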