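# Shared fixture builders (everything is generated in code at test time).

peaks_df <- function(chrom, start, end, summit, dataset = "S1.TFX.c",
                     score = NA_real_) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             summit = as.integer(summit), dataset = dataset, score = score,
             stringsAsFactors = FALSE)
}

intervals_df <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

sites_df <- function(chrom, start, end, tf) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             tf = tf, stringsAsFactors = FALSE)
}

random_peaks <- function(n, n_chrom = 2, span = 10000, max_width = 300,
                         dataset = "S1.TFX.c") {
  chrom <- paste0("chr", sample.int(n_chrom, n, replace = TRUE))
  start <- sample.int(span, n, replace = TRUE) - 1L
  width <- sample.int(max_width, n, replace = TRUE)
  summit <- start + vapply(width, function(w) sample.int(w, 1L) - 1L, 1L)
  peaks_df(chrom, start, start + width, summit, dataset)
}

# Small noise-free study configuration for identity checks.
noise_free_config <- function(seed = 11, ...) {
  sim_config(seed = seed, chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
             n_genes = 40, n_tfs = 10, n_modules = 80,
             summit_jitter_sd = 0, peak_width_sd = 0, sensitivity = 1,
             noise_peaks_per_dataset = 0, ...)
}

# Merge all simulated datasets into per-TF non-redundant sites.
sites_from_datasets <- function(datasets) {
  peaks <- do.call(rbind, datasets)
  tf <- vapply(strsplit(peaks$dataset, ".", fixed = TRUE), `[[`, "", 2L)
  out <- do.call(rbind, lapply(split(peaks, tf), merge_tf_peaks))
  rownames(out) <- NULL
  out
}

# One per-TF site per (truth site, member TF): the idealised catalogue input.
sites_from_truth <- function(truth) {
  n <- lengths(truth$tf_set)
  idx <- rep(seq_len(nrow(truth)), n)
  out <- sites_df(truth$chrom[idx], truth$start[idx], truth$end[idx],
                  unlist(truth$tf_set))
  out$summit <- truth$summit[idx]
  out
}
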