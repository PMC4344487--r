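# Synthetic study generator.  Plants multi-TF regulatory modules with block
# co-binding structure on a toy genome, then emits noisy per-dataset peaks,
# stranded reads and spiked query regions with known ground truth.
#
# Randomness is organised as one master seed feeding deterministic
# per-component substreams (genome / sites / one per dataset / reads /
# queries), so e.g. changing the number of datasets never perturbs gene or
# module placement.

#' Simulation configuration
#'
#' Bundles all knobs of the synthetic-study generator with validation.
#' Defaults describe a small but realistic study: a 10 Mb two-chromosome
#' genome, 30 TFs organised in 6 co-binding blocks of 5, 800 planted
#' multi-TF modules plus singletons (enough that a typical dataset clears
#' the 100-peak retention floor of the quality gate), 3 ChIP-seq datasets
#' per TF with summit jitter, width variation, missed sites and noise
#' peaks, and 200 bp fragments sequenced as 36 bp stranded reads.
#'
#' @param seed Master seed (integer, < 2^31).
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param n_genes Number of genes placed on the genome.
#' @param n_tfs Number of TFs in the panel (named `TF01`, `TF02`, ...).
#' @param community_blocks Named list partitioning the TF names into
#'   co-binding blocks; default: consecutive blocks of 5.
#' @param within_block_prob,between_block_prob Probability that a module
#'   drawn for a block includes a given TF of that block / of another block.
#' @param n_modules Number of planted multi-TF modules (CRM ground truth).
#' @param singleton_rate Fraction of all truth sites that are single-TF
#'   sites; singletons are added on top of `n_modules` modules so that they
#'   make up this fraction of the truth table.
#' @param promoter_bias Probability that a site is placed TSS-proximally
#'   (within Normal(0, 500 bp) of a random TSS) rather than uniformly.
#' @param mean_site_width Width of planted sites and mean simulated peak
#'   width (bp).
#' @param min_site_gap Minimum gap enforced between planted sites (bp).
#' @param datasets_per_tf ChIP-seq datasets simulated per TF.
#' @param summit_jitter_sd SD of the per-dataset summit jitter (bp).
#' @param peak_width_sd SD of the per-peak width noise (bp; width floor 50).
#' @param sensitivity Probability that a dataset recovers each true site of
#'   its TF.
#' @param noise_peaks_per_dataset False-positive peaks added per dataset.
#' @param fragment_length,read_length Sequencing fragment and read length
#'   (bp); `fragment_length > read_length` required.
#' @param read_scatter_sd SD of fragment-centre scatter around the summit.
#' @param reads_per_site Fragments generated per site.
#' @param background_read_fraction Fraction of all reads placed uniformly on
#'   the genome instead of at sites.
#' @param query_width Width of simulated query regions (bp).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                       n_genes = 120L,
                       n_tfs = 30L,
                       community_blocks = NULL,
                       within_block_prob = 0.8,
                       between_block_prob = 0.02,
                       n_modules = 800L,
                       singleton_rate = 0.25,
                       promoter_bias = 0.25,
                       mean_site_width = 300L,
                       min_site_gap = 1000L,
                       datasets_per_tf = 3L,
                       summit_jitter_sd = 10,
                       peak_width_sd = 50,
                       sensitivity = 0.8,
                       noise_peaks_per_dataset = 10L,
                       fragment_length = 200L,
                       read_length = 36L,
                       read_scatter_sd = 30,
                       reads_per_site = 30L,
                       background_read_fraction = 0.1,
                       query_width = 2000L) {
  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  if (is.null(community_blocks)) {
    community_blocks <- split(tfs, paste0("B", (seq_len(n_tfs) - 1L) %/% 5L + 1L))
  }
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              tfs = tfs, community_blocks = community_blocks,
              within_block_prob = within_block_prob,
              between_block_prob = between_block_prob,
              n_modules = as.integer(n_modules),
              singleton_rate = singleton_rate,
              promoter_bias = promoter_bias,
              mean_site_width = as.integer(mean_site_width),
              min_site_gap = as.integer(min_site_gap),
              datasets_per_tf = as.integer(datasets_per_tf),
              summit_jitter_sd = summit_jitter_sd,
              peak_width_sd = peak_width_sd,
              sensitivity = sensitivity,
              noise_peaks_per_dataset = as.integer(noise_peaks_per_dataset),
              fragment_length = as.integer(fragment_length),
              read_length = as.integer(read_length),
              read_scatter_sd = read_scatter_sd,
              reads_per_site = as.integer(reads_per_site),
              background_read_fraction = background_read_fraction,
              query_width = as.integer(query_width))
  stopifnot(length(cfg$chrom_lengths) >= 1L,
            !is.null(names(cfg$chrom_lengths)),
            all(cfg$chrom_lengths >= 1))
  stopifnot(setequal(unlist(cfg$community_blocks), tfs))
  for (f in c("singleton_rate", "promoter_bias", "sensitivity",
              "background_read_fraction", "within_block_prob",
              "between_block_prob")) {
    if (!.is_fraction(cfg[[f]])) stop("config: ", f, " must be in [0,1]",
                                      call. = FALSE)
  }
  if (cfg$singleton_rate >= 1) stop("config: singleton_rate must be < 1",
                                    call. = FALSE)
  if (cfg$fragment_length <= cfg$read_length) {
    stop("config: fragment_length must exceed read_length", call. = FALSE)
  }
  for (f in c("n_genes", "n_tfs", "n_modules", "datasets_per_tf",
              "noise_peaks_per_dataset", "reads_per_site")) {
    if (!.is_count(cfg[[f]])) stop("config: ", f, " must be a count",
                                   call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

.sample_chrom <- function(cfg, n) {
  sample(names(cfg$chrom_lengths), n, replace = TRUE,
         prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
}

#' Simulate a gene annotation
#'
#' Places `n_genes` non-overlapping gene models (1-6 exons, CDS with 5' and
#' 3' UTRs) on the configured chromosomes.  Deterministic given the config
#' seed.  The TSS is `tx_start` on the plus strand and `tx_end - 1` on the
#' minus strand.
#'
#' @param config A [sim_config()].
#' @return An annotation data.frame (see [read_annotation()]).
#' @export
simulate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.substream_seed(config$seed, "genome"), {
    n <- config$n_genes
    a <- empty_annotation()
    if (n == 0L) return(a)
    min_len <- 3000L
    if (max(config$chrom_lengths) < min_len + 2L) {
      stop("config error: no chromosome can host a gene", call. = FALSE)
    }
    taken <- lapply(config$chrom_lengths, function(...) {
      data.frame(start = integer(0), end = integer(0))
    })
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:1000) {
        chrom <- .sample_chrom(config, 1L)
        L <- config$chrom_lengths[[chrom]]
        glen <- sample(min_len:min(12000L, as.integer(L) - 1L), 1L)
        if (glen >= L) next
        s <- sample.int(as.integer(L) - glen, 1L) - 1L
        e <- s + glen
        t <- taken[[chrom]]
        if (nrow(t) && any(s < t$end & e > t$start)) next
        taken[[chrom]] <- rbind(t, data.frame(start = s, end = e))
        n_exon <- sample(1:6, 1L)
        if (n_exon == 1L) {
          es <- s; ee <- e
        } else {
          b <- sort(sample.int(glen - 1L, 2L * n_exon - 2L))
          bounds <- c(0L, b, glen) + s
          es <- bounds[seq(1L, by = 2L, length.out = n_exon)]
          ee <- bounds[seq(2L, by = 2L, length.out = n_exon)]
        }
        # CDS interior to the first/last exon gives both UTRs
        cs <- es[1] + sample.int(max(1L, ee[1] - es[1] - 1L), 1L)
        ce <- ee[n_exon] - sample.int(max(1L, ee[n_exon] - es[n_exon] - 1L), 1L)
        if (cs > ce) { cs <- es[1]; ce <- ee[n_exon] }
        rows[[i]] <- list(gene_id = sprintf("G%04d", i), chrom = chrom,
                          strand = sample(c("+", "-"), 1L),
                          tx_start = s, tx_end = e, cds_start = cs,
                          cds_end = ce, exon_starts = es, exon_ends = ee)
        placed <- TRUE
        break
      }
      if (!placed) stop("config error: genome too small to place ", n,
                        " non-overlapping genes", call. = FALSE)
    }
    a <- data.frame(
      gene_id = vapply(rows, `[[`, "", "gene_id"),
      chrom = vapply(rows, `[[`, "", "chrom"),
      strand = vapply(rows, `[[`, "", "strand"),
      tx_start = vapply(rows, function(r) r$tx_start, 1L),
      tx_end = vapply(rows, function(r) r$tx_end, 1L),
      cds_start = vapply(rows, function(r) r$cds_start, 1L),
      cds_end = vapply(rows, function(r) r$cds_end, 1L),
      stringsAsFactors = FALSE)
    a$exon_starts <- lapply(rows, `[[`, "exon_starts")
    a$exon_ends <- lapply(rows, `[[`, "exon_ends")
    validate_annotation(a)
    a
  })
}

#' TSS positions of an annotation
#'
#' @param annotation An annotation data.frame.
#' @return data.frame with `chrom`, `pos` (0-based TSS base), `strand`.
#' @export
annotation_tss <- function(annotation) {
  data.frame(chrom = annotation$chrom,
             pos = ifelse(annotation$strand == "+", annotation$tx_start,
                          annotation$tx_end - 1L),
             strand = annotation$strand, stringsAsFactors = FALSE)
}

# Draw one site location honouring the promoter bias; returns list or NULL.
.draw_site <- function(cfg, tss, taken, bias) {
  w <- cfg$mean_site_width
  for (try in 1:1000) {
    if (nrow(tss) && stats::runif(1) < bias) {
      j <- sample.int(nrow(tss), 1L)
      chrom <- tss$chrom[j]
      summit <- tss$pos[j] + .round_half_up(stats::rnorm(1, 0, 500))
    } else {
      chrom <- .sample_chrom(cfg, 1L)
      summit <- sample.int(as.integer(cfg$chrom_lengths[[chrom]]), 1L) - 1L
    }
    L <- as.integer(cfg$chrom_lengths[[chrom]])
    s <- as.integer(summit) - w %/% 2L
    s <- max(0L, min(s, L - w))
    if (s < 0L) next
    e <- s + w
    t <- taken[[chrom]]
    if (nrow(t) && any(s < t$end + cfg$min_site_gap &
                       e + cfg$min_site_gap > t$start)) next
    return(list(chrom = chrom, start = s, end = e,
                summit = s + w %/% 2L))
  }
  NULL
}

#' Plant regulatory sites (ground truth)
#'
#' Draws `n_modules` multi-TF modules: each module picks a co-binding block,
#' then includes each TF of that block with probability `within_block_prob`
#' and every other TF with probability `between_block_prob`, redrawing until
#' at least two TFs are bound.  Additional single-TF sites are appended so
#' that singletons form `singleton_rate` of all truth sites.  Sites never
#' overlap (minimum gap `min_site_gap`).
#'
#' @param config A [sim_config()].
#' @param annotation Annotation data.frame used for TSS-proximal placement.
#' @param promoter_bias Optional override of `config$promoter_bias`; either a
#'   scalar probability or a function of the module's TF count returning a
#'   probability (used to plant complexity-dependent promoter bias).
#' @return A truth data.frame: `chrom`, `start`, `end`, `summit`,
#'   `module_id`, `block_id`, `tf_set` (list-column), `n_tfs`, `kind`.
#' @export
plant_regulatory_sites <- function(config, annotation,
                                   promoter_bias = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(promoter_bias)) promoter_bias <- config$promoter_bias
  bias_fun <- if (is.function(promoter_bias)) promoter_bias else {
    function(size) promoter_bias
  }
  .with_seed(.substream_seed(config$seed, "sites"), {
    tss <- annotation_tss(annotation)
    blocks <- config$community_blocks
    n_single <- if (config$singleton_rate > 0) {
      as.integer(round(config$n_modules * config$singleton_rate /
                         (1 - config$singleton_rate)))
    } else 0L
    n_total <- config$n_modules + n_single
    if (n_total == 0L) {
      out <- .empty_catalogue()
      out$summit <- integer(0); out$module_id <- integer(0)
      out$block_id <- character(0)
      return(out[c("chrom", "start", "end", "summit", "module_id",
                   "block_id", "tf_set", "n_tfs", "kind")])
    }
    taken <- lapply(config$chrom_lengths, function(...) {
      data.frame(start = integer(0), end = integer(0))
    })
    tf_block <- stats::setNames(
      rep(names(blocks), lengths(blocks)), unlist(blocks))
    rows <- vector("list", n_total)
    for (m in seq_len(n_total)) {
      if (m <= config$n_modules) {
        bl <- sample(names(blocks), 1L)
        set <- character(0)
        for (try in 1:100) {
          p <- ifelse(config$tfs %in% blocks[[bl]],
                      config$within_block_prob, config$between_block_prob)
          set <- config$tfs[stats::runif(config$n_tfs) < p]
          if (length(set) >= 2L) break
        }
        if (length(set) < 2L) set <- sample(blocks[[bl]], 2L)
      } else {
        set <- sample(config$tfs, 1L)
        bl <- unname(tf_block[set])
      }
      loc <- .draw_site(config, tss, taken, bias_fun(length(set)))
      if (is.null(loc)) {
        stop("placement error: genome too small for ", n_total,
             " non-overlapping sites", call. = FALSE)
      }
      taken[[loc$chrom]] <- rbind(
        taken[[loc$chrom]],
        data.frame(start = loc$start, end = loc$end))
      rows[[m]] <- c(loc, list(module_id = m, block_id = bl, tf_set = set))
    }
    out <- data.frame(
      chrom = vapply(rows, `[[`, "", "chrom"),
      start = vapply(rows, function(r) r$start, 1L),
      end = vapply(rows, function(r) r$end, 1L),
      summit = vapply(rows, function(r) r$summit, 1L),
      module_id = vapply(rows, function(r) r$module_id, 1L),
      block_id = vapply(rows, `[[`, "", "block_id"),
      stringsAsFactors = FALSE)
    out$tf_set <- lapply(rows, function(r) sort(r$tf_set))
    out$n_tfs <- lengths(out$tf_set)
    out$kind <- ifelse(out$n_tfs >= 2L, "crm", "singleton")
    out
  })
}

#' Simulate per-dataset ChIP-seq peaks
#'
#' For every TF, `datasets_per_tf` datasets labelled `SIM<k>.<TF>.sim` are
#' generated.  Each dataset recovers every true site of its TF independently
#' with probability `sensitivity`, with the observed summit jittered by
#' Normal(0, `summit_jitter_sd`) (clamped strictly inside the peak) and the
#' peak width drawn as `mean_site_width` + Normal(0, `peak_width_sd`)
#' (floored at 50 bp), and adds `noise_peaks_per_dataset` uniformly placed
#' false peaks.  The `origin` column records provenance (`module_id` or
#' `"noise"`); noise peaks may still overlap truth by chance.
#'
#' Each dataset draws from its own seeded substream, so adding or removing
#' datasets never changes the others.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [plant_regulatory_sites()].
#' @return Named list (by dataset label) of peak data.frames.
#' @export
simulate_peak_datasets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), config$datasets_per_tf >= 1L)
  out <- list()
  for (tf in config$tfs) {
    has_tf <- vapply(truth$tf_set, function(s) tf %in% s, TRUE)
    sites <- truth[has_tf, , drop = FALSE]
    for (k in seq_len(config$datasets_per_tf)) {
      label <- sprintf("SIM%d.%s.sim", k, tf)
      out[[label]] <- .with_seed(
        .substream_seed(config$seed, paste0("dataset:", label)),
        .simulate_one_dataset(config, sites, label))
    }
  }
  out
}

.simulate_one_dataset <- function(cfg, sites, label) {
  n <- nrow(sites)
  det <- if (n) stats::runif(n) < cfg$sensitivity else logical(0)
  sig <- sites[det, , drop = FALSE]
  ns <- nrow(sig)
  mk <- function(chrom, summit0, origin) {
    m <- length(summit0)
    w <- pmax(50L, as.integer(.round_half_up(
      cfg$mean_site_width + stats::rnorm(m, 0, cfg$peak_width_sd))))
    sm <- as.integer(.round_half_up(
      summit0 + stats::rnorm(m, 0, cfg$summit_jitter_sd)))
    L <- as.integer(cfg$chrom_lengths[chrom])
    s <- pmax(0L, pmin(sm - w %/% 2L, L - w))
    e <- s + w
    sm <- pmax(s, pmin(sm, e - 1L))  # clamp summit strictly inside
    df <- data.frame(chrom = chrom, start = s, end = e, summit = sm,
                     dataset = label, score = NA_real_,
                     stringsAsFactors = FALSE)
    df$origin <- origin
    df
  }
  sig_peaks <- if (ns) mk(sig$chrom, sig$summit, as.character(sig$module_id))
  else NULL
  nn <- cfg$noise_peaks_per_dataset
  noise_peaks <- if (nn) {
    chrom <- .sample_chrom(cfg, nn)
    L <- as.integer(cfg$chrom_lengths[chrom])
    summit0 <- vapply(L, function(l) sample.int(l, 1L) - 1L, 1L)
    mk(chrom, summit0, "noise")
  } else NULL
  out <- rbind(sig_peaks, noise_peaks)
  if (is.null(out)) {
    out <- empty_peaks(); out$origin <- character(0)
  }
  rownames(out) <- NULL
  out
}

#' Simulate stranded sequencing reads
#'
#' Generates `reads_per_site` fragments of length `fragment_length` per site,
#' with fragment centres scattered Normal(0, `read_scatter_sd`) around the
#' summit.  Each fragment emits one 5' read position on a uniformly chosen
#' strand: the plus-strand 5' end is the fragment's left end, the
#' minus-strand 5' end its right end (`left + fragment_length - 1`).
#' `background_read_fraction` of all reads are instead placed uniformly on
#' the genome on random strands.
#'
#' @param config A [sim_config()].
#' @param sites A data.frame with `chrom` and `summit` (truth table or
#'   peaks); reads are centred on the summits.
#' @return A [read_positions()] object.
#' @export
simulate_reads <- function(config, sites) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.substream_seed(config$seed, "reads"), {
    n_sites <- nrow(sites)
    n_total <- config$reads_per_site * n_sites
    n_bg <- as.integer(round(config$background_read_fraction * n_total))
    n_sig <- n_total - n_bg
    fl <- config$fragment_length
    pos <- data.frame(chrom = character(0), p = integer(0),
                      minus = logical(0))
    if (n_sig > 0L) {
      idx <- rep(seq_len(n_sites), length.out = n_sig)
      centre <- sites$summit[idx] +
        .round_half_up(stats::rnorm(n_sig, 0, config$read_scatter_sd))
      L <- as.integer(config$chrom_lengths[sites$chrom[idx]])
      left <- as.integer(pmax(0L, pmin(centre - fl %/% 2L, L - fl)))
      minus <- stats::runif(n_sig) < 0.5
      pos <- rbind(pos, data.frame(
        chrom = sites$chrom[idx],
        p = ifelse(minus, left + fl - 1L, left),
        minus = minus, stringsAsFactors = FALSE))
    }
    if (n_bg > 0L) {
      chrom <- .sample_chrom(config, n_bg)
      L <- as.integer(config$chrom_lengths[chrom])
      p <- vapply(L, function(l) sample.int(l, 1L) - 1L, 1L)
      pos <- rbind(pos, data.frame(chrom = chrom, p = p,
                                   minus = stats::runif(n_bg) < 0.5,
                                   stringsAsFactors = FALSE))
    }
    read_positions(split(pos$p[!pos$minus], pos$chrom[!pos$minus]),
                   split(pos$p[pos$minus], pos$chrom[pos$minus]),
                   config$read_length)
  })
}

#' Simulate query regions with planted TF enrichment
#'
#' `spike_fraction` of the regions are windows of `query_width` bp centred
#' on randomly chosen truth sites bound by at least one of `enriched_tfs`;
#' the rest are uniform random windows.
#'
#' @param config A [sim_config()].
#' @param truth Truth table from [plant_regulatory_sites()].
#' @param enriched_tfs Character vector of TFs to spike.
#' @param n_regions Number of query regions.
#' @param spike_fraction Fraction of regions spiked.
#' @return data.frame `chrom`, `start`, `end`, `provenance`
#'   (`"spiked"`/`"background"`).
#' @export
simulate_query_regions <- function(config, truth, enriched_tfs, n_regions,
                                   spike_fraction) {
  stopifnot(inherits(config, "sim_config"), .is_fraction(spike_fraction),
            all(enriched_tfs %in% config$tfs))
  .with_seed(.substream_seed(config$seed, "queries"), {
    n_spike <- as.integer(round(spike_fraction * n_regions))
    n_bg <- n_regions - n_spike
    qw <- config$query_width
    parts <- list()
    if (n_spike > 0L) {
      cand <- which(vapply(truth$tf_set,
                           function(s) any(enriched_tfs %in% s), TRUE))
      if (length(cand) == 0L) {
        stop("generation error: no truth site contains an enriched TF",
             call. = FALSE)
      }
      idx <- cand[sample.int(length(cand), n_spike, replace = TRUE)]
      L <- as.integer(config$chrom_lengths[truth$chrom[idx]])
      s <- as.integer(pmax(0L, pmin(truth$summit[idx] - qw %/% 2L, L - qw)))
      parts$spike <- data.frame(chrom = truth$chrom[idx], start = s,
                                end = s + qw, provenance = "spiked",
                                stringsAsFactors = FALSE)
    }
    if (n_bg > 0L) {
      chrom <- .sample_chrom(config, n_bg)
      L <- as.integer(config$chrom_lengths[chrom])
      s <- vapply(L, function(l) sample.int(l - qw, 1L) - 1L, 1L)
      parts$bg <- data.frame(chrom = chrom, start = s, end = s + qw,
                             provenance = "background",
                             stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, parts)
    if (is.null(out)) {
      out <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), provenance = character(0),
                        stringsAsFactors = FALSE)
    }
    rownames(out) <- NULL
    out
  })
}
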