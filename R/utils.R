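# Internal helpers: coordinate conversion, validation, seeded substreams.

# Convert a 0-based half-open interval data.frame to GRanges (1-based closed).
.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

.check_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L) || any(df$start >= df$end)) {
    stop(what, ": requires 0 <= start < end", call. = FALSE)
  }
  invisible(df)
}

.sort_regions <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# Round half away from zero (deterministic summit averaging).
.round_half_up <- function(x) floor(x + 0.5)

# Deterministic substream seed derived from a master seed and a component id.
# Keeps every derived seed below 2^31 - 1.
.substream_seed <- function(seed, component) {
  m <- 2147480009          # large prime < 2^31
  h <- 0
  for (ch in utf8ToInt(as.character(component))) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) * 1103515 + h) %% m)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

.is_fraction <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1
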