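# On-disk formats.  All files are whitespace-delimited, headerless BED
# dialects in 0-based half-open coordinates; `track`/`browser`/`#` lines are
# ignored.  Chromosome names are compared as exact text (no "chr"
# normalisation).

.read_bed_fields <- function(path, min_fields) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*$|^track\\b|^browser\\b|^#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(list(fields = list(), lineno = integer(0)))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    bad <- lineno[which(nf < min_fields)[1]]
    stop("parse error at line ", bad, " of '", path, "': expected >= ",
         min_fields, " fields", call. = FALSE)
  }
  list(fields = fields, lineno = lineno)
}

.field_int <- function(fields, idx, path, lineno) {
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", idx)))
  bad <- is.na(x) | x != floor(x)
  if (any(bad)) {
    stop("parse error at line ", lineno[which(bad)[1]], " of '", path,
         "': non-integer coordinate in column ", idx, call. = FALSE)
  }
  as.integer(x)
}

#' Read a peak file
#'
#' Peaks are BED4+ records `chrom start end summit-offset [score]` where the
#' summit offset is relative to `start` (the convention of MACS-style summit
#' output).  Coordinates are 0-based half-open.
#'
#' @param path Path to a whitespace-delimited peak file.
#' @param dataset A [dataset_label()] (or its dotted string form) attached to
#'   every peak.
#' @param missing_summit `"error"` (default) requires the 4th column;
#'   `"midpoint"` accepts BED3 records, assigning `summit = floor((start +
#'   end)/2)` (useful for external cluster tracks distributed without
#'   summits); such calls set the attribute `summit_imputed = TRUE` on the
#'   result.
#' @return A data.frame of peaks with columns `chrom`, `start`, `end`,
#'   `summit`, `dataset`, `score` (NA when absent), in file order.
#' @export
read_peaks <- function(path, dataset, missing_summit = c("error", "midpoint")) {
  missing_summit <- match.arg(missing_summit)
  if (inherits(dataset, "dataset_label")) dataset <- format(dataset)
  dataset <- format(parse_dataset_label(dataset))  # validates
  min_fields <- if (missing_summit == "error") 4L else 3L
  parsed <- .read_bed_fields(path, min_fields)
  fields <- parsed$fields
  if (length(fields) == 0L) return(empty_peaks())
  lineno <- parsed$lineno
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- .field_int(fields, 2L, path, lineno)
  end <- .field_int(fields, 3L, path, lineno)
  bad <- start < 0L | start >= end
  if (any(bad)) {
    stop("invalid record at line ", lineno[which(bad)[1]], " of '", path,
         "': requires 0 <= start < end", call. = FALSE)
  }
  nf <- lengths(fields)
  imputed <- FALSE
  if (all(nf >= 4L)) {
    offset <- .field_int(fields, 4L, path, lineno)
    summit <- start + offset
    bad <- summit < start | summit >= end
    if (any(bad)) {
      stop("invalid record at line ", lineno[which(bad)[1]], " of '", path,
           "': summit outside [start, end)", call. = FALSE)
    }
  } else if (missing_summit == "midpoint") {
    summit <- start + (end - start) %/% 2L
    imputed <- TRUE
  } else {
    stop("parse error in '", path, "': missing summit column", call. = FALSE)
  }
  score <- rep(NA_real_, length(fields))
  has5 <- nf >= 5L
  if (any(has5)) {
    score[has5] <- suppressWarnings(
      as.numeric(vapply(fields[has5], `[[`, "", 5L)))
  }
  out <- data.frame(chrom = chrom, start = start, end = end, summit = summit,
                    dataset = dataset, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "summit_imputed") <- imputed
  out
}

#' An empty peak data.frame
#' @return Zero-row peaks data.frame with the canonical columns.
#' @export
empty_peaks <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             summit = integer(0), dataset = character(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Write peaks or catalogue regions as BED
#'
#' Peak-style input (any data.frame with a `summit` column) is written as
#' BED4+ `chrom start end summit-offset [score]`.  Catalogue-style input
#' (with a `tf_set` list-column) is written as BED5 `chrom start end
#' TF1,TF2,... n_TFs`.  Rows are sorted by `(chrom, start, end)`;
#' re-reading with [read_peaks()] / [read_regions()] reproduces the records.
#'
#' @param x A peaks data.frame or a catalogue data.frame (see
#'   [build_crms()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(x, path) {
  .check_intervals(x, "write_regions")
  x <- .sort_regions(x)
  if ("summit" %in% names(x)) {
    cols <- data.frame(x$chrom, x$start, x$end, x$summit - x$start)
    if ("score" %in% names(x) && any(!is.na(x$score))) cols$score <- x$score
  } else if ("tf_set" %in% names(x)) {
    tfs <- vapply(x$tf_set, function(s) paste(sort(s), collapse = ","), "")
    cols <- data.frame(x$chrom, x$start, x$end, tfs,
                       vapply(x$tf_set, length, 1L))
  } else {
    cols <- data.frame(x$chrom, x$start, x$end)
  }
  utils::write.table(cols, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a catalogue region file
#'
#' Reads BED5 `chrom start end TF-list TF-count` as written by
#' [write_regions()].  `n_sites` is not stored in the file and is returned as
#' `NA`.
#'
#' @param path Path to a catalogue BED file.
#' @return A catalogue data.frame with columns `chrom`, `start`, `end`,
#'   `tf_set` (list of character vectors), `n_tfs`, `n_sites` (NA), `kind`.
#' @export
read_regions <- function(path) {
  parsed <- .read_bed_fields(path, 5L)
  fields <- parsed$fields
  if (length(fields) == 0L) return(.empty_catalogue())
  lineno <- parsed$lineno
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- .field_int(fields, 2L, path, lineno)
  end <- .field_int(fields, 3L, path, lineno)
  tf_set <- strsplit(vapply(fields, `[[`, "", 4L), ",", fixed = TRUE)
  n_tfs <- .field_int(fields, 5L, path, lineno)
  if (any(lengths(tf_set) != n_tfs)) {
    bad <- lineno[which(lengths(tf_set) != n_tfs)[1]]
    stop("invalid record at line ", bad, " of '", path,
         "': TF count does not match TF list", call. = FALSE)
  }
  out <- data.frame(chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  out$tf_set <- tf_set
  out$n_tfs <- n_tfs
  out$n_sites <- NA_integer_
  out$kind <- ifelse(n_tfs >= 2L, "crm", "singleton")
  .check_intervals(out, "read_regions")
  out
}

.empty_catalogue <- function() {
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  out$tf_set <- list()
  out$n_tfs <- integer(0)
  out$n_sites <- integer(0)
  out$kind <- character(0)
  out
}

#' Read a bedGraph score track
#'
#' 4 columns `chrom start end value`, 0-based half-open; runs on the same
#' chromosome must not overlap (book-ended runs are allowed).  Bases not
#' covered by any run are absent (`NA` on lookup).
#'
#' @param path Path to a bedGraph-dialect file.
#' @return An object of class `score_track`: a named list of per-chromosome
#'   data.frames `start`, `end`, `value`, sorted by start.
#' @seealso [track_values()]
#' @export
read_score_track <- function(path) {
  parsed <- .read_bed_fields(path, 4L)
  fields <- parsed$fields
  if (length(fields) == 0L) return(score_track(list()))
  lineno <- parsed$lineno
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = .field_int(fields, 2L, path, lineno),
    end = .field_int(fields, 3L, path, lineno),
    value = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L))),
    stringsAsFactors = FALSE)
  if (anyNA(df$value)) {
    stop("parse error in '", path, "': non-numeric value", call. = FALSE)
  }
  score_track(split(df[c("start", "end", "value")], df$chrom))
}

#' Construct a score track from per-chromosome runs
#'
#' @param runs Named list (by chromosome) of data.frames with columns
#'   `start`, `end`, `value` (0-based half-open runs).
#' @return A `score_track` object.
#' @export
score_track <- function(runs) {
  runs <- lapply(runs, function(r) {
    r <- r[order(r$start), , drop = FALSE]
    .check_intervals(cbind(chrom = "x", r), "score_track")
    if (nrow(r) > 1L && any(r$start[-1] < r$end[-nrow(r)])) {
      stop("invalid track: overlapping runs", call. = FALSE)
    }
    rownames(r) <- NULL
    r
  })
  structure(runs, class = "score_track")
}

#' Look up per-base track values
#'
#' @param track A `score_track`.
#' @param chrom Chromosome name (scalar).
#' @param positions Integer vector of 0-based base positions.
#' @return Numeric vector of values; `NA` where the track has no run.
#' @export
track_values <- function(track, chrom, positions) {
  stopifnot(inherits(track, "score_track"))
  r <- track[[chrom]]
  out <- rep(NA_real_, length(positions))
  if (is.null(r) || nrow(r) == 0L) return(out)
  idx <- findInterval(positions, r$start)
  ok <- idx >= 1L
  ok[ok] <- positions[ok] < r$end[idx[ok]]
  out[ok] <- r$value[idx[ok]]
  out
}

#' Stranded 5' read positions
#'
#' Container for the 5'-end positions of plus- and minus-strand reads, used
#' by the cross-correlation quality metrics.  Positions are 0-based and kept
#' sorted per chromosome.
#'
#' @param plus,minus Named lists (by chromosome) of integer position vectors.
#' @param read_length Read length in bp (>= 1).
#' @return An object of class `read_positions`.
#' @export
read_positions <- function(plus, minus, read_length) {
  stopifnot(.is_count(read_length), read_length >= 1)
  norm <- function(x) {
    x <- lapply(x, function(p) {
      p <- as.integer(sort(p))
      if (length(p) && p[1] < 0L) stop("negative read position", call. = FALSE)
      p
    })
    x[lengths(x) > 0L]
  }
  structure(list(plus = norm(plus), minus = norm(minus),
                 read_length = as.integer(read_length)),
            class = "read_positions")
}

#' @export
print.read_positions <- function(x, ...) {
  cat("<read_positions> ", sum(lengths(x$plus)), " plus / ",
      sum(lengths(x$minus)), " minus reads on ",
      length(union(names(x$plus), names(x$minus))),
      " chromosome(s), read length ", x$read_length, "\n", sep = "")
  invisible(x)
}

#' Write stranded read positions
#'
#' One file per strand: a `#read_length=N` header line followed by
#' 2-column records `chrom position` (0-based 5' position).
#'
#' @param reads A [read_positions()] object.
#' @param plus_path,minus_path Output paths for the two strands.
#' @return Invisibly, `c(plus_path, minus_path)`.
#' @export
write_reads <- function(reads, plus_path, minus_path) {
  stopifnot(inherits(reads, "read_positions"))
  wr <- function(strand, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#read_length=", reads$read_length), con)
    for (chrom in names(strand)) {
      writeLines(paste(chrom, strand[[chrom]], sep = "\t"), con)
    }
  }
  wr(reads$plus, plus_path)
  wr(reads$minus, minus_path)
  invisible(c(plus_path, minus_path))
}

#' Read stranded read positions
#'
#' @param plus_path,minus_path Files written by [write_reads()].
#' @return A [read_positions()] object.
#' @export
read_reads <- function(plus_path, minus_path) {
  rd <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#read_length=", lines, value = TRUE)
    if (length(hdr) != 1L) {
      stop("'", path, "': expected one #read_length= header", call. = FALSE)
    }
    rl <- as.integer(sub("^#read_length=", "", hdr))
    lines <- lines[!grepl("^#|^\\s*$", lines)]
    if (length(lines) == 0L) return(list(pos = list(), read_length = rl))
    fields <- strsplit(trimws(lines), "\\s+")
    chrom <- vapply(fields, `[[`, "", 1L)
    pos <- as.integer(vapply(fields, `[[`, "", 2L))
    list(pos = split(pos, chrom), read_length = rl)
  }
  p <- rd(plus_path)
  m <- rd(minus_path)
  if (p$read_length != m$read_length) {
    stop("read length differs between strand files", call. = FALSE)
  }
  read_positions(p$pos, m$pos, p$read_length)
}

#' Write a gene annotation as BED12
#'
#' @param annotation An annotation data.frame (see [read_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  a <- annotation
  n <- nrow(a)
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  sizes <- vapply(seq_len(n), function(i) {
    paste(a$exon_ends[[i]] - a$exon_starts[[i]], collapse = ",")
  }, "")
  rel <- vapply(seq_len(n), function(i) {
    paste(a$exon_starts[[i]] - a$tx_start[i], collapse = ",")
  }, "")
  cols <- data.frame(a$chrom, a$tx_start, a$tx_end, a$gene_id, 0L, a$strand,
                     a$cds_start, a$cds_end, 0L,
                     lengths(a$exon_starts), sizes, rel)
  utils::write.table(cols, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation from BED12
#'
#' Gene models carry transcript and CDS bounds plus exon blocks; the TSS of a
#' plus-strand gene is `tx_start`, of a minus-strand gene `tx_end - 1`.
#' Non-coding genes are encoded with `cds_start == cds_end` (BED12 thickStart
#' = thickEnd convention).
#'
#' @param path Path to a BED12 file.
#' @return An annotation data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_start`, `cds_end` and list-columns
#'   `exon_starts`, `exon_ends` (absolute 0-based half-open coordinates).
#' @export
read_annotation <- function(path) {
  parsed <- .read_bed_fields(path, 12L)
  fields <- parsed$fields
  if (length(fields) == 0L) return(empty_annotation())
  lineno <- parsed$lineno
  a <- data.frame(
    gene_id = vapply(fields, `[[`, "", 4L),
    chrom = vapply(fields, `[[`, "", 1L),
    strand = vapply(fields, `[[`, "", 6L),
    tx_start = .field_int(fields, 2L, path, lineno),
    tx_end = .field_int(fields, 3L, path, lineno),
    cds_start = .field_int(fields, 7L, path, lineno),
    cds_end = .field_int(fields, 8L, path, lineno),
    stringsAsFactors = FALSE)
  if (!all(a$strand %in% c("+", "-"))) {
    stop("parse error in '", path, "': strand must be + or -", call. = FALSE)
  }
  ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1]])
  a$exon_starts <- lapply(seq_along(fields), function(i) {
    a$tx_start[i] + ints(fields[[i]][12])
  })
  a$exon_ends <- lapply(seq_along(fields), function(i) {
    a$exon_starts[[i]] + ints(fields[[i]][11])
  })
  validate_annotation(a)
}

#' @rdname read_annotation
#' @return `empty_annotation()`: a zero-row annotation data.frame.
#' @export
empty_annotation <- function() {
  out <- data.frame(gene_id = character(0), chrom = character(0),
                    strand = character(0), tx_start = integer(0),
                    tx_end = integer(0), cds_start = integer(0),
                    cds_end = integer(0), stringsAsFactors = FALSE)
  out$exon_starts <- list()
  out$exon_ends <- list()
  out
}

#' Validate an annotation data.frame
#'
#' Checks the gene-model invariants: exons within `[tx_start, tx_end)`,
#' sorted and non-overlapping; CDS within the transcript.
#'
#' @param a An annotation data.frame.
#' @return `a`, invisibly (or an error).
#' @export
validate_annotation <- function(a) {
  for (i in seq_len(nrow(a))) {
    es <- a$exon_starts[[i]]; ee <- a$exon_ends[[i]]
    if (length(es) == 0L || length(es) != length(ee)) {
      stop("gene ", a$gene_id[i], ": needs >= 1 exon block", call. = FALSE)
    }
    if (any(es >= ee) || es[1] < a$tx_start[i] ||
        ee[length(ee)] > a$tx_end[i] ||
        (length(es) > 1L && any(es[-1] < ee[-length(ee)]))) {
      stop("gene ", a$gene_id[i], ": exon blocks must be sorted, ",
           "non-overlapping and within the transcript", call. = FALSE)
    }
    if (a$cds_start[i] > a$cds_end[i] || a$cds_start[i] < a$tx_start[i] ||
        a$cds_end[i] > a$tx_end[i]) {
      stop("gene ", a$gene_id[i], ": CDS outside transcript", call. = FALSE)
    }
  }
  invisible(a)
}
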