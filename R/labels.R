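#' Dataset labels
#'
#' Each ChIP-seq dataset is identified by the dotted concatenation of a series
#' accession, an uppercased official TF symbol and a biological condition,
#' e.g. `"GSE41561.ESR1.MCF-7"`.  The condition may itself contain dots
#' (only the first two dots delimit fields), so cell line names such as
#' `MCF-7` or compound conditions survive a round trip.
#'
#' @param series_id,tf_name,condition Character scalars; none may be empty.
#' @return An object of class `dataset_label`: a named list with fields
#'   `series_id`, `tf_name` and `condition`.
#' @examples
#' lab <- dataset_label("GSE41561", "ESR1", "MCF-7")
#' format(lab)
#' parse_dataset_label("S1.TF1.cond.a")$condition  # "cond.a"
#' @export
dataset_label <- function(series_id, tf_name, condition) {
  parts <- c(series_id = series_id, tf_name = tf_name, condition = condition)
  if (any(!nzchar(parts)) || anyNA(parts)) {
    stop("malformed label: all of series_id, tf_name, condition must be non-empty",
         call. = FALSE)
  }
  structure(list(series_id = unname(series_id),
                 tf_name = unname(tf_name),
                 condition = unname(condition)),
            class = "dataset_label")
}

#' Parse a dotted dataset label
#'
#' Splits on the first two dots only: the first token is the series
#' accession, the second the TF name, and the remainder (which may contain
#' further dots) is the condition.
#'
#' @param text A character scalar such as `"GSE41561.ESR1.MCF-7"`.
#' @return A [dataset_label()].
#' @export
parse_dataset_label <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, ".", fixed = TRUE)[[1]]
  if (length(parts) < 3L) {
    stop("malformed label '", text,
         "': expected series.TF.condition (>= 2 dots)", call. = FALSE)
  }
  dataset_label(parts[1], parts[2], paste(parts[-(1:2)], collapse = "."))
}

#' @export
format.dataset_label <- function(x, ...) {
  paste(x$series_id, x$tf_name, x$condition, sep = ".")
}

#' @export
print.dataset_label <- function(x, ...) {
  cat("<dataset_label> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.dataset_label <- function(x, ...) format(x)

# TF name for a vector of label strings (vectorised, internal).
.label_tf <- function(labels) {
  vapply(strsplit(labels, ".", fixed = TRUE), function(p) {
    if (length(p) < 3L) stop("malformed label '", paste(p, collapse = "."),
                             "'", call. = FALSE)
    p[2]
  }, character(1))
}
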