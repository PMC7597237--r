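# Serialization: pmf documents (TSV/CSV/JSON), observation tables.
#
# The tabular dialect is deliberately simple: a header of variable names
# plus a final probability column `p`, '#' comments, '.' decimal separator;
# fractions such as "5/6" are accepted and parsed exactly.  Results are
# validated into `joint_pmf` objects on read.

.parse_prob <- function(x) {
  x <- trimws(as.character(x))
  vapply(x, function(s) {
    if (grepl("^[-+0-9.eE]+/[0-9.eE]+$", s)) {
      parts <- strsplit(s, "/", fixed = TRUE)[[1L]]
      as.numeric(parts[1L]) / as.numeric(parts[2L])
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop(sprintf("cannot parse probability '%s'", s))
      v
    }
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Read a joint pmf from a TSV, CSV or JSON document
#'
#' Tabular documents carry one state per row with a final probability (or
#' count) column named `p`; JSON documents carry `variables`, optionally
#' `alphabets`, and a `table` of rows.  Alphabet order is first-appearance
#' order unless declared in the JSON header.
#'
#' @param path input file.
#' @param format `"tsv"`, `"csv"` or `"json"`; guessed from the extension by
#'   default.
#' @param counts if `TRUE`, the probability column holds counts and is
#'   normalized to a plug-in pmf.
#' @param tol normalization tolerance for files (default `1e-6`).
#' @return A [joint_pmf].
#' @export
read_pmf <- function(path, format = NULL, counts = FALSE, tol = 1e-6) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tsv", "csv", "json")) ext else "tsv"
  }
  format <- match.arg(format, c("tsv", "csv", "json"))
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(doc$table) || is.null(doc$variables))
      stop("JSON pmf document needs fields 'variables' and 'table'")
    tab <- as.data.frame(doc$table, stringsAsFactors = FALSE)
    vars <- as.character(doc$variables)
    alphabets <- if (!is.null(doc$alphabets))
      lapply(doc$alphabets, as.character) else NULL
    p <- .parse_prob(tab$p)
    states <- tab[vars]
  } else {
    sep <- if (format == "tsv") "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             comment.char = "#", colClasses = "character",
                             check.names = FALSE, strip.white = TRUE)
    if (ncol(tab) < 2L)
      stop("a pmf document needs at least one variable column plus 'p'")
    pcol <- if ("p" %in% names(tab)) "p" else names(tab)[ncol(tab)]
    vars <- setdiff(names(tab), pcol)
    p <- .parse_prob(tab[[pcol]])
    states <- tab[vars]
    alphabets <- NULL
  }
  if (!nrow(states)) stop("empty pmf document")
  key <- do.call(paste, c(states, sep = .SEP))
  if (anyDuplicated(key))
    stop("duplicate state rows in pmf document")
  if (counts) {
    if (any(p < 0)) stop("negative counts")
    p <- p / sum(p)
  } else if (abs(sum(p) - 1) > tol) {
    stop(sprintf("probabilities sum to %.8g (deficit %.3g); not a pmf",
                 sum(p), 1 - sum(p)))
  }
  joint_pmf(states, p / sum(p), alphabets = alphabets)
}

#' Write a joint pmf to TSV, CSV or JSON
#'
#' @param pmf a [joint_pmf].
#' @param path output file.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @param drop_zero omit zero-probability states from tabular output
#'   (alphabet order of remaining symbols is preserved).
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path, format = c("tsv", "csv", "json"),
                      drop_zero = TRUE) {
  stopifnot(inherits(pmf, "joint_pmf"))
  format <- match.arg(format)
  df <- as.data.frame(pmf)
  if (format == "json") {
    jsonlite::write_json(list(variables = pmf$variables,
                              alphabets = pmf$alphabets,
                              table = df[df$p > 0 | !drop_zero, ]),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    if (drop_zero) df <- df[df$p > 0, , drop = FALSE]
    utils::write.table(format(df, digits = 17, scientific = FALSE,
                              trim = TRUE),
                       path, sep = if (format == "tsv") "\t" else ",",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Plug-in pmf from raw categorical observations
#'
#' Reads a table with one categorical record per row (header = variable
#' names) and returns the empirical relative-frequency pmf.
#'
#' @param path input file.
#' @param sep field separator (tab by default).
#' @return A [joint_pmf].
#' @export
read_observations <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", colClasses = "character",
                           check.names = FALSE, strip.white = TRUE)
  if (!nrow(tab)) stop("no observations in file")
  if (nrow(tab) == 1L)
    warning("a single observation yields a degenerate pmf")
  key <- do.call(paste, c(tab, sep = .SEP))
  counts <- table(key)
  first <- tab[!duplicated(key), , drop = FALSE]
  joint_pmf(first, as.numeric(counts[do.call(paste,
                                             c(first, sep = .SEP))]) / nrow(tab))
}
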