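#' Mixed-type data matrices with an explicit missingness mask
#'
#' The container used throughout: samples x variables, continuous values
#' stored as numerics and discrete values as integer codes into the
#' declared level sets, plus a logical missingness mask of the same
#' shape.  Construct from a data frame whose discrete columns are
#' character or factor.
#'
#' @param values data frame or matrix, one column per variable; column
#'   names must match `meta$name` (any order; alignment is by name).
#' @param meta a [variable_meta()] table covering every column.
#' @param sample_ids optional character vector of row identifiers;
#'   defaults to row names or `"S1"..."Sn"`.
#' @return An object of class `mixbn_data`: a list with elements `x`
#'   (numeric matrix; discrete columns hold level codes), `missing`
#'   (logical matrix), `meta` and `sample_ids`.
#' @export
mixbn_data <- function(values, meta, sample_ids = NULL) {
  validate_meta(meta)
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  miss.cols <- setdiff(meta$name, names(values))
  if (length(miss.cols))
    stop("variables declared in metadata but absent from data: ",
         paste(miss.cols, collapse = ", "))
  extra <- setdiff(names(values), meta$name)
  if (length(extra))
    stop("columns not declared in metadata: ", paste(extra, collapse = ", "))
  values <- values[meta$name]
  n <- nrow(values)
  if (is.null(sample_ids)) {
    rn <- rownames(values)
    sample_ids <- if (!is.null(rn) && !identical(rn, as.character(seq_len(n))))
      rn else paste0("S", seq_len(n))
  }
  stopifnot(length(sample_ids) == n)
  x <- matrix(NA_real_, n, nrow(meta), dimnames = list(NULL, meta$name))
  for (j in seq_len(nrow(meta))) {
    v <- values[[j]]
    if (meta$dtype[j] == "discrete") {
      lev <- meta$levels[[j]]
      v <- as.character(v)
      code <- match(v, lev)
      bad <- !is.na(v) & is.na(code)
      if (any(bad))
        stop("undeclared level(s) for '", meta$name[j], "': ",
             paste(unique(v[bad]), collapse = ", "))
      x[, j] <- code
    } else {
      if (is.character(v) || is.factor(v)) {
        vs <- as.character(v)
        vn <- suppressWarnings(as.numeric(vs))
        if (any(!is.na(vs) & is.na(vn)))
          stop("non-numeric value in continuous column '", meta$name[j], "'")
        v <- vn
      }
      x[, j] <- as.numeric(v)
    }
  }
  missing <- is.na(x)
  if (any(colSums(!missing) == 0))
    stop("every variable needs at least one non-missing value")
  structure(list(x = x, missing = missing, meta = meta,
                 sample_ids = as.character(sample_ids)),
            class = "mixbn_data")
}

#' @rdname mixbn_data
#' @param data a `mixbn_data` object.
#' @export
n_samples <- function(data) nrow(data$x)

#' @rdname mixbn_data
#' @export
n_variables <- function(data) ncol(data$x)

#' @rdname mixbn_data
#' @export
is_complete <- function(data) !any(data$missing)

#' @export
print.mixbn_data <- function(x, ...) {
  cat(sprintf("mixbn_data: %d samples x %d variables (%d discrete), %.1f%% missing\n",
              n_samples(x), n_variables(x), sum(is_discrete(x$meta)),
              100 * mean(x$missing)))
  invisible(x)
}

#' @export
as.data.frame.mixbn_data <- function(x, ...) {
  out <- as.data.frame(x$x)
  for (j in which(is_discrete(x$meta))) {
    lev <- x$meta$levels[[j]]
    out[[j]] <- lev[x$x[, j]]
  }
  rownames(out) <- x$sample_ids
  out
}

# Replace the values matrix keeping metadata; recompute the mask.
with_values <- function(data, x) {
  stopifnot(identical(dim(x), dim(data$x)))
  data$x <- x
  data$missing <- is.na(x)
  data
}

# Row-subset (bootstrap resampling); duplicated indices allowed.
subset_rows <- function(data, rows) {
  structure(list(x = data$x[rows, , drop = FALSE],
                 missing = data$missing[rows, , drop = FALSE],
                 meta = data$meta,
                 sample_ids = data$sample_ids[rows]),
            class = "mixbn_data")
}

#' Read and write sample x variable data tables
#'
#' Delimited text with a header row, first column the sample identifier,
#' missing values coded `"NA"`.  Columns are aligned to the metadata by
#' name, not by position.  The separator is auto-detected (tab or comma)
#' unless given.
#'
#' @param path data file path.
#' @param meta a [variable_meta()] table, or a path to a metadata file
#'   readable by [read_meta()].
#' @param sep field separator; `NULL` (default) auto-detects.
#' @return `read_data()` returns a [mixbn_data()] object.
#' @export
read_data <- function(path, meta, sep = NULL) {
  if (is.character(meta)) meta <- read_meta(meta)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, na.strings = "NA",
                           colClasses = "character", check.names = FALSE)
  ids <- raw[[1]]
  raw <- raw[-1]
  mixbn_data(raw, meta, sample_ids = ids)
}

#' @rdname read_data
#' @param data a `mixbn_data` object.
#' @param id_column name for the sample-identifier column.
#' @export
write_data <- function(data, path, sep = "\t", id_column = "sample_id") {
  df <- as.data.frame(data)
  out <- cbind(stats::setNames(data.frame(data$sample_ids,
                                          stringsAsFactors = FALSE), id_column),
               df)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
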