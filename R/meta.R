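#' Variable metadata tables
#'
#' A `mixbn_meta` table declares, for each variable, its measurement type
#' (`dtype`: `"continuous"` or `"discrete"`) and its biological class
#' (`vclass`: clinical, metabolite, protein, expression or allele score).
#' Discrete variables additionally carry an ordered vector of category
#' labels.  The declared type is honoured everywhere: a binary trait
#' declared continuous (e.g. a disease indicator that should be allowed
#' continuous parents) is modelled as Gaussian, never re-typed from its
#' cardinality.
#'
#' @param name character vector of unique variable names.
#' @param dtype character vector, `"continuous"` or `"discrete"`.
#' @param vclass character vector, one of `"clinical"`, `"metabolite"`,
#'   `"protein"`, `"expression"`, `"allele_score"`.
#' @param levels list of character vectors of category labels; must be
#'   given (length >= 2) for discrete variables, and `NULL` entries for
#'   continuous ones.
#' @return A data frame of class `mixbn_meta` with columns `name`,
#'   `dtype`, `vclass` and a list column `levels`.
#' @examples
#' variable_meta(c("bmi", "sex"), c("continuous", "discrete"),
#'               c("clinical", "clinical"),
#'               list(NULL, c("F", "M")))
#' @export
variable_meta <- function(name, dtype, vclass, levels = NULL) {
  name <- as.character(name)
  dtype <- as.character(dtype)
  vclass <- as.character(vclass)
  if (is.null(levels))
    levels <- vector("list", length(name))
  stopifnot(length(dtype) == length(name), length(vclass) == length(name),
            length(levels) == length(name))
  meta <- data.frame(name = name, dtype = dtype, vclass = vclass,
                     stringsAsFactors = FALSE)
  meta$levels <- lapply(levels, function(l) if (is.null(l)) NULL else as.character(l))
  class(meta) <- c("mixbn_meta", "data.frame")
  validate_meta(meta)
  meta
}

#' @rdname variable_meta
#' @param meta an object to validate as variable metadata.
#' @export
validate_meta <- function(meta) {
  stopifnot(is.data.frame(meta),
            all(c("name", "dtype", "vclass", "levels") %in% names(meta)))
  if (anyDuplicated(meta$name))
    stop("variable names must be unique")
  if (!all(meta$dtype %in% c("continuous", "discrete")))
    stop("dtype must be 'continuous' or 'discrete'")
  ok.class <- c("clinical", "metabolite", "protein", "expression", "allele_score")
  if (!all(meta$vclass %in% ok.class))
    stop("vclass must be one of: ", paste(ok.class, collapse = ", "))
  disc <- meta$dtype == "discrete"
  n.lev <- vapply(meta$levels, length, integer(1))
  if (any(disc & n.lev < 2))
    stop("discrete variables must declare at least 2 levels")
  if (any(!disc & n.lev > 0))
    stop("continuous variables must not declare levels")
  if (any(meta$vclass == "allele_score" & disc))
    stop("allele-score variables must be continuous")
  invisible(meta)
}

is_discrete <- function(meta) meta$dtype == "discrete"

meta_levels <- function(meta, var) meta$levels[[match(var, meta$name)]]

#' Read and write variable metadata files
#'
#' Delimited text with columns `name`, `dtype`, `vclass`, `levels`;
#' the levels of a discrete variable are semicolon-joined in a single
#' field, empty for continuous variables.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return `read_meta()` returns a `mixbn_meta` table; `write_meta()`
#'   returns `path` invisibly.
#' @export
read_meta <- function(path, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = NULL)
  stopifnot(all(c("name", "dtype", "vclass", "levels") %in% names(raw)))
  levels <- lapply(raw$levels, function(s) {
    if (is.na(s) || !nzchar(s)) NULL else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  variable_meta(raw$name, raw$dtype, raw$vclass, levels)
}

#' @rdname read_meta
#' @param meta a `mixbn_meta` table.
#' @export
write_meta <- function(meta, path, sep = "\t") {
  validate_meta(meta)
  out <- data.frame(name = meta$name, dtype = meta$dtype, vclass = meta$vclass,
                    levels = vapply(meta$levels, function(l)
                      paste(l, collapse = ";"), character(1)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
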