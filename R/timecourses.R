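#' Component time courses for a single scan
#'
#' Container for the atomic input of the pipeline: a `T x C` matrix of
#' component (intrinsic connectivity network) activity for one resting-state
#' scan, together with the repetition time and optional component names.
#'
#' @param data numeric `T x C` matrix (rows = time points, columns =
#'   components); `T >= 2`, `C >= 2`, no missing values.
#' @param scan_id character scalar identifying the scan.
#' @param tr_seconds repetition time in seconds (default 2.2).
#' @param component_names optional character vector of length `C`; defaults to
#'   the column names of `data` or `IC001...`.
#' @return An object of class `component_tc` with fields `scan_id`, `data`,
#'   `tr_seconds`, `component_names`.
#' @examples
#' tc <- component_tc(matrix(rnorm(40), 20, 2), scan_id = "demo")
#' tc
#' @export
component_tc <- function(data, scan_id = "scan", tr_seconds = 2.2,
                         component_names = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L)
    stop("component_tc: need at least 2 time points, got ", nrow(data))
  if (ncol(data) < 2L)
    stop("component_tc: need at least 2 components, got ", ncol(data))
  if (anyNA(data) || any(!is.finite(data)))
    stop("component_tc: data contains missing or non-finite values")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("component_tc: tr_seconds must be a positive scalar")
  if (is.null(component_names)) {
    component_names <- colnames(data)
    if (is.null(component_names))
      component_names <- sprintf("IC%03d", seq_len(ncol(data)))
  }
  if (length(component_names) != ncol(data))
    stop("component_tc: component_names must have length C = ", ncol(data))
  colnames(data) <- component_names
  structure(
    list(scan_id = as.character(scan_id), data = data,
         tr_seconds = tr_seconds, component_names = component_names),
    class = "component_tc")
}

#' @export
print.component_tc <- function(x, ...) {
  cat(sprintf("Component time courses '%s': %d time points x %d components (TR = %g s)\n",
              x$scan_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' @export
dim.component_tc <- function(x) dim(x$data)

#' Read component time courses from delimited text
#'
#' Expects one file per scan: a header row of component names followed by
#' `T` rows by `C` columns of comma-separated values.  Malformed or
#' incomplete rows are reported with their line number.
#'
#' @param path path to a delimited text file.
#' @param tr_seconds repetition time in seconds.
#' @param scan_id scan identifier; defaults to the file name without
#'   extension.
#' @param sep field separator (default comma).
#' @return A [component_tc] object.
#' @export
load_timecourses <- function(path, tr_seconds = 2.2, scan_id = NULL,
                             sep = ",") {
  if (!file.exists(path)) stop("load_timecourses: file not found: ", path)
  if (is.null(scan_id))
    scan_id <- sub("\\.[^.]*$", "", basename(path))
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "numeric", fill = TRUE),
    error = function(e) stop("load_timecourses: cannot parse '", path, "': ",
                             conditionMessage(e)))
  m <- as.matrix(df)
  bad <- which(!stats::complete.cases(m) | apply(!is.finite(m), 1L, any))
  if (length(bad))
    stop("load_timecourses: missing/short values in '", path, "' at data line",
         if (length(bad) > 1L) "s" else "", " ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "),
         " (line 1 is the header)")
  component_tc(m, scan_id = scan_id, tr_seconds = tr_seconds)
}

#' Write component time courses as delimited text
#'
#' @param tc a [component_tc] object.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_timecourses <- function(tc, path, sep = ",") {
  stopifnot(inherits(tc, "component_tc"))
  utils::write.table(tc$data, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}
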