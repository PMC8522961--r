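#' Response tables
#'
#' The central data container: one row per replicate measurement of one
#' condition (a chemical or a mixture) at one concentration or dilution
#' level of one endpoint, on the normalised scale where the solvent
#' control averages 100%.
#'
#' @param x A data.frame with columns `chemical`, `endpoint`,
#'   `concentration`, `unit`, `replicate`, `value`. Extra columns (e.g.
#'   `role`, `feature`, `dilution_level`) are preserved.
#' @return `x`, validated, with class `response_table` prepended.
#' @export
response_table <- function(x) {
  required <- c("chemical", "endpoint", "concentration", "unit",
                "replicate", "value")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("response table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(x$value))) stop("non-finite response values")
  if (any(x$value < 0)) stop("negative response values (% of control)")
  if (any(x$concentration < 0)) stop("negative concentrations")
  class(x) <- unique(c("response_table", class(x)))
  x
}

#' @rdname response_table
#' @param path File path for CSV input/output.
#' @export
read_response_table <- function(path) {
  response_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname response_table
#' @export
write_response_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
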