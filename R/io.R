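#' Read a long-format cohort table
#'
#' Reads a delimited text file with one assessment per row.  Required
#' columns: `age` (months) and `score`; optional: `weight`, `group`,
#' `child_id`, `wave`.  The delimiter (comma or tab) is auto-detected from
#' the header line.
#'
#' @param path file path.
#' @return data.frame with validated columns.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- setdiff(c("age", "score"), names(d))
  if (length(need))
    stop("cohort file must have a header with columns 'age' and 'score'; ",
         "missing: ", paste(need, collapse = ", "), call. = FALSE)
  if (!is.numeric(d$age) || !is.numeric(d$score))
    stop("'age' and 'score' must be numeric", call. = FALSE)
  if ("weight" %in% names(d) &&
      (!is.numeric(d$weight) || any(d$weight <= 0, na.rm = TRUE)))
    stop("'weight' must be positive numeric", call. = FALSE)
  d
}

#' Serialize a fit summary to JSON
#'
#' Writes the dense-grid calculator model together with the fit criteria,
#' sufficient to reconstruct scoring exactly without the fitting code.
#'
#' @param fit an `lms_fit`.
#' @param path output path.
#' @param ... passed to [as_lms_model()].
#' @return the written path, invisibly.
#' @export
write_lms_fit <- function(fit, path, ...) {
  stopifnot(inherits(fit, "lms_fit"))
  write_lms_model(as_lms_model(fit, ...), path)
}
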