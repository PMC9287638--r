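# Classed conditions: validation errors (bad values, empty results) map to
# CLI exit code 1, format errors (unparseable input) to exit code 2.

validation_error <- function(msg, ..., class = character()) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "diffact_validation_error", "diffact_error")))
}

format_error <- function(msg, ..., class = character()) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "diffact_format_error", "diffact_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce any Matrix / base matrix to numeric column-compressed sparse form.
as_dgc <- function(m) {
  if (is.matrix(m)) m <- Matrix::Matrix(m, sparse = TRUE)
  m <- methods::as(m, "dMatrix")
  methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
}
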