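# Independent LP oracle: the same LP-SVM assembled from scratch in Python
# and solved with scipy's HiGHS backend. Used only to cross-check
# objectives; never as the implementation.

lp_oracle_objectives <- function(instances) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  stopifnot(nzchar(py))
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  payload <- lapply(instances, function(inst)
    list(K = inst$K, y = inst$y, yprime = inst$yprime %||% inst$y,
         theta = inst$theta, c = inst$c %||% 1))
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  status <- system2(py, c(test_path("lpsvm-oracle.py"), infile, outfile))
  stopifnot(status == 0L)
  res <- jsonlite::fromJSON(outfile)
  res$objective
}

`%||%` <- function(a, b) if (is.null(a)) b else a
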