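# internal helpers shared across modules

# run expr under an explicit seed without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTSV <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

checkCount <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != floor(x)) {
    stop("'", name, "' must be a single integer >= ", min,
         " (got ", deparse(substitute(x)), " = ", format(x), ")")
  }
  as.integer(x)
}

checkFraction <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop("'", name, "' must be a single value in [0, 1]")
  }
  as.numeric(x)
}
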