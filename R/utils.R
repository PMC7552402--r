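# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(
    class = c("spliceflip_invalid_parameter", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# Truncated normal via inverse CDF so the number of RNG draws is fixed
# (keeps seeded streams aligned regardless of acceptance region).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

# Tab-separated I/O: one header line, no quoting, fixed number formatting
# so repeated runs are byte-identical.
write_tsv <- function(x, path) {
  x <- as.data.table(x)
  if (ncol(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  data.table::fwrite(x, path, sep = "\t", quote = FALSE,
                     na = "NA", logical01 = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                    data.table = TRUE)
}

# Junction key string used in column names and reports: chrom:start-end.
junction_key <- function(chrom, intron_start, intron_end) {
  sprintf("%s:%d-%d", chrom, as.integer(intron_start), as.integer(intron_end))
}
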