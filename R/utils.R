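# Run code under a temporary RNG seed (restoring the caller's RNG state),
# or as-is when seed is NULL.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code)
  else withr::with_seed(as.integer(seed), code)
}

# Deterministically derive named sub-seeds from one root seed, so each
# pipeline stage has its own reproducible stream regardless of order.
derive_seeds <- function(seed, labels) {
  withr::with_seed(as.integer(seed), {
    s <- sample.int(.Machine$integer.max - 1L, length(labels))
  })
  stats::setNames(as.list(s), labels)
}

#' Write a table as TSV with a commented metadata header
#'
#' Output tables carry `#`-prefixed header lines recording the package
#' version, the root seed and a hash of the configuration, so any table can
#' be traced back to the run that produced it. Floats are written in full
#' precision.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config Optional `lac_config` whose hash is recorded.
#' @param seed Optional root seed to record.
#' @param extra Optional named character vector of extra header fields.
#' @return `path`, invisibly.
#' @export
write_lac_tsv <- function(df, path, config = NULL, seed = NULL,
                          extra = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# lacdfe ",
                    as.character(utils::packageVersion("lacdfe"))), con)
  if (!is.null(config)) {
    writeLines(paste0("# config_hash: ", rlang::hash(unclass(config))), con)
  }
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  if (!is.null(extra)) {
    writeLines(paste0("# ", names(extra), ": ", extra), con)
  }
  utils::write.table(format_full(df), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

format_full <- function(df) {
  as.data.frame(lapply(df, function(x) {
    if (is.double(x)) format(x, digits = 17, trim = TRUE, scientific = NA)
    else x
  }), check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a TSV written by [write_lac_tsv()]
#'
#' @param path Path to the TSV.
#' @return A tibble (comment header lines are skipped).
#' @export
read_lac_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                      check.names = FALSE))
}
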