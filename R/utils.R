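# Shared small helpers: TSV IO and argument checks.

#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used by all
#' package inputs: header row, tab separator, no factor coercion, names kept
#' as-is.
#'
#' @param path Path to a TSV file.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a tab-separated table
#'
#' @param x A data.frame or matrix. Matrices are written with a leading id
#'   column holding the row names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv_table <- function(x, path) {
  if (is.matrix(x)) {
    x <- data.frame(id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# stop() without the call, used for user-facing argument errors
.fail <- function(...) stop(..., call. = FALSE)

.check_count <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x)) {
    .fail("`", name, "` must be a single positive integer")
  }
  as.integer(x)
}

.check_fraction <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    .fail("`", name, "` must be a single value in [0, 1]")
  }
  as.numeric(x)
}

# Run `expr` under a fixed RNG seed when `seed` is non-NULL, otherwise use
# the current RNG stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
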