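#' @importFrom stats prcomp p.adjust pnorm wilcox.test t.test rnbinom rnorm
#'   runif lm coef setNames sd var median quantile rlnorm aggregate rpois
#' @importFrom utils head tail
#' @import data.table
NULL

utils::globalVariables(c(".", "tool", "gene5", "gene3", "n_tools", "key",
                         "pos5", "pos3", "supporting_tools"))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic TSV writer
#'
#' Thin wrapper around [data.table::fwrite()] with fixed options so repeated
#' runs produce byte-identical files (fixed eol, full numeric precision,
#' no scientific notation drift).
#'
#' @param x data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(as.data.table(x), path, sep = "\t", quote = FALSE,
                     eol = "\n", scipen = 50L, na = "NA")
  invisible(path)
}

#' Read a TSV with header
#'
#' @param path file path.
#' @return data.table.
#' @export
read_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
}

## counts-per-million on a gene x sample matrix
cpm <- function(mat) {
  libs <- colSums(mat)
  libs[libs == 0] <- 1
  sweep(mat, 2, libs, "/") * 1e6
}

## library-size normalized counts kept on the count scale:
## divide each column by its size factor (library size / mean library size)
normalize_counts <- function(mat) {
  libs <- colSums(mat)
  sf <- libs / mean(libs[libs > 0])
  sf[sf == 0] <- 1
  sweep(mat, 2, sf, "/")
}

## per-row z-score; zero-variance rows map to 0
row_standardize <- function(mat) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  out <- sweep(mat, 1, mu, "-")
  nz <- s > 0
  out[nz, ] <- sweep(out[nz, , drop = FALSE], 1, s[nz], "/")
  out[!nz, ] <- 0
  out
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

## seed handling: all generators take an integer seed and restore the RNG
## state of the caller on exit
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
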