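#' Derive a child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed so that stages are individually reproducible and the full run is
#' bit-identical under the same master seed.
#'
#' @param master integer master seed.
#' @param k integer stage index (>= 0).
#' @return an integer seed below 2^31.
#' @export
child_seed <- function(master, k) {
  as.integer((as.double(master) * 48271 + 1000003 * as.double(k)) %% 2147483629)
}

# stderr logger used across the pipeline; optionally tees to a file
mmra_log <- function(..., file = NULL) {
  msg <- sprintf("[mmra %s] %s", format(Sys.time(), "%H:%M:%S"),
                 paste0(..., collapse = ""))
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE)
  invisible(msg)
}

# linear-interpolation percentile (type 7), the package-wide definition
pctl <- function(x, p) unname(stats::quantile(x, p / 100, type = 7, names = FALSE))

`%||%` <- function(a, b) if (is.null(a)) b else a
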