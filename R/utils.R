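#' @importFrom rlang %||% .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib lipidsites, .registration = TRUE
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# center of geometry of rows of an n x 3 matrix
cog <- function(xyz) {
  if (is.null(dim(xyz))) return(xyz)
  colMeans(xyz)
}

# deterministic child seeds derived from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483629L
}
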