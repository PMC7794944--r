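# Uniform-LBP bin for 8-bit patterns given as an (N x 8) logical matrix:
# patterns with at most 2 circular transitions map to bins 1..9 by their
# number of set bits; all others share bin 10.
uniform_lbp_bins <- function(bits) {
  trans <- rowSums(bits != bits[, c(2:8, 1), drop = FALSE])
  ones <- rowSums(bits)
  ifelse(trans <= 2, ones + 1L, 10L)
}

#' One-dimensional local ternary pattern histogram (20)
#'
#' For every sample with 4 neighbours on each side, the 8 neighbours are
#' compared against the centre value plus/minus the ternary threshold `t`:
#' neighbours above centre + t set bits of the upper pattern, neighbours
#' below centre - t set bits of the lower pattern. Each 8-bit pattern is
#' mapped to the 10-bin uniform-LBP histogram (9 uniform classes by number
#' of set bits, one catch-all non-uniform bin); the feature vector is the
#' upper histogram followed by the lower one. Counts are unnormalised, so
#' each histogram sums to N - 8.
#'
#' @param x numeric signal.
#' @param t ternary threshold.
#' @return named numeric vector of length 20.
#' @export
ltp_features <- function(x, t = 0.01) {
  n <- length(x)
  if (n < 9) stop("need at least 9 samples", call. = FALSE)
  centre_idx <- 5:(n - 4)
  centre <- x[centre_idx]
  offs <- c(-4:-1, 1:4)
  nb <- vapply(offs, function(o) x[centre_idx + o],
               numeric(length(centre_idx)))
  if (!is.matrix(nb)) nb <- matrix(nb, nrow = 1L)
  upper <- nb > centre + t
  lower <- nb < centre - t
  hist10 <- function(bins) tabulate(bins, nbins = 10L)
  v <- c(hist10(uniform_lbp_bins(upper)), hist10(uniform_lbp_bins(lower)))
  names(v) <- paste(ordinal(1:20), "Coefficient of LTP")
  v
}
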