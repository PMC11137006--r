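#' Sample oncoprotein expression levels
#'
#' Draws i.i.d. oncoprotein values from a normal distribution restricted to a
#' bounded support by rejection sampling (truncation by resampling, not
#' clipping, so no probability atoms appear at the support ends).  With the
#' default mean 1, sd 0.25 and support \[0, 2\] the truncation sits at
#' +/- 4 sd and distorts the moments negligibly.
#'
#' @param n number of draws.
#' @param mean,sd moments of the parent normal.
#' @param lower,upper support bounds.
#' @return Numeric vector of length `n`, all values inside `[lower, upper]`.
#' @examples
#' set.seed(1)
#' mean(sample_oncoprotein(1e4))
#' @export
sample_oncoprotein <- function(n, mean = 1, sd = 0.25, lower = 0, upper = 2) {
  stopifnot(n >= 1, lower < upper)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(n - length(out) + 16L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Discretise oncoprotein expression into cell types
#'
#' Type 1: 1.5 <= o < 2.0 (most mutated, fastest cycling, most immunogenic);
#' Type 2: 1.0 <= o < 1.5; Type 3: 0.5 <= o < 1.0; Type 4: 0.0 <= o < 0.5
#' (below the recognition threshold, cannot be killed in antigen-specific
#' mode).  The measure-zero upper end o = 2 is assigned to Type 1.
#'
#' @param o oncoprotein values in \[0, 2\].
#' @return Integer vector of type labels in 1..4.
#' @export
classify_type <- function(o) {
  if (any(o < 0 | o > 2)) {
    abort("oncoprotein values must lie in [0, 2]")
  }
  ifelse(o >= 1.5, 1L, ifelse(o >= 1.0, 2L, ifelse(o >= 0.5, 3L, 4L)))
}

#' Immunogenicity of a cancer cell
#'
#' The multiplier on a CAR T-cell's per-attempt kill probability.  In
#' antigen-specific mode it is proportional to the oncoprotein expression
#' above the recognition threshold and zero below it (such cells cannot be
#' recognised).  In multi-antigen (syn-Notch-like) mode every cancer cell is
#' an equally valid target and the multiplier is 1 regardless of expression.
#'
#' @param o oncoprotein values in \[0, 2\].
#' @param mode `"antigen_specific"` or `"multi_antigen"`.
#' @param threshold recognition threshold (antigen-specific mode).
#' @return Numeric vector of multipliers in \[0, 2\].
#' @export
immunogenicity <- function(o, mode = c("antigen_specific", "multi_antigen"),
                           threshold = 0.5) {
  mode <- match.arg(mode)
  stopifnot(all(o >= 0 & o <= 2))
  if (mode == "multi_antigen") {
    return(rep(1, length(o)))
  }
  ifelse(o < threshold, 0, o)
}
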