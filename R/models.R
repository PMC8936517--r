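#' Four-parameter log-logistic viability
#'
#' Standard LL4 concentration-response model on the natural concentration
#' scale: `V(x) = c + (d - c) / (1 + exp(b * (log(x) - log(e))))` where `d` is
#' the upper asymptote (untreated viability, %), `c` the lower asymptote,
#' `b > 0` the Hill slope and `e` the midpoint concentration in nM (the IC50
#' when `d = 100`, `c = 0`). With `b > 0` viability decreases with dose.
#'
#' @param conc concentration(s) in nM, strictly positive.
#' @param b Hill slope (> 0 for a decreasing curve).
#' @param c lower asymptote (% viability).
#' @param d upper asymptote (% viability).
#' @param e midpoint concentration (nM).
#' @return viability in percent, same length as `conc`.
#' @export
ll4_viability <- function(conc, b, c, d, e) {
  c + (d - c) / (1 + exp(b * (log(conc) - log(e))))
}

#' Logistic viability on the log10-concentration axis
#'
#' Fallback model used when the LL4 fit fails to converge: the same sigmoid
#' with the transformed dose `u = log10(conc)` entering linearly and the
#' midpoint `m` expressed in log10 nM.
#'
#' @param conc concentration(s) in nM.
#' @param b slope on the log10 axis.
#' @param c,d lower/upper asymptotes (% viability).
#' @param m midpoint in log10 nM.
#' @return viability in percent.
#' @export
l4_viability <- function(conc, b, c, d, m) {
  c + (d - c) / (1 + exp(b * (log10(conc) - m)))
}

#' Ground-truth Hill viability for simulated drugs
#'
#' `viability(x) = bottom + (top - bottom) / (1 + (x / ic50)^slope)`; the same
#' family the fitting stage estimates, parameterized by IC50 so that
#' `viability(ic50) = (top + bottom) / 2`.
#'
#' @param conc concentration(s) in nM.
#' @param ic50 midpoint concentration in nM (> 0).
#' @param slope Hill slope (> 0).
#' @param top,bottom asymptotic viabilities in percent, `top > bottom`.
#' @return viability in percent.
#' @export
hill_viability <- function(conc, ic50, slope = 1, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + (conc / ic50)^slope)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
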