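# Independent oracles used to freeze expected values. These deliberately do
# not call the closed-form code paths they check.

# Root of the single-unit mass balance VI F/(1-F) = lambda Q (Fv - F) by
# plain interval bisection on (0, Fv).
oracle_fa_bisect <- function(lambda, Q, VI, Fv, iters = 200L) {
  if (Fv == 0) return(0)
  g <- function(F) VI * F / (1 - F) - lambda * Q * (Fv - F)
  lo <- 0
  hi <- Fv
  for (i in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  0.5 * (lo + hi)
}

# Homogeneous-lung venous N2O fraction producing a given whole-lung
# elimination rate: FA follows from VI FA/(1-FA) = target, then the venous
# fraction from the blood-side balance.
oracle_fv_homogeneous <- function(target, lambda = 0.47, VI = 4, Q = 5) {
  FA <- target / (VI + target)
  FA + target / (lambda * Q)
}

# Perfusion-weighted mean and SD helpers for lung checks.
wmean <- function(w, v) sum(w * v) / sum(w)
wsd <- function(w, v) sqrt(wmean(w, (v - wmean(w, v))^2))
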