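# Independent numerical oracles for the vergence engine.
#
# These deliberately avoid the package's closed forms: the forward trace
# propagates vergences surface by surface and finds the spectacle refraction
# by root-finding; the back-calculation oracle bisects on corneal power using
# that trace. Agreement between the closed forms and these oracles is the
# correctness contract for the optics.

# spectacle refraction by stepwise vergence propagation + uniroot
oracle_predict_refraction <- function(k, iol_power, axial_length, elp, cst) {
  n <- cst$n_aqueous
  dx <- cst$vertex_distance / 1000
  L <- axial_length / 1000
  d <- elp / 1000
  residual <- function(rx) {
    rc <- rx / (1 - rx * dx)          # refraction moved to the corneal plane
    v1 <- rc + k                      # vergence leaving the cornea
    v2 <- v1 / (1 - (d / n) * v1)     # reduced transfer cornea -> IOL
    v3 <- v2 + iol_power              # vergence leaving the IOL
    v3 - n / (L - d)                  # zero when focused on the retina
  }
  # bracket wide enough for K in [25, 60] over the sampled biometry, but
  # short of the vertex-distance singularity at rx = 1000/dx_mm (= +83 D)
  stats::uniroot(residual, c(-80, 45), tol = 1e-12)$root
}

# corneal power explaining an observed SE, by bisection on the trace
oracle_back_calculated_k <- function(postop_se, iol_power, axial_length, elp,
                                     cst, lower = 25, upper = 60) {
  f <- function(k) {
    oracle_predict_refraction(k, iol_power, axial_length, elp, cst) - postop_se
  }
  lo <- lower; hi <- upper
  flo <- f(lo); fhi <- f(hi)
  stopifnot(sign(flo) != sign(fhi))
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# IOL power for a target by successively refined grid search (final step 1e-7)
oracle_iol_power_grid <- function(k, target_se, axial_length, elp, cst,
                                  lower = -10, upper = 40) {
  grid_best <- function(lo, hi, by) {
    p <- seq(lo, hi, by = by)
    err <- abs(predict_refraction(k, p, axial_length, elp, cst) - target_se)
    p[which.min(err)]
  }
  best <- grid_best(lower, upper, 0.01)
  best <- grid_best(best - 0.02, best + 0.02, 1e-4)
  grid_best(best - 2e-4, best + 2e-4, 1e-7)
}

# sampler of random valid optical states under the caller's RNG stream
sample_states <- function(n) {
  data.frame(
    axial_length = runif(n, 22, 32),
    acd = runif(n, 2.9, 4.2),
    k = runif(n, 30, 50),
    target = runif(n, -3, 1)
  )
}

test_constants <- function(vertex_distance = 12) {
  iol_constants(a0 = 1.513, a1 = 0.4, a2 = 0.1,
                vertex_distance = vertex_distance, label = "test")
}
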