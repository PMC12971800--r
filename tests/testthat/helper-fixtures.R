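# Shared fixtures: small, fast phantom specs and a brute-force Cox oracle.

# compact circular phantom for geometry-exact checks
disk_spec <- function(r = 150, sat = 20, pixel = 1, img = 384L, noise = 0,
                      seed = 1L, ...) {
  args <- list(image_size = c(img, img), pixel_spacing = c(pixel, pixel),
               body_center_mm = c(0, -8), body_semiaxes_mm = c(r, r),
               sat_ring_thickness = sat, sat_ring_perturb = 0,
               visceral_fat_fraction = 0, n_fat_blobs = 0,
               organ_blobs = list(), hu_noise_sd = noise,
               include_table = FALSE, seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# small fast default-style phantom
small_spec <- function(seed = 1L, ...) {
  args <- list(image_size = c(160L, 160L), pixel_spacing = c(2.2, 2.2),
               body_center_mm = c(0, -15), body_semiaxes_mm = c(120, 82),
               sat_ring_thickness = 20, muscle_ring_thickness = 10,
               seed = seed)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# Breslow partial log-likelihood for a single binary covariate, written
# directly from the definition: the independent oracle for cox_fit.
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[d]) - length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

brute_force_cox <- function(time, event, x, lower = -8, upper = 8) {
  opt <- stats::optimize(function(b) -breslow_loglik(b, time, event, x),
                         c(lower, upper), tol = 1e-9)
  opt$minimum
}

# run expr under a seed without touching the session RNG state
with_seed_helper <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
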