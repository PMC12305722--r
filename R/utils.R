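# Internal helpers: seeding, deterministic RNG scoping, small numerics.

# Deterministic integer fold of a sequence of integer-valued inputs into a
# seed below 2^31.  Multiplier 69069 (classic LCG) keeps every intermediate
# product below 2^53, so the arithmetic is exact in doubles.
.hashSeed <- function(...) {
  vals <- c(...)
  h <- 0
  for (v in vals) {
    iv <- round(v) %% 2147483647
    h <- (h * 69069 + iv + 1) %% 2147483647
  }
  as.integer(h)
}

# Seed for the speckle field of the pose at (x, pitch, roll): derived from
# the global seed and the pose's position on the actuator lattice (0.01 mm
# stepper quantum, 0.01 deg angular quantum), so an image is reproducible
# regardless of the order in which poses are visited.
.poseSeed <- function(globalSeed, x, pitch, roll) {
  .hashSeed(globalSeed, round(x * 100), round(pitch * 100), round(roll * 100))
}

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Unit-mean Rayleigh deviates (first-order fully developed speckle model).
# Rayleigh(sigma) has mean sigma * sqrt(pi/2); sigma = sqrt(2/pi) gives mean 1.
.rrayleighUnit <- function(n) {
  sqrt(-(4 / pi) * log(stats::runif(n)))
}

.isScalar <- function(x) length(x) == 1L && is.finite(x)

# seq() by a possibly non-integer step without accumulating FP drift.
.seqStep <- function(from, to, by) {
  n <- floor((to - from) / by + 1e-9)
  from + by * (0:max(n, 0))
}
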