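# Unit conversions and small shared utilities.
#
# Internal computations run in SI (Pa, m, m^3/s); user-facing values are in
# the clinical units of the field: mmHg, cm, mL/s, mmHg.s/mL, mL/mmHg.

MMHG_PA <- 133.322          # 1 mmHg in Pa
ML_M3   <- 1e-6             # 1 mL in m^3
CM_M    <- 1e-2             # 1 cm in m
# 1 mmHg.s/mL in Pa.s/m^3
RES_SI  <- MMHG_PA / ML_M3

mmHg_to_Pa <- function(x) x * MMHG_PA
Pa_to_mmHg <- function(x) x / MMHG_PA
mls_to_m3s <- function(x) x * ML_M3
m3s_to_mls <- function(x) x / ML_M3

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching how clinical
#' tables print percentages (e.g. 7.875\% prints as 7.9\%). Base
#' \code{round()} rounds ties to even, which would disagree with such tables
#' at exact midpoints.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# structured condition helpers: validation (bad inputs), convergence
# (iterative solver failures), io (file-format problems)
fd_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "fd_error")))
}
fd_validation_error  <- function(msg, ...) fd_stop(msg, "fd_validation_error", ...)
fd_convergence_error <- function(msg, ...) fd_stop(msg, "fd_convergence_error", ...)
fd_io_error          <- function(msg, ...) fd_stop(msg, "fd_io_error", ...)

# evaluate expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# trapezoidal integral of y(x) on the given samples
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) fd_validation_error("need at least 2 samples for integration")
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
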