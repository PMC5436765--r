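# Mass-action right-hand side and local stability analysis.

#' Mass-action time derivatives of all species
#'
#' Hand-derived per-species balance equations of the 25-step network, e.g.
#' \deqn{d[CTS]/dt = k_8[DCTS] - k_9[CTS] + k_{14}[DCTS][CTS]^2 -
#'   k_{15}[ALDO][CTS]^2 - k_{16}[CRH][CTS] - k_{17}[ACTH][CTS] -
#'   k_{21}[CTS]}
#' \deqn{d[CORT]/dt = k_{13}[HPGS] - k_{23}[CORT]}
#' The CRH balance is `k2 * circadian_factor - k16[CRH][CTS] - k19[CRH]`:
#' the ACTH-production step R4 leaves CRH unchanged (catalytic action), so
#' `k4` appears only in the ACTH balance.
#'
#' Every negative term in a species' balance carries that species'
#' concentration as a factor, so the nonnegative orthant is forward
#' invariant.
#'
#' @param state Named nonnegative concentration vector over
#'   [hpa_species()] (M).
#' @param k Rate constants, as from [hpa_rate_constants()].
#' @param circadian_factor Positive dimensionless value of the circadian
#'   drive (possibly scaled by a stress multiplier) at the current time.
#' @return Named vector of time derivatives (M min^-1).
#' @export
mass_action_rhs <- function(state, k = hpa_rate_constants(),
                            circadian_factor = 1) {
  if (length(state) != 11L)
    stop("state must have 11 species, got ", length(state))
  if (length(k) != 25L)
    stop("k must have 25 rate constants, got ", length(k))
  if (any(state < 0)) stop("negative concentration in state")
  if (circadian_factor <= 0) stop("circadian_factor must be > 0")
  if (!is.null(names(state))) state <- state[hpa_species()]
  CHOL <- state[[1]]; CRH <- state[[2]]; ALDO <- state[[3]]
  ACTH <- state[[4]]; PNN <- state[[5]]; PGS <- state[[6]]
  DCTS <- state[[7]]; CTS <- state[[8]]; HPNN <- state[[9]]
  HPGS <- state[[10]]; CORT <- state[[11]]
  d <- c(
    CHOL = k[[1]] - k[[5]] * ACTH * CHOL - k[[18]] * CHOL,
    CRH  = k[[2]] * circadian_factor - k[[16]] * CRH * CTS - k[[19]] * CRH,
    ALDO = k[[3]] + k[[9]] * CTS - k[[15]] * ALDO * CTS^2 - k[[22]] * ALDO,
    ACTH = k[[4]] * CRH - k[[5]] * ACTH * CHOL - k[[17]] * ACTH * CTS -
           k[[20]] * ACTH,
    PNN  = k[[5]] * ACTH * CHOL - (k[[6]] + k[[11]] + k[[24]]) * PNN,
    PGS  = k[[6]] * PNN - (k[[7]] + k[[10]] + k[[25]]) * PGS,
    DCTS = k[[7]] * PGS - k[[8]] * DCTS - k[[14]] * DCTS * CTS^2,
    CTS  = k[[8]] * DCTS - k[[9]] * CTS + k[[14]] * DCTS * CTS^2 -
           k[[15]] * ALDO * CTS^2 - k[[16]] * CRH * CTS -
           k[[17]] * ACTH * CTS - k[[21]] * CTS,
    HPNN = k[[11]] * PNN - k[[12]] * HPNN,
    HPGS = k[[10]] * PGS + k[[12]] * HPNN - k[[13]] * HPGS,
    CORT = k[[13]] * HPGS - k[[23]] * CORT)
  d
}

# Finite-difference Jacobian of the RHS at `state` (linear scale).
rhs_jacobian <- function(state, k = hpa_rate_constants(),
                         circadian_factor = 1) {
  f0 <- mass_action_rhs(state, k, circadian_factor)
  n <- length(state)
  J <- matrix(0, n, n, dimnames = list(hpa_species(), hpa_species()))
  for (j in seq_len(n)) {
    h <- max(1e-7 * abs(state[[j]]), 1e-18)
    sp <- state; sp[[j]] <- sp[[j]] + h
    J[, j] <- (mass_action_rhs(sp, k, circadian_factor) - f0) / h
  }
  J
}

#' Fixed point and local stability under frozen forcing
#'
#' Finds a steady state of the mass-action system with the circadian drive
#' frozen at a constant value, by damped Newton iteration on
#' log-concentrations (which keeps iterates positive across the twelve
#' orders of magnitude spanned by the species). The local linearization at
#' the root is obtained by finite differences and its eigenvalue spectrum
#' returned; with the default constants and the period-mean drive the
#' spectrum contains a complex pair with positive real part (an unstable
#' focus), the signature of sustained ultradian oscillation.
#'
#' @param k Rate constants.
#' @param frozen_D Positive frozen value of the circadian drive (default:
#'   its mean over one period).
#' @param guess Positive starting state (default [hpa_initial_state()]).
#' @param tol Convergence threshold on the maximum absolute residual
#'   (M min^-1).
#' @param max_iter Iteration cap.
#' @return List with `state` (the steady state), `residual` (max abs RHS),
#'   `eigenvalues` (complex spectrum of the linearization), `jacobian`, and
#'   `iterations`.
#' @export
hpa_fixed_point <- function(k = hpa_rate_constants(),
                            frozen_D = mean_circadian_drive(),
                            guess = hpa_initial_state(),
                            tol = 1e-18, max_iter = 400) {
  stopifnot(frozen_D > 0, all(guess > 0))
  g <- function(x) mass_action_rhs(exp(x), k, frozen_D)
  x <- log(unname(guess[hpa_species()]))
  fv <- g(x)
  it <- 0L
  while (max(abs(fv)) > tol && it < max_iter) {
    it <- it + 1L
    J <- matrix(0, 11, 11)
    for (j in 1:11) {
      h <- 1e-7
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (g(xp) - fv) / h
    }
    dx <- tryCatch(solve(J, -fv), error = function(e) NULL)
    if (is.null(dx)) stop("singular Jacobian in Newton iteration")
    lam <- 1
    repeat {
      xn <- x + lam * dx
      if (sum(g(xn)^2) < sum(fv^2) || lam < 1e-8) break
      lam <- lam / 2
    }
    x <- xn
    fv <- g(x)
  }
  if (max(abs(fv)) > tol)
    stop(sprintf("fixed-point iteration did not converge: residual %.3e",
                 max(abs(fv))))
  ss <- exp(x)
  names(ss) <- hpa_species()
  J <- rhs_jacobian(ss, k, frozen_D)
  list(state = ss, residual = max(abs(fv)),
       eigenvalues = eigen(J, only.values = TRUE)$values,
       jacobian = J, iterations = it)
}
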