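## Shared binding math: competitive 1:1 calcium equilibria under the
## rapid-buffering approximation, the indicator saturation law, and the
## Hill-type assembly propensity.

## Diffusion coefficient of free Ca2+ (um^2/s); free calcium is not a
## BindingSpecies so its transport constant lives here.
.D_FREE_CA <- 400

#' Solve a competitive calcium-binding equilibrium
#'
#' Finds the free calcium concentration \eqn{f} satisfying the scalar mass
#' balance \eqn{T = f + \sum_i B_i f / (K_i + f)} for a panel of independent
#' 1:1 binding species with totals \eqn{B_i} and dissociation constants
#' \eqn{K_i}, then reports the bound amount of each species. The residual is
#' strictly monotone in \eqn{f}, so a bracketed root solve on
#' \eqn{[0, T]} is guaranteed to converge.
#'
#' @param panel a \linkS4class{ReagentPanel}.
#' @param tol absolute tolerance on free calcium (uM).
#' @return an \linkS4class{EquilibriumState}.
#' @examples
#' p <- ReagentPanel(list(BindingSpecies("chelator", 500, 3000)), 600)
#' solveCompetitiveEquilibrium(p)
#' @export
solveCompetitiveEquilibrium <- function(panel, tol = 1e-12) {
  stopifnot(is(panel, "ReagentPanel"))
  validObject(panel)
  total <- panel@totalCalcium
  nm <- speciesNames(panel)
  if (length(panel@species) == 0L || total == 0) {
    bound <- setNames(numeric(length(nm)), nm)
    return(new("EquilibriumState", freeCa = total, bound = bound))
  }
  B <- vapply(panel@species, function(s) s@total, numeric(1))
  K <- vapply(panel@species, function(s) s@kd, numeric(1))
  f <- solveFreeCa(total, B, K, tol = tol)
  bound <- setNames(B * f / (K + f), nm)
  ## mass-balance audit: unreachable for a monotone residual, kept as a guard
  if (abs(f + sum(bound) - total) > 1e-10 * max(total, 1))
    stop("equilibrium solver failed to satisfy mass balance")
  new("EquilibriumState", freeCa = f, bound = bound)
}

#' Vectorised free-calcium solve
#'
#' Solves the same mass balance as \code{\link{solveCompetitiveEquilibrium}}
#' for vectors of pixel totals. Used pixelwise by the simulator; exported for
#' testing and for building custom equilibration steps.
#'
#' @param total vector of total calcium (uM).
#' @param B matrix (length(total) x nSpecies) or vector of species totals (uM).
#' @param K vector of dissociation constants (uM).
#' @param tol absolute tolerance (uM).
#' @return vector of free calcium, same length as \code{total}.
#' @export
solveFreeCa <- function(total, B, K, tol = 1e-12) {
  n <- length(total)
  if (is.null(dim(B))) B <- matrix(B, nrow = n, ncol = length(B), byrow = TRUE)
  stopifnot(ncol(B) == length(K), nrow(B) == n, all(K > 0), all(total >= -1e-9),
            all(B >= -1e-9))
  total <- pmax(total, 0)
  solve_free_ca_cpp(as.numeric(total), B, as.numeric(K), as.numeric(tol))
}

#' Saturation-law indicator response
#'
#' \code{y = a * x / (b + x)}: monotone increasing in the free calcium
#' \code{x}, bounded above by the saturation level \code{a}, with
#' half-saturation at \code{x = b}.
#'
#' @param freeCa free calcium (uM, >= 0); vectorised.
#' @param curve a \linkS4class{SaturationCurve}.
#' @return intensity above camera offset, same shape as \code{freeCa}.
#' @export
saturationResponse <- function(freeCa, curve) {
  stopifnot(is(curve, "SaturationCurve"))
  if (any(freeCa < 0, na.rm = TRUE))
    stop("'freeCa' must be >= 0")
  curve@a * freeCa / (curve@b + freeCa)
}

#' Invert the saturation law
#'
#' Recovers free calcium from an offset-subtracted intensity:
#' \code{x = b * I / (a - I)}. Intensities at or above the saturation level
#' cannot be inverted; they are returned as \code{NA} (saturated) with a
#' warning unless \code{onSaturated = "error"}.
#'
#' @param intensity offset-subtracted intensity; vectorised. Values in
#'   \code{[0, a)} invert exactly; small negative values (noise) are clipped
#'   to 0.
#' @param curve a \linkS4class{SaturationCurve}.
#' @param onSaturated "na" (default) marks saturated pixels NA; "error" stops.
#' @return free calcium (uM), same shape as \code{intensity}.
#' @export
invertSaturation <- function(intensity, curve, onSaturated = c("na", "error")) {
  stopifnot(is(curve, "SaturationCurve"))
  onSaturated <- match.arg(onSaturated)
  sat <- !is.na(intensity) & intensity >= curve@a
  if (any(sat)) {
    if (onSaturated == "error")
      stop(sum(sat), " intensity value(s) at or above the saturation level")
    warning(sum(sat), " saturated value(s) marked NA")
  }
  x <- pmax(intensity, 0)
  out <- curve@b * x / (curve@a - x)
  out[sat] <- NA_real_
  out
}

#' Hill-type response
#'
#' \code{y = x^N / (K^N + x^N)}, evaluated in the log domain so that very
#' large exponents (sharp, switch-like transitions) remain numerically stable.
#'
#' @param x input (uM, >= 0); vectorised.
#' @param model a \linkS4class{HillModel}.
#' @return response fraction in [0, 1].
#' @export
hillResponse <- function(x, model) {
  stopifnot(is(model, "HillModel"))
  if (any(x < 0, na.rm = TRUE)) stop("'x' must be >= 0")
  out <- x # keeps shape/dimnames
  pos <- !is.na(x) & x > 0
  ## 1 / (1 + exp(-N * (log x - log K))) == x^N / (K^N + x^N)
  out[pos] <- stats::plogis(model@nHill * (log(x[pos]) - log(model@kHalf)))
  out[!is.na(x) & x == 0] <- 0
  out
}

## Derivative of total bound calcium with respect to free calcium, summed
## over species: sum_i B_i K_i / (K_i + f)^2. Used by the buffer-corrected
## bound-protein estimator.
.bufferingSlope <- function(f, B, K) {
  out <- 0
  for (j in seq_along(K)) out <- out + B[j] * K[j] / (K[j] + f)^2
  out
}
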