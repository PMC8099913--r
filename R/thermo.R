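## Closed-form two-state unfolding thermodynamics coupled to 1:1 ligand
## binding. These are the shared primitives behind curve fitting, isothermal
## analysis and simulation. All temperatures here are Kelvin; all energies
## kcal/mol; all concentrations molar.

#' Gibbs energy of unfolding at a temperature
#'
#' Two-state unfolding free energy
#' \deqn{\Delta G_U(T) = \Delta H_{Tm} + \Delta C_p (T - T_m)
#'       - T\left(\Delta S_{Tm} + \Delta C_p \ln(T/T_m)\right)}
#' with the entropy at the midpoint fixed by the two-state condition
#' \eqn{\Delta S_{Tm} = \Delta H_{Tm}/T_m}, so that \eqn{\Delta G_U(T_m) = 0}
#' for any heat-capacity change.
#'
#' @param T temperature (K); vectorized.
#' @param Tm melting temperature (K), where half the protein is unfolded.
#' @param dH unfolding enthalpy at `Tm` (kcal/mol); must be positive.
#' @param dCp heat-capacity change upon unfolding (kcal/(mol K)); default 0.
#' @return \eqn{\Delta G_U(T)} in kcal/mol.
#' @seealso [apparentKu()], [fractionUnfolded()]
#' @examples
#' dGUnfolding(313.15, Tm = 323.15, dH = 100)      # dCp = 0 closed form
#' dGUnfolding(323.15, Tm = 323.15, dH = 100, 5)   # zero at Tm
#' @export
dGUnfolding <- function(T, Tm, dH, dCp = 0) {
    if (any(!is.finite(T)) || any(T <= 0)) stop("'T' must be positive (Kelvin)")
    .assertScalarNumeric(Tm, "Tm", positive = TRUE)
    .assertScalarNumeric(dH, "dH", positive = TRUE)
    .assertScalarNumeric(dCp, "dCp")
    ## grouped so that every term vanishes identically at T = Tm
    dH * (1 - T / Tm) + dCp * ((T - Tm) - T * log(T / Tm))
}

#' Total Gibbs energy of unfolding in the presence of free ligand
#'
#' Adds the ligand-dissociation penalty to the unfolding free energy:
#' \deqn{\Delta G(T) = \Delta G_U(T) + RT \ln(1 + [L]_{free}/K_d).}
#' The ligand binds only the folded state, so any free ligand raises the
#' apparent stability; equality with [dGUnfolding()] holds iff
#' `Lfree = 0`.
#'
#' @inheritParams dGUnfolding
#' @param Lfree free (unbound) ligand concentration (M); non-negative.
#' @param Kd dissociation constant of the folded-protein--ligand complex (M).
#' @return Total \eqn{\Delta G(T)} in kcal/mol.
#' @export
dGTotal <- function(T, Tm, dH, dCp = 0, Lfree, Kd) {
    .assertScalarNumeric(Kd, "Kd", positive = TRUE)
    if (any(Lfree < 0)) stop("'Lfree' must be non-negative")
    dGUnfolding(T, Tm, dH, dCp) + .RGAS * T * log(1 + Lfree / Kd)
}

#' Free ligand concentration under coupled folding and binding
#'
#' Mass-balance expression for the unbound ligand concentration when the
#' folded state binds one ligand and a fraction of the protein is unfolded:
#' \deqn{[L]_{free} = \frac{[L]_0 - [P]_0/(K_u+1) - K_d}{2}
#'   + \sqrt{\frac{([L]_0 + [P]_0/(K_u+1) + K_d)^2}{4}
#'           - \frac{[L]_0 [P]_0}{K_u+1}}}
#' i.e. the bindable protein pool is taken as \eqn{[P]_0/(K_u+1)}. This is
#' the expression used throughout fitting and simulation; see
#' [freeLigandExact()] for the exact three-species solution kept as a
#' cross-check.
#'
#' @param L0 total (initial) ligand concentration (M); vectorized.
#' @param P0 total protein concentration (M).
#' @param Ku unfolding equilibrium constant \eqn{[U]/[F]} (dimensionless).
#' @param Kd dissociation constant (M).
#' @return Free ligand concentration in \[0, `L0`\] (M).
#' @export
freeLigand <- function(L0, P0, Ku, Kd) {
    if (any(L0 < 0) || any(P0 < 0) || any(Ku < 0))
        stop("concentrations and Ku must be non-negative")
    if (any(!is.finite(Kd)) || any(Kd <= 0)) stop("'Kd' must be > 0")
    b <- P0 / (Ku + 1)
    ## the printed discriminant (L0+b+Kd)^2/4 - L0*b equals
    ## (b+Kd-L0)^2/4 + Kd*L0 identically; the latter is a sum of positives
    ## and therefore free of cancellation, as is the conjugate form of the
    ## root used when L0 < b + Kd
    h <- (b + Kd - L0) / 2
    disc <- h^2 + Kd * L0
    stopifnot(all(disc >= 0))
    out <- ifelse(h <= 0, -h + sqrt(disc), Kd * L0 / (h + sqrt(disc)))
    pmin(pmax(out, 0), L0)
}

#' Exact free ligand concentration (three-species mass balance)
#'
#' Solves the full equilibrium system \eqn{FL \rightleftharpoons F + L
#' \rightleftharpoons U + L} exactly. Eliminating species gives a quadratic in
#' \eqn{[L]_{free}} with the effective constant \eqn{K_d (1 + K_u)}: the
#' ligand competes against the whole unbound protein pool, of which only a
#' \eqn{1/(1+K_u)} fraction is folded. Provided for comparison with
#' [freeLigand()]; not used by the fitting routines.
#'
#' @inheritParams freeLigand
#' @return Free ligand concentration (M).
#' @export
freeLigandExact <- function(L0, P0, Ku, Kd) {
    if (any(L0 < 0) || any(P0 < 0) || any(Ku < 0))
        stop("concentrations and Ku must be non-negative")
    if (any(!is.finite(Kd)) || any(Kd <= 0)) stop("'Kd' must be > 0")
    Keff <- Kd * (1 + Ku)
    out <- .posQuadRoot(Keff + P0 - L0, -Keff * L0)
    pmin(pmax(out, 0), L0)
}

#' Apparent unfolding equilibrium constant
#'
#' \deqn{K'_U(T) = e^{-\Delta G(T)/RT}.} With the ligand-free
#' \eqn{\Delta G_U} this is the plain unfolding constant \eqn{K_U}; with the
#' ligand-coupled total \eqn{\Delta G} it is the apparent constant in the
#' presence of ligand.
#'
#' @param dG Gibbs energy (kcal/mol); vectorized.
#' @param T temperature (K).
#' @return Dimensionless equilibrium constant, strictly positive.
#' @export
apparentKu <- function(dG, T) {
    if (any(!is.finite(T)) || any(T <= 0)) stop("'T' must be positive (Kelvin)")
    exp(-dG / (.RGAS * T))
}

#' Fraction of unfolded protein
#'
#' \deqn{f_u = K'_U / (K'_U + 1)}, the ratio \eqn{[U]/[P]_0} observable by
#' DSF, which distinguishes only folded (F + FL) from unfolded (U) species.
#' At the melting temperature \eqn{K'_U = 1} and \eqn{f_u = 0.5}.
#'
#' @param Ku apparent unfolding constant, non-negative; vectorized.
#' @return Fraction unfolded in \[0, 1\].
#' @export
fractionUnfolded <- function(Ku) {
    if (any(Ku < 0)) stop("'Ku' must be non-negative")
    Ku / (Ku + 1)
}

#' Fluorescence signal from fraction unfolded and linear baselines
#'
#' \deqn{Y(T) = f_u(T)(m_u T + b_u) + (1 - f_u(T))(m_f T + b_f)}: a convex
#' combination of the folded and unfolded linear baselines. The folded--bound
#' state is assumed to emit like the folded--unbound state. The expression is
#' scale-agnostic; the package convention is to evaluate baselines on the
#' Celsius scale (intercepts at 0 degC).
#'
#' @param T temperature (same scale as the baseline parameters); vectorized.
#' @param fu fraction unfolded in \[0, 1\]; vectorized.
#' @param mf,bf slope and intercept of the folded-state baseline.
#' @param mu,bu slope and intercept of the unfolded-state baseline.
#' @return Signal values.
#' @export
signalModel <- function(T, fu, mf, bf, mu, bu) {
    if (any(fu < 0 | fu > 1)) stop("'fu' must lie in [0, 1]")
    fu * (mu * T + bu) + (1 - fu) * (mf * T + bf)
}

#' Heat-capacity change estimated from chain length
#'
#' Empirical estimate of the unfolding heat-capacity change from the number
#' of residues: \eqn{\Delta C_p = 13.88 \, N_{res}} cal/(mol K), returned in
#' kcal/(mol K). Useful when no calorimetric value is available.
#'
#' @param Nres number of residues (positive integer); vectorized.
#' @return \eqn{\Delta C_p} in kcal/(mol K).
#' @examples
#' estimateDCp(422)  # ~5.9 kcal/(mol K)
#' @export
estimateDCp <- function(Nres) {
    if (any(!is.finite(Nres)) || any(Nres <= 0) || any(Nres != round(Nres)))
        stop("'Nres' must be a positive integer")
    13.88e-3 * Nres
}

## Internal: full melting-curve signal model in experimental units.
## Tc: temperature grid in degC; TmC in degC; baselines on the Celsius scale.
.meltSignal <- function(Tc, TmC, dH, dCp, mf, bf, mu, bu) {
    TK <- .CtoK(Tc)
    dG <- dH + dCp * (TK - .CtoK(TmC)) -
        TK * (dH / .CtoK(TmC) + dCp * log(TK / .CtoK(TmC)))
    fu <- 1 / (1 + exp(dG / (.RGAS * TK)))
    fu * (mu * Tc + bu) + (1 - fu) * (mf * Tc + bf)
}
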