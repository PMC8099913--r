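## Internal helpers: constants, unit handling, smoothing, seeds.

## Gas constant in kcal mol^-1 K^-1. All thermodynamic arithmetic is done in
## Kelvin; user-facing temperatures are degrees Celsius.
.RGAS <- 1.987204e-3

.CtoK <- function(x) x + 273.15
.KtoC <- function(x) x - 273.15

#' Gas constant used throughout the package
#'
#' Returns the gas constant in kcal mol^-1 K^-1 as used in all Gibbs-energy
#' expressions of the package.
#'
#' @return A length-one numeric, 1.987204e-3 kcal/(mol K).
#' @export
gasConstant <- function() .RGAS

.assertScalarNumeric <- function(x, name, positive = FALSE, nonneg = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
    if (positive && x <= 0)
        stop(sprintf("'%s' must be > 0", name), call. = FALSE)
    if (nonneg && x < 0)
        stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
    invisible(x)
}

#' Parse a concentration with an optional SI suffix
#'
#' Converts strings such as `"2mM"`, `"610nM"`, `"0.5 uM"` or plain numbers
#' (molar) to molar concentration. Recognised suffixes: `M`, `mM`, `uM`
#' (or `µM`), `nM`, `pM`.
#'
#' @param x character or numeric vector of concentrations.
#' @return Numeric vector of concentrations in molar units.
#' @examples
#' parseConcentration(c("2mM", "610nM", "1e-6"))
#' @export
parseConcentration <- function(x) {
    if (is.numeric(x)) return(as.numeric(x))
    x <- trimws(as.character(x))
    out <- vapply(x, function(s) {
        if (grepl("^[-+0-9.eE]+$", s)) return(as.numeric(s))
        s <- gsub("µ", "u", s)  # micro sign -> 'u'
        m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*([munp]?)M$", s))[[1]]
        if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[2]))))
            stop(sprintf("cannot parse concentration '%s'", s), call. = FALSE)
        mult <- if (m[3] == "") 1 else
            switch(m[3], "m" = 1e-3, "u" = 1e-6, "n" = 1e-9, "p" = 1e-12)
        as.numeric(m[2]) * mult
    }, numeric(1), USE.NAMES = FALSE)
    out
}

## Centered quadratic (Savitzky-Golay-type) smoothing, 7-point window.
## Edges keep the raw values; adequate for locating the transition midpoint.
.smoothQuad7 <- function(y) {
    n <- length(y)
    if (n < 7L) return(y)
    w <- c(-2, 3, 6, 7, 6, 3, -2) / 21
    ys <- stats::filter(y, w, sides = 2)
    ys <- as.numeric(ys)
    ys[is.na(ys)] <- y[is.na(ys)]
    ys
}

## Deterministic child-seed derivation (kept below 2^31 - 1).
.childSeed <- function(seed, k) {
    s <- (as.double(seed) %% 2147483647) + 1
    for (i in seq_len(2L)) s <- (s * 48271) %% 2147483647
    as.integer((s + as.double(k) * 7919) %% 2147483629) + 1L
}

## Stable positive root of x^2 + b*x + c with c <= 0 (so one root >= 0).
.posQuadRoot <- function(b, c) {
    disc <- sqrt(b * b / 4 - c)
    ifelse(b <= 0, -b / 2 + disc, -c / (b / 2 + disc))
}
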