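#' Round half away from zero
#'
#' Deterministic "commercial" rounding used for all displayed coefficients.
#' Base R's [round()] rounds half to even (banker's rounding), which does not
#' reproduce printed tables in which e.g. 0.255 appears as 0.26.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded half-up to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.255, 2) # 0.26, not 0.26/0.25 depending on parity
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

# reduce an integer fraction stored as doubles (exact for |values| < 2^53)
reduce_fraction <- function(num, den) {
  stopifnot(den != 0)
  if (num == 0) return(c(num = 0, den = 1))
  g <- gcd_int(num, den)
  c(num = num / g, den = den / g)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# `offset` gives each operation its own named substream so that adding new
# operations never perturbs previously frozen test values.
with_stream <- function(seed, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  sub <- (as.numeric(seed) * 48271 + offset) %% 2147483647
  set.seed(as.integer(sub))
  force(expr)
}

# IUPAC element symbols, H..Og
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

# divalent cations the gelation-salt registry knows about
.divalent_metals <- c("Ba", "Sr", "Ca", "Zn", "Cu", "Ni", "Mn", "Mg", "Cd",
                      "Co", "Fe", "Pb")
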