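#' Ground-truth specification for a synthetic EDX table
#'
#' Describes a known gel model from which an EDX-style atomic-percent table
#' can be forward-generated: the monomer ratio, the gelation salt, the
#' structural occupancy (bare in-cell cations), adsorbed associate count,
#' in-cell complex fraction, hydration, residual sodium, and a
#' multiplicative noise level emulating EDX quantification error.
#'
#' @param mu a [monomer_ratio()] or numeric.
#' @param salt a [salt_spec()].
#' @param structural_x bare in-cell cations per C12 block, in \[0, 1\].
#' @param associates adsorbed salt units per C12 block (>= 0).
#' @param complex_fraction in-cell hydrated complexes per C12 block
#'   (\[0, 1\]; `structural_x + complex_fraction <= 1`).
#' @param water_per_unit waters per salt unit (integer >= 0).
#' @param sodium_residual residual Na per C12 block (>= 0).
#' @param alginate_oxygen backbone oxygens per C12 block (default the
#'   theoretical 12).
#' @param noise_cv per-element multiplicative coefficient of variation
#'   (default 0.02, a placeholder for unreported EDX error magnitudes).
#' @param seed integer seed.
#' @return object of class `synthetic_gel_spec`.
#' @export
synthetic_gel_spec <- function(mu, salt, structural_x, associates = 0,
                               complex_fraction = 0, water_per_unit = 0,
                               sodium_residual = 0, alginate_oxygen = 12,
                               noise_cv = 0.02, seed = 1L) {
  mu <- as_monomer_ratio(mu)
  stopifnot(inherits(salt, "salt_spec"),
            structural_x >= 0, structural_x <= 1,
            associates >= 0, complex_fraction >= 0, complex_fraction <= 1,
            structural_x + complex_fraction <= 1 + 1e-9,
            water_per_unit >= 0, sodium_residual >= 0, noise_cv >= 0)
  structure(list(mu = mu, salt = salt, structural_x = structural_x,
                 associates = associates, complex_fraction = complex_fraction,
                 water_per_unit = water_per_unit,
                 sodium_residual = sodium_residual,
                 alginate_oxygen = alginate_oxygen,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "synthetic_gel_spec")
}

#' Forward-generate an EDX atomic-percent table
#'
#' Builds exact per-C12-block element counts from the ground truth (C 12;
#' H 14 then dropped because EDX sees no hydrogen; O = backbone + anion +
#' water oxygens; metal = structural + adsorbed + complexed; anion per salt
#' stoichiometry; residual Na), converts to atomic percent excluding H,
#' applies per-element multiplicative lognormal noise with the requested
#' CV, and renormalizes to 100. With `noise_cv = 0` the rescale + decompose
#' round trip recovers the spec parameters exactly.
#'
#' @param spec a [synthetic_gel_spec()].
#' @return an [elemental_composition()] whose metadata records the truth.
#' @export
generate_edx_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_gel_spec"))
  s <- spec$salt
  units <- spec$associates + spec$complex_fraction
  counts <- c(
    C = 12,
    O = spec$alginate_oxygen + s$anion_oxygens * units +
      spec$water_per_unit * units,
    Na = spec$sodium_residual
  )
  metal <- spec$structural_x + spec$associates + spec$complex_fraction
  counts[s$cation] <- metal
  anion_atoms <- s$nu * units
  if (anion_atoms > 0) counts[s$anion_element] <- anion_atoms
  counts <- counts[counts > 0]
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    noise <- with_stream(spec$seed, offset = 101,
                         stats::rlnorm(length(counts), -sdlog^2 / 2, sdlog))
    counts <- counts * noise
  }
  atpct <- 100 * counts / sum(counts)
  elemental_composition(
    sample_id = sprintf("synthetic-%s", s$cation),
    entries = atpct,
    metadata = list(truth = spec)
  )
}

#' Monte Carlo simulation of egg-box cell classes
#'
#' Samples `n_cells` cells, each built from two independent ordered blocks
#' of two monomers, classifies them with the same symmetry rule as the
#' enumeration oracle, and returns empirical class frequencies with
#' binomial standard errors. The `iid` model draws monomers independently
#' with P(M) = mu/(1+mu). The `markov` model makes the second monomer of
#' each block copy the first so that the marginal probability of two equal
#' neighbours is `p_stay`; `p_stay` equal to the i.i.d. same-probability
#' P(M)^2 + P(G)^2 reproduces the i.i.d. model bit-identically (smaller
#' values, i.e. anticorrelation, are not supported).
#'
#' @param ratio a [monomer_ratio()] (or bare numeric mu).
#' @param n_cells number of cells to sample (>= 1).
#' @param model `"iid"` or `"markov"`.
#' @param p_stay marginal same-neighbour probability for `model = "markov"`.
#' @param seed integer seed (named substream; other operations unaffected).
#' @return tibble `label`, `count`, `frequency`, `se`, `probability`
#'   (the i.i.d. analytic value for reference).
#' @export
simulate_chain_cells <- function(ratio, n_cells, model = c("iid", "markov"),
                                 p_stay = NULL, seed = 1L) {
  ratio <- as_monomer_ratio(ratio)
  model <- match.arg(model)
  stopifnot(n_cells >= 1)
  pm <- ratio$p_m
  s0 <- pm^2 + (1 - pm)^2
  w <- 0
  if (model == "markov") {
    if (is.null(p_stay) || p_stay < 0 || p_stay > 1) {
      stop("markov model requires p_stay in [0, 1]")
    }
    if (p_stay < s0 - 1e-12) {
      stop(sprintf("p_stay = %.3f below the i.i.d. same-probability %.3f; anticorrelated chains unsupported",
                   p_stay, s0))
    }
    w <- (p_stay - s0) / (1 - s0)
  }
  mono <- with_stream(seed, offset = 202, {
    m <- matrix(stats::runif(4 * n_cells) < pm, ncol = 4)
    if (w > 0) {
      copy <- matrix(stats::runif(2 * n_cells) < w, ncol = 2)
      m[, 2][copy[, 1]] <- m[, 1][copy[, 1]]
      m[, 4][copy[, 2]] <- m[, 3][copy[, 2]]
    }
    m
  })
  labels <- classify_cells(mono)
  classes <- cell_classes()
  counts <- table(factor(labels, levels = classes$label))
  freq <- as.numeric(counts) / n_cells
  tibble::tibble(
    label = classes$label,
    count = as.integer(counts),
    frequency = freq,
    se = sqrt(freq * (1 - freq) / n_cells),
    probability = cell_probabilities(ratio)$probability
  )
}

# vectorized cell classification; m is a logical matrix (TRUE = M monomer)
# columns 1:2 = block of chain A, 3:4 = block of chain B
classify_cells <- function(m) {
  blk <- function(a, b) ifelse(a, ifelse(b, "MM", "MG"), ifelse(b, "GM", "GG"))
  b1 <- blk(m[, 1], m[, 2])
  b2 <- blk(m[, 3], m[, 4])
  key <- function(b) ifelse(b %in% c("GM", "MG"), "GM*", b)
  k1 <- key(b1); k2 <- key(b2)
  lo <- pmin(k1, k2); hi <- pmax(k1, k2)
  out <- character(nrow(m))
  out[lo == "GG" & hi == "GG"] <- "GG-GG"
  out[lo == "GG" & hi == "GM*"] <- "GG-GM/GG-MG"
  out[lo == "GG" & hi == "MM"] <- "GG-MM"
  out[lo == "GM*" & hi == "MM"] <- "MM-GM/MM-MG"
  out[lo == "MM" & hi == "MM"] <- "MM-MM"
  both <- lo == "GM*" & hi == "GM*"
  out[both & b1 == b2] <- "GM-GM"
  out[both & b1 != b2] <- "GM-MG"
  out
}
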