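#' Gelation salt specification
#'
#' Describes the divalent-metal salt used for ionotropic gelation: its
#' anion, the number of anion formula units per cation (2 for chlorides,
#' 1 for sulfates), the oxygens each anion unit carries, and the default
#' hydration of physically adsorbed associates.
#'
#' @param cation element symbol of the divalent metal.
#' @param anion anion formula unit, `"Cl"` or `"SO4"` (free-form allowed).
#' @param nu anions per cation formula unit (1 or 2).
#' @param anion_oxygens oxygen atoms per anion unit (Cl 0, SO4 4).
#' @param default_hydration waters per adsorbed associate (integer >= 0).
#' @return object of class `salt_spec`.
#' @export
#' @examples
#' salt_spec("Sr", "Cl", nu = 2, anion_oxygens = 0)
salt_spec <- function(cation, anion, nu, anion_oxygens, default_hydration = 0) {
  stopifnot(nu %in% c(1, 2), anion_oxygens >= 0, default_hydration >= 0)
  # EDX reports the anion through one measurable element (Cl, or S for SO4)
  anion_element <- if (anion == "SO4") "S" else anion
  structure(list(cation = cation, anion = anion, anion_element = anion_element,
                 nu = nu, anion_oxygens = anion_oxygens,
                 default_hydration = default_hydration),
            class = "salt_spec")
}

#' Registry of the gelation salts used for the reference hydrogels
#'
#' Chlorides for Ba, Sr, Ca, Mn; sulfates for Zn, Cu, Ni. Default hydration:
#' 4 waters per adsorbed nickel-sulfate associate, 8 per in-cell copper
#' sulfate complex.
#'
#' @param cation optional element symbol; when given, returns one
#'   [salt_spec()].
#' @return named list of `salt_spec` objects.
#' @export
salt_registry <- function(cation = NULL) {
  reg <- list(
    Ba = salt_spec("Ba", "Cl", 2, 0),
    Sr = salt_spec("Sr", "Cl", 2, 0),
    Ca = salt_spec("Ca", "Cl", 2, 0),
    Mn = salt_spec("Mn", "Cl", 2, 0),
    Zn = salt_spec("Zn", "SO4", 1, 4),
    Cu = salt_spec("Cu", "SO4", 1, 4, default_hydration = 8),
    Ni = salt_spec("Ni", "SO4", 1, 4, default_hydration = 4)
  )
  if (is.null(cation)) return(reg)
  if (!cation %in% names(reg)) stop("no registered salt for cation ", cation)
  reg[[cation]]
}

#' Decompose measured metal content into structural and adsorbed species
#'
#' In nearly all reference gels the metal coefficient per C12 block exceeds
#' the egg-box maximum X = 1, which signals metal present in nonequivalent
#' positions: cross-linking cations inside cells, neutral salt associates
#' physically adsorbed on the junction-zone sheets, and (for small
#' transition metals) hydrated salt complexes occupying cells in place of
#' bare ions. Four policies split the totals:
#'
#' * `anion_driven` - every anion belongs to an adsorbed associate:
#'   `associates = anion/nu`, `structural_x = metal - associates`
#'   (Sr, Ca, Zn).
#' * `full_occupancy` - all cells are filled (`X = 1`); excess metal is
#'   adsorbed and any anion imbalance is reported as a residual (Mn, whose
#'   strong oxygen deficit signals chain degradation).
#' * `complex_in_cell` - cells are filled; excess metal is adsorbed as
#'   associates (capped at 2 per block, one per sheet face); anion beyond
#'   the adsorbed share sits in in-cell complexes; when the remaining anion
#'   nearly matches the in-cell metal, every occupied cell is taken to hold
#'   a complex (Cu, Ni).
#' * `auto` - decision tree: no anion -> pure structural; alginate oxygen
#'   < 8 (degradation) -> `full_occupancy`; anion/nu >= metal - 1 and metal
#'   within 0.05 of an integer >= 1 -> `complex_in_cell`; metal - anion/nu
#'   in (0, 1] -> `anion_driven`.
#'
#' Sodium is carried as an inert counterion and never counted toward X.
#' Metal conservation `structural_x + associates + in_cell_complex_fraction
#' = metal` holds exactly (pre-rounding) under every policy.
#'
#' @param c12 a `c12_composition` (round with [round_coefficients()] first
#'   to work from reported two-decimal tables).
#' @param salt a [salt_spec()]; defaults to the registry entry for the
#'   composition's cation.
#' @param policy `"auto"`, `"anion_driven"`, `"full_occupancy"` or
#'   `"complex_in_cell"`.
#' @param tol numerical tolerance (default 1e-6).
#' @return object of class `decomposition_result` with fields
#'   `structural_x` (bare in-cell cations), `in_cell_complex_fraction`,
#'   `occupied_cells` (their sum, the X used for zone classification),
#'   `associates`, `associate_formula`, `complex_formula`,
#'   `alginate_oxygen`, `water_per_complex` (NA until [infer_hydration()]),
#'   `residual` (per-element imbalance), `policy_used`, `zone_type`, `notes`.
#' @export
#' @examples
#' sr <- rescale_to_c12(elemental_composition("Sr-alg",
#'   c(C = 43.18, O = 41.73, Sr = 6.47, Na = 0.36, Cl = 8.27)))
#' decompose(round_coefficients(sr)) # associates 1.15, structural X 0.65
decompose <- function(c12, salt = NULL, policy = c("auto", "anion_driven",
                                                   "full_occupancy",
                                                   "complex_in_cell"),
                      tol = 1e-6) {
  stopifnot(inherits(c12, "c12_composition"))
  policy <- match.arg(policy)
  if (is.null(salt)) salt <- salt_registry(c12$cation)
  stopifnot(inherits(salt, "salt_spec"))
  coef <- c12$coefficients
  if (!salt$cation %in% names(coef)) {
    stop(sprintf("sample '%s' has no %s to decompose",
                 c12$sample_id, salt$cation))
  }
  metal <- coef[[salt$cation]]
  anion <- if (salt$anion_element %in% names(coef)) coef[[salt$anion_element]] else 0
  oxy <- if ("O" %in% names(coef)) coef[["O"]] else 0
  notes <- character(0)

  if (policy == "auto") {
    policy <- if (anion <= tol) {
      "anion_driven" # degenerates to pure structural metal
    } else if (oxy < 8) {
      notes <- c(notes, "auto: strong oxygen deficit signals chain degradation")
      "full_occupancy"
    } else if (anion / salt$nu >= metal - 1 - tol &&
               abs(metal - round(metal)) <= 0.05 && round(metal) >= 1) {
      "complex_in_cell"
    } else if (metal - anion / salt$nu > tol &&
               metal - anion / salt$nu <= 1 + tol) {
      "anion_driven"
    } else {
      stop(sprintf("sample '%s': no auto policy applies (metal %.3f, anion %.3f)",
                   c12$sample_id, metal, anion))
    }
    notes <- c(notes, paste0("auto policy -> ", policy))
  }

  residual <- c(O = 0)
  water <- NA_real_
  complex_fraction <- 0
  if (policy == "anion_driven") {
    associates <- anion / salt$nu
    structural <- metal - associates
    if (structural < -tol) {
      stop(sprintf("sample '%s': anion exceeds metal stoichiometry (%s %.3f vs %s %.3f)",
                   c12$sample_id, salt$anion_element, anion, salt$cation, metal))
    }
    structural <- max(structural, 0)
  } else if (policy == "full_occupancy") {
    structural <- 1
    associates <- metal - 1
    if (associates < -tol) {
      stop(sprintf("sample '%s': metal %.3f below full occupancy",
                   c12$sample_id, metal))
    }
    residual <- c(residual,
                  stats::setNames(anion - salt$nu * associates,
                                  salt$anion_element))
    if (associates > 2 + tol) {
      notes <- c(notes,
                 "adsorbed associates exceed the 2-per-block cap: surface increased by chain breaks")
    }
  } else { # complex_in_cell
    associates <- min(2, max(0, metal - 1))
    anion_left <- anion - salt$nu * associates
    in_cell_metal <- metal - associates
    if (anion_left < -tol) {
      residual <- c(residual,
                    stats::setNames(anion_left, salt$anion_element))
      anion_left <- 0
    }
    if (abs(anion_left / salt$nu - in_cell_metal) <= 0.05) {
      # anion matches in-cell metal: every occupied cell holds a complex
      complex_fraction <- in_cell_metal
      residual <- c(residual,
                    stats::setNames(anion_left - salt$nu * complex_fraction,
                                    salt$anion_element))
      notes <- c(notes, "all occupied cells hold hydrated complexes")
    } else {
      complex_fraction <- anion_left / salt$nu
      if (complex_fraction > in_cell_metal + tol) {
        stop(sprintf("sample '%s': anion exceeds metal stoichiometry in cells",
                     c12$sample_id))
      }
    }
    structural <- in_cell_metal - complex_fraction
  }

  occupied <- structural + complex_fraction
  zone <- classify_junction_zone(min(occupied, 1 + 0.05))
  na_coef <- if ("Na" %in% names(coef)) coef[["Na"]] else 0

  res <- structure(list(
    sample_id = c12$sample_id,
    cation = salt$cation,
    salt = salt,
    policy_used = policy,
    structural_x = structural,
    in_cell_complex_fraction = complex_fraction,
    occupied_cells = occupied,
    associates = associates,
    associate_formula = associate_formula(salt, hydration = salt$default_hydration),
    complex_formula = if (complex_fraction > 0) {
      paste0(salt$cation, salt$anion)
    } else NA_character_,
    alginate_oxygen = oxy,
    observed_oxygen = oxy,
    sodium = na_coef,
    total_metal = metal,
    total_anion = anion,
    water_per_complex = water,
    residual = residual,
    zone_type = zone,
    notes = notes
  ), class = "decomposition_result")
  res
}

associate_formula <- function(salt, hydration = 0) {
  base <- paste0(salt$cation, salt$anion,
                 if (salt$nu > 1) salt$nu else "")
  if (hydration > 0) paste0(base, "·", hydration, "H2O") else base
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("<decomposition_result> %s  policy %s\n", x$sample_id, x$policy_used))
  cat(sprintf("  structural X %.3f | in-cell complexes %.3f | adsorbed %s %.3f\n",
              x$structural_x, x$in_cell_complex_fraction,
              x$associate_formula, x$associates))
  cat(sprintf("  occupied cells %.3f -> %s\n", x$occupied_cells,
              x$zone_type$label))
  cat("  ", render_formula(x), "\n")
  invisible(x)
}

#' Infer hydration water of associates and in-cell complexes
#'
#' Oxygen beyond the alginate backbone and the anion oxygens is attributed
#' to hydration water: `water = (O_observed - O_alginate -
#' anion_oxygens * units) / carrier_units`, rounded to the nearest integer.
#' By default the water rides on adsorbed associates when any exist,
#' otherwise on the in-cell complexes; `carrier = "all"` hydrates both
#' (the alternative composition reading for nickel). A negative estimate
#' clamps to 0 with a degradation flag (oxygen-deficient manganese gels).
#'
#' @param result a [decompose()] result.
#' @param alginate_oxygen_reference oxygens per C12 block belonging to the
#'   alginate itself (theoretical 12; measured gels run ~10.7-11.6;
#'   default 11).
#' @param carrier `"auto"`, `"adsorbed"`, `"complexes"` or `"all"`.
#' @return integer water count with attributes `degradation` (logical) and
#'   `alginate_oxygen` (oxygen left to the backbone after assignment).
#'   Zero salt units with an oxygen excess beyond `tol` triggers a warning.
#' @param tol unassigned-oxygen warning threshold (default 0.5 O).
#' @param backbone_max largest oxygen count the C12 backbone itself can
#'   carry (theoretical 12). When the anhydrous reading already leaves the
#'   backbone at or below this, no water is inferred: hydration is only
#'   invoked to explain an otherwise impossible oxygen excess. Set to 0 to
#'   force the plain excess/units estimate.
#' @export
infer_hydration <- function(result, alginate_oxygen_reference = 11,
                            carrier = c("auto", "adsorbed", "complexes", "all"),
                            tol = 0.5, backbone_max = 12) {
  stopifnot(inherits(result, "decomposition_result"))
  carrier <- match.arg(carrier)
  units_total <- result$associates + result$in_cell_complex_fraction
  carrier_units <- switch(carrier,
    auto = if (result$associates > 0) result$associates else result$in_cell_complex_fraction,
    adsorbed = result$associates,
    complexes = result$in_cell_complex_fraction,
    all = units_total)
  anhydrous_o <- result$observed_oxygen -
    result$salt$anion_oxygens * units_total
  excess <- anhydrous_o - alginate_oxygen_reference
  degraded <- FALSE
  if (units_total == 0 || carrier_units == 0) {
    if (excess > max(tol, backbone_max - alginate_oxygen_reference)) {
      warning(sprintf("sample '%s': %.2f unassigned oxygen per C12 block",
                      result$sample_id, excess))
    }
    water <- 0
    degraded <- result$observed_oxygen < alginate_oxygen_reference - tol
  } else if (anhydrous_o <= backbone_max + 0.25) {
    # plausible backbone oxygen: nothing left over to call hydration water
    water <- 0
    degraded <- anhydrous_o < 8
  } else {
    water <- round(excess / carrier_units)
    if (water < 0) {
      water <- 0
      degraded <- TRUE
    }
  }
  alg_o <- anhydrous_o - water * carrier_units
  structure(water, degradation = degraded, alginate_oxygen = alg_o,
            carrier = carrier)
}

#' Render the chemical formula of a decomposition
#'
#' Produces the per-C12-block formula string, e.g.
#' `"(C12H14O11.6Na0.1Sr0.65 + 1.15·SrCl2)n"`. Coefficients are half-up
#' rounded to two decimals with trailing zeros trimmed; unity coefficients
#' and zero terms are omitted. Results with in-cell complexes use the
#' braced multi-term form.
#'
#' @param result a [decompose()] result (optionally after
#'   [infer_hydration()] has been used to set `water_per_complex`).
#' @param water optional integer hydration of the associates/complexes,
#'   overriding the salt default.
#' @return formula string; deterministic for identical rounded results.
#' @export
render_formula <- function(result, water = NULL) {
  stopifnot(inherits(result, "decomposition_result"))
  s <- result$salt
  water <- water %||% s$default_hydration
  alg <- function(metal_part, oxygen) {
    paste0("C12H14O", format_coef2(oxygen),
           if (result$sodium > 0) paste0("Na", format_coef2(result$sodium)) else "",
           metal_part)
  }
  salt_term <- function(n, hydr) {
    unit <- paste0(s$cation, s$anion, if (s$nu > 1) s$nu else "")
    if (hydr > 0) unit <- paste0("(", unit, "·", hydr, "H2O)")
    if (abs(n - 1) < 5e-3) unit else paste0(format_coef2(n, keep_one = TRUE),
                                            "·", unit)
  }
  if (result$in_cell_complex_fraction > 0) {
    plain <- result$structural_x
    cf <- result$in_cell_complex_fraction
    o <- format_coef2(result$alginate_oxygen)
    terms <- character(0)
    if (plain > 5e-3) {
      terms <- c(terms, paste0(format_coef2(plain, keep_one = TRUE),
                               "·C12H14O", o, result$cation))
    }
    complex_unit <- paste0("(", s$cation, s$anion,
                           if (water > 0 && result$associates == 0)
                             paste0("·", water, "H2O") else "", ")")
    cf_term <- if (abs(cf - 1) < 5e-3 && plain <= 5e-3) {
      paste0("C12H14O", o, complex_unit)
    } else {
      paste0(format_coef2(cf, keep_one = TRUE), "·C12H14O", o,
             "·", complex_unit)
    }
    terms <- c(terms, cf_term)
    if (result$associates > 5e-3) {
      terms <- c(terms, salt_term(result$associates, water))
    }
    paste0("{", paste(terms, collapse = " + "), "}n")
  } else {
    metal_part <- paste0(result$cation, format_coef(result$structural_x))
    body <- alg(metal_part, result$alginate_oxygen)
    if (result$associates > 5e-3) {
      body <- paste0(body, " + ", salt_term(result$associates, water))
    }
    paste0("(", body, ")n")
  }
}

# like format_coef but keeps "1" when requested and never drops the number
format_coef2 <- function(x, digits = 2, keep_one = FALSE) {
  r <- round_half_up(x, digits)
  if (!keep_one && r == 1) return("")
  s <- formatC(r, format = "f", digits = digits)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Compare experimental occupancy with the combinatorial prediction
#'
#' For plain decompositions, compares the experimental X (occupied cells)
#' against the theoretical occupancy X_T of the cation's preference set;
#' for complex-in-cell results, compares the in-cell complex fraction
#' against the probability of the preferred (GG-containing) cells.
#'
#' @param result a [decompose()] result.
#' @param ratio a [monomer_ratio()] (or bare numeric mu).
#' @param prefs a [preference_set()]; defaults to the registry entry for
#'   the cation when one exists.
#' @return tibble with columns `sample_id`, `component`, `x_experimental`,
#'   `x_theoretical`, `difference`, `classes`.
#' @export
compare_occupancy <- function(result, ratio, prefs = NULL) {
  stopifnot(inherits(result, "decomposition_result"))
  ratio <- as_monomer_ratio(ratio)
  if (is.null(prefs)) {
    reg <- preference_sets()
    if (!result$cation %in% names(reg)) {
      stop("no registered preference set for ", result$cation,
           "; supply `prefs`")
    }
    prefs <- reg[[result$cation]]
  }
  x_t <- as.numeric(occupancy(ratio, prefs))
  if (result$policy_used == "complex_in_cell" &&
      result$in_cell_complex_fraction > 0 &&
      result$in_cell_complex_fraction < result$occupied_cells) {
    x_exp <- result$in_cell_complex_fraction
    component <- "in_cell_complex_fraction"
  } else {
    x_exp <- result$occupied_cells
    component <- "occupancy"
  }
  tibble::tibble(
    sample_id = result$sample_id,
    component = component,
    x_experimental = x_exp,
    x_theoretical = x_t,
    difference = abs(x_exp - x_t),
    classes = paste(prefs$classes, collapse = ",")
  )
}
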