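#' Rescale an atomic-percent composition to the alginate C12 block
#'
#' The natural comparison unit for alginate gels is the block of two uronic
#' monomers, C12H14O12 for the sodium form with both carboxyls exchanged.
#' Every atomic percent is multiplied by `12 / K_C`, where `K_C` is the
#' carbon atomic percent, so that carbon becomes exactly 12 and all pairwise
#' element ratios are preserved. Because EDX emits no characteristic line
#' for hydrogen, H is imputed as 14 per block (flag-controlled).
#'
#' @param comp an [elemental_composition()], usually after [discard_traces()].
#' @param impute_hydrogen add `H = 14` to the coefficients (default TRUE).
#' @param cation element symbol of the divalent metal; autodetected from the
#'   known divalent set when `NULL`.
#' @return object of class `c12_composition` with fields `coefficients`
#'   (element -> atoms per C12 block), `k_c`, `hydrogen_imputed`, `cation`.
#' @export
#' @examples
#' ba <- elemental_composition("Ba-alg", c(C = 51.16, O = 45.81, Ba = 2.74, Na = 0.14))
#' rescale_to_c12(ba) # C 12, O 10.75, Ba 0.64, Na 0.03 (2 d.p.)
rescale_to_c12 <- function(comp, impute_hydrogen = TRUE, cation = NULL) {
  stopifnot(inherits(comp, c("elemental_composition", "c12_composition")))
  if (inherits(comp, "c12_composition")) return(comp) # idempotent
  if (!"C" %in% names(comp$entries) || comp$entries[["C"]] <= 0) {
    stop(sprintf("sample '%s': carbon absent, cannot anchor C12 rescaling",
                 comp$sample_id))
  }
  k_c <- comp$entries[["C"]]
  coef <- comp$entries * 12 / k_c
  coef[["C"]] <- 12 # exact by construction
  if (impute_hydrogen) coef <- c(coef, H = 14)
  coef <- coef[order(match(names(coef), .element_symbols))]
  if (is.null(cation)) {
    hit <- intersect(names(coef), .divalent_metals)
    cation <- if (length(hit)) hit[[1]] else NA_character_
  }
  structure(
    list(sample_id = comp$sample_id, coefficients = coef, k_c = unname(k_c),
         hydrogen_imputed = impute_hydrogen, cation = cation,
         metadata = comp$metadata),
    class = "c12_composition"
  )
}

#' @export
print.c12_composition <- function(x, ...) {
  cat(sprintf("<c12_composition> %s  (K_C = %.2f at%%, cation %s)\n",
              x$sample_id, x$k_c, x$cation))
  cat(" ", format_c12(x), "\n")
  invisible(x)
}

#' Round C12 coefficients to reporting precision
#'
#' The published per-sample formulas carry two decimals; downstream
#' decomposition of the reported tables therefore starts from rounded
#' coefficients. Rounding is half-up; carbon stays exactly 12.
#'
#' @param c12 a `c12_composition`.
#' @param digits decimal places (default 2).
#' @return the composition with rounded coefficients.
#' @export
round_coefficients <- function(c12, digits = 2) {
  stopifnot(inherits(c12, "c12_composition"))
  c12$coefficients <- round_half_up(c12$coefficients, digits)
  c12
}

# "C12O10.75Na0.03Ba0.64"-style formula string (display rounding, trailing
# zeros trimmed as in the reference tables: 11.60 -> 11.6)
format_c12 <- function(c12, digits = 2) {
  coef <- c12$coefficients
  ord <- c("C", "H", "O", "Na")
  ord <- c(intersect(ord, names(coef)), setdiff(names(coef), ord))
  paste0(vapply(ord, function(e) {
    paste0(e, format_coef(coef[[e]], digits))
  }, character(1)), collapse = "")
}

# coefficient formatting: half-up, trim trailing zeros, omit "1"
format_coef <- function(x, digits = 2) {
  r <- round_half_up(x, digits)
  if (r == 1) return("")
  s <- formatC(r, format = "f", digits = digits)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Classify the junction-zone type from the cation occupancy X
#'
#' Lateral association of alginate dimers yields flat junction-zone sheets
#' of three types, distinguished by the average number X of divalent cations
#' per C12 block: dimers held together only by van der Waals contacts and
#' hydrogen bonds (X <= 0.5), electrostatically assembled zones
#' (0.5 < X < 1), and sheets with every egg-box cell filled (X = 1).
#'
#' @param x occupancy, cations per C12 block.
#' @param tol tolerance on the X = 1 boundary (default 0.05, so that a
#'   measured 0.99 classifies as a complete sheet).
#' @return object of class `junction_zone_type` with fields `label` (one of
#'   `"dimer_vdw"`, `"electrostatic_intermediate"`, `"complete_sheet"`) and
#'   `occupancy_range`.
#' @export
#' @examples
#' classify_junction_zone(0.26)$label # dimer_vdw
#' classify_junction_zone(0.64)$label # electrostatic_intermediate
classify_junction_zone <- function(x, tol = 0.05) {
  stopifnot(is.numeric(x), length(x) == 1, x >= 0)
  if (x > 1 + tol) {
    stop(sprintf(paste0("occupancy X = %.2f exceeds the egg-box maximum of 1;",
                        " unseparated adsorbed associates - run decomposition first"), x))
  }
  if (abs(x - 1) <= tol) {
    label <- "complete_sheet"; rng <- c(1 - tol, 1 + tol)
  } else if (x <= 0.5) {
    label <- "dimer_vdw"; rng <- c(0, 0.5)
  } else {
    label <- "electrostatic_intermediate"; rng <- c(0.5, 1 - tol)
  }
  structure(list(label = label, occupancy_range = rng, x = x),
            class = "junction_zone_type")
}

#' @export
print.junction_zone_type <- function(x, ...) {
  cat(sprintf("<junction_zone_type> %s (X = %.3f in [%.2f, %.2f])\n",
              x$label, x$x, x$occupancy_range[1], x$occupancy_range[2]))
  invisible(x)
}
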