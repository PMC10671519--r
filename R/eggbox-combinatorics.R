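#' Monomer ratio mu = M/G
#'
#' Alginate is an irregular copolymer of beta-D-mannuronate (M) and
#' alpha-L-guluronate (G). Under the i.i.d. sequence model each monomer is
#' M with probability `mu/(1 + mu)` and G with probability `1/(1 + mu)`.
#' An exact rational representation `p/q` enables exact-fraction arithmetic
#' in all probability computations.
#'
#' @param mu positive real, the M/G ratio (1.56 for the reference sample).
#' @param exact optional exact rational, either an integer vector `c(p, q)`
#'   or a string `"p/q"`; must agree with `mu` to 1e-12.
#' @return object of class `monomer_ratio` with fields `mu`, `p_m`
#'   (= mu/(1+mu)), `p_g`, and optionally `num`/`den`.
#' @export
#' @examples
#' monomer_ratio(1.56, exact = "39/25")
monomer_ratio <- function(mu, exact = NULL) {
  stopifnot(is.numeric(mu), length(mu) == 1, is.finite(mu))
  if (mu <= 0) stop("mu must be > 0")
  num <- den <- NULL
  if (!is.null(exact)) {
    if (is.character(exact)) {
      parts <- as.numeric(strsplit(exact, "/", fixed = TRUE)[[1]])
      if (length(parts) == 1) parts <- c(parts, 1)
      exact <- parts
    }
    stopifnot(length(exact) == 2, all(exact == floor(exact)), all(exact > 0))
    if (abs(exact[1] / exact[2] - mu) > 1e-12) {
      stop(sprintf("exact fraction %d/%d does not equal mu = %g",
                   exact[1], exact[2], mu))
    }
    f <- reduce_fraction(exact[1], exact[2])
    num <- unname(f["num"]); den <- unname(f["den"])
  }
  structure(list(mu = mu, p_m = mu / (1 + mu), p_g = 1 / (1 + mu),
                 num = num, den = den),
            class = "monomer_ratio")
}

is_exact <- function(ratio) !is.null(ratio$num)

as_monomer_ratio <- function(x) {
  if (inherits(x, "monomer_ratio")) x else monomer_ratio(x)
}

#' @export
print.monomer_ratio <- function(x, ...) {
  cat(sprintf("<monomer_ratio> mu = %g%s  (P(M) = %.4f, P(G) = %.4f)\n",
              x$mu, if (is_exact(x)) sprintf(" = %d/%d", x$num, x$den) else "",
              x$p_m, x$p_g))
  invisible(x)
}

#' The seven egg-box cell equivalence classes
#'
#' A cell of the egg-box lattice is formed by two opposed two-monomer blocks
#' (one per chain of a dimer), i.e. an ordered pair of ordered blocks, 16
#' configurations in all. Configurations related by swapping the two chains
#' or by reversing the reading direction of both chains simultaneously are
#' equivalent; GM-GM (= MG-MG) remains distinct from GM-MG (= MG-GM). This
#' yields seven classes with multiplicities 1, 4, 2, 2, 2, 4, 1.
#'
#' @return tibble with columns `label`, `multiplicity`, `mu_degree` (the
#'   power of mu in the probability numerator: the number of M monomers in
#'   the configuration) in the canonical row order.
#' @export
cell_classes <- function() {
  tibble::tibble(
    label = c("GG-GG", "GG-GM/GG-MG", "GG-MM", "GM-GM", "GM-MG",
              "MM-GM/MM-MG", "MM-MM"),
    multiplicity = c(1L, 4L, 2L, 2L, 2L, 4L, 1L),
    mu_degree = c(0L, 1L, 2L, 2L, 2L, 3L, 4L)
  )
}

#' Probabilities of the four two-monomer blocks
#'
#' Under the i.i.d. model the ordered blocks of a single chain occur with
#' P(GG) = 1/(1+mu)^2, P(GM) = P(MG) = mu/(1+mu)^2, P(MM) = mu^2/(1+mu)^2.
#'
#' @param ratio a [monomer_ratio()] (or bare numeric mu).
#' @return tibble with columns `block`, `probability`, and in exact mode
#'   `num`, `den` (reduced integer fractions).
#' @export
#' @examples
#' block_probabilities(1.56) # GG 0.153, GM = MG 0.238, MM 0.371
block_probabilities <- function(ratio) {
  ratio <- as_monomer_ratio(ratio)
  mu <- ratio$mu
  out <- tibble::tibble(
    block = c("GG", "GM", "MG", "MM"),
    probability = c(1, mu, mu, mu^2) / (1 + mu)^2
  )
  if (is_exact(ratio)) {
    p <- ratio$num; q <- ratio$den
    den0 <- (p + q)^2
    nums <- c(q^2, p * q, p * q, p^2)
    fr <- t(vapply(nums, reduce_fraction, numeric(2), den = den0))
    out$num <- fr[, 1]; out$den <- fr[, 2]
    out$probability <- out$num / out$den
  }
  out
}

#' Probabilities of the seven egg-box cell classes
#'
#' Class probability = multiplicity * mu^degree / (1 + mu)^4; the seven
#' probabilities sum to 1 by the binomial identity (1 + mu)^4 =
#' sum(multiplicity * mu^degree).
#'
#' @param ratio a [monomer_ratio()] (or bare numeric mu).
#' @return [cell_classes()] tibble with a `probability` column appended, and
#'   `num`/`den` reduced fractions in exact mode.
#' @export
#' @examples
#' cell_probabilities(monomer_ratio(1.5, exact = "3/2")) # GG-GG = 16/625
cell_probabilities <- function(ratio) {
  ratio <- as_monomer_ratio(ratio)
  mu <- ratio$mu
  out <- cell_classes()
  out$probability <- out$multiplicity * mu^out$mu_degree / (1 + mu)^4
  if (is_exact(ratio)) {
    p <- ratio$num; q <- ratio$den
    den0 <- (p + q)^4
    nums <- out$multiplicity * p^out$mu_degree * q^(4 - out$mu_degree)
    fr <- t(vapply(nums, reduce_fraction, numeric(2), den = den0))
    out$num <- fr[, 1]; out$den <- fr[, 2]
    out$probability <- out$num / out$den
  }
  out
}

#' Registered cation preference sets
#'
#' Literature-derived sets of cell classes each divalent cation is thought
#' to occupy. Ba and Zn share one set (GG- and MM-containing cells); Sr's
#' set is tentative (conflicting literature); Ca binds only GG-containing
#' cells, a set reused for the in-cell complexes of Ni; `"GG-GG"` alone
#' gives the probability of the nucleation cell that triggers chain zipping.
#'
#' @param cation optional element symbol; when given, returns that single
#'   [preference_set()].
#' @return named list of `preference_set` objects.
#' @export
preference_sets <- function(cation = NULL) {
  reg <- list(
    Ba = preference_set("Ba", c("GG-GG", "GG-MM", "MM-GM/MM-MG", "MM-MM"),
                        "GG/MM-block cells; GM-MM inclusion tentative"),
    Sr = preference_set("Sr", c("GG-GG", "GG-GM/GG-MG", "GG-MM", "MM-GM/MM-MG"),
                        "tentative: contradictory literature"),
    Ca = preference_set("Ca", c("GG-GG", "GG-GM/GG-MG", "GG-MM"),
                        "GG-containing cells only (largest cavities)"),
    Zn = preference_set("Zn", c("GG-GG", "GG-MM", "MM-GM/MM-MG", "MM-MM"),
                        "as Ba; largest transition-metal radius"),
    Ni = preference_set("Ni", c("GG-GG", "GG-GM/GG-MG", "GG-MM"),
                        "GG-containing cells host the in-cell complexes"),
    GG_only = preference_set(NA_character_, "GG-GG", "zipping nucleation cell")
  )
  if (is.null(cation)) return(reg)
  if (!cation %in% names(reg)) {
    stop("no registered preference set for cation ", cation)
  }
  reg[[cation]]
}

#' Define a cation preference set
#'
#' @param cation element symbol (or NA for anonymous sets).
#' @param classes character vector of cell-class labels, drawn from
#'   `cell_classes()$label`.
#' @param literature_note free-text provenance note.
#' @return object of class `preference_set`.
#' @export
preference_set <- function(cation, classes, literature_note = "") {
  bad <- setdiff(classes, cell_classes()$label)
  if (length(bad)) {
    stop("unknown cell class label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(classes)) stop("duplicate cell class labels")
  structure(list(cation = cation, classes = classes,
                 literature_note = literature_note),
            class = "preference_set")
}

#' Theoretical occupancy X_T of a preference set
#'
#' The theoretical average cell filling is the summed probability of the
#' cell classes a cation prefers. For the registered sets this evaluates
#' the closed forms (all over (1 + mu)^4): Ba/Zn numerator
#' 1 + 2mu^2 + 4mu^3 + mu^4; Sr numerator 1 + 4mu + 2mu^2 + 4mu^3; Ca/Ni
#' numerator 1 + 4mu + 2mu^2; GG-GG alone 1.
#'
#' @param ratio a [monomer_ratio()] (or bare numeric mu).
#' @param prefs a [preference_set()] or character vector of class labels.
#' @return X_T as a number; in exact mode carries a `"fraction"` attribute
#'   `c(num, den)`.
#' @export
#' @examples
#' occupancy(1.56, preference_sets("Ba")) # 0.628... -> 0.63
occupancy <- function(ratio, prefs) {
  ratio <- as_monomer_ratio(ratio)
  if (inherits(prefs, "preference_set")) prefs <- prefs$classes
  bad <- setdiff(prefs, cell_classes()$label)
  if (length(bad)) {
    stop("unknown cell class label(s): ", paste(bad, collapse = ", "))
  }
  cp <- cell_probabilities(ratio)
  sel <- cp$label %in% prefs
  x_t <- sum(cp$probability[sel])
  if (is_exact(ratio)) {
    p <- ratio$num; q <- ratio$den
    num <- sum(cp$multiplicity[sel] * p^cp$mu_degree[sel] *
                 q^(4 - cp$mu_degree[sel]))
    fr <- reduce_fraction(num, (p + q)^4)
    x_t <- unname(fr["num"] / fr["den"])
    attr(x_t, "fraction") <- unname(fr)
  }
  x_t
}

#' Brute-force enumeration oracle for cell-class probabilities
#'
#' Independently of the closed forms, enumerates all 2^4 = 16 ordered
#' four-monomer configurations (two ordered blocks of two i.i.d. monomers),
#' canonicalizes each under the symmetry group {identity, chain swap,
#' simultaneous reversal, both}, and accumulates exact probabilities per
#' class. In exact mode the comparison with [cell_probabilities()] is an
#' integer identity.
#'
#' @param ratio a [monomer_ratio()] (or bare numeric mu).
#' @return tibble `label`, `probability` (+ `num`, `den` in exact mode) in
#'   canonical class order, with the observed `multiplicity` per class.
#' @export
enumerate_cells_oracle <- function(ratio) {
  ratio <- as_monomer_ratio(ratio)
  monomers <- c("G", "M")
  grid <- expand.grid(m1 = monomers, m2 = monomers, m3 = monomers,
                      m4 = monomers, stringsAsFactors = FALSE)
  canon <- character(nrow(grid))
  n_m <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    b1 <- paste0(grid$m1[i], grid$m2[i])
    b2 <- paste0(grid$m3[i], grid$m4[i])
    rev2 <- function(b) paste0(substr(b, 2, 2), substr(b, 1, 1))
    images <- c(paste(b1, b2), paste(b2, b1),
                paste(rev2(b1), rev2(b2)), paste(rev2(b2), rev2(b1)))
    canon[i] <- min(images)
    n_m[i] <- sum(strsplit(paste0(b1, b2), "")[[1]] == "M")
  }
  classes <- cell_classes()
  # map canonical configuration strings to the seven labels via block content
  label_of <- function(cfg) {
    blocks <- strsplit(cfg, " ")[[1]]
    key <- function(b) if (b %in% c("GM", "MG")) "GM*" else b
    k <- sort(c(key(blocks[1]), key(blocks[2])))
    if (identical(k, c("GG", "GG"))) return("GG-GG")
    if (identical(k, c("GG", "GM*"))) return("GG-GM/GG-MG")
    if (identical(k, c("GG", "MM"))) return("GG-MM")
    if (identical(k, c("GM*", "GM*"))) {
      # same reading direction (after canonicalization GM GM vs GM MG)
      return(if (blocks[1] == blocks[2]) "GM-GM" else "GM-MG")
    }
    if (identical(k, c("GM*", "MM"))) return("MM-GM/MM-MG")
    "MM-MM"
  }
  labels <- vapply(canon, label_of, character(1))
  if (is_exact(ratio)) {
    p <- ratio$num; q <- ratio$den
    den0 <- (p + q)^4
    nums <- vapply(split(seq_len(16), labels)[classes$label],
                   function(idx) sum(p^n_m[idx] * q^(4 - n_m[idx])),
                   numeric(1))
    fr <- t(vapply(nums, reduce_fraction, numeric(2), den = den0))
    tibble::tibble(label = classes$label,
                   multiplicity = as.integer(table(labels)[classes$label]),
                   probability = unname(fr[, 1] / fr[, 2]),
                   num = unname(fr[, 1]), den = unname(fr[, 2]))
  } else {
    pm <- ratio$p_m; pg <- ratio$p_g
    probs <- pm^n_m * pg^(4 - n_m)
    mass <- vapply(split(probs, labels)[classes$label], sum, numeric(1))
    tibble::tibble(label = classes$label,
                   multiplicity = as.integer(table(labels)[classes$label]),
                   probability = unname(mass))
  }
}

#' Best rational approximation of mu with bounded denominator
#'
#' Probability tables compiled by hand require mu to be a simple fraction;
#' the measured 1.56 was historically approximated by 3/2. This returns the
#' continued-fraction best approximation with denominator at most
#' `max_denominator`.
#'
#' @param mu positive real.
#' @param max_denominator integer >= 1.
#' @return integer vector `c(num, den)`.
#' @export
#' @examples
#' rationalize_mu(1.56, 2)  # 3/2
#' rationalize_mu(1.56, 25) # 39/25
rationalize_mu <- function(mu, max_denominator) {
  stopifnot(mu > 0, max_denominator >= 1)
  # continued-fraction convergents with semiconvergent refinement
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  x <- mu
  best <- c(round(mu), 1)
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_denominator) {
      # largest admissible semiconvergent between (p0,q0) and (p1,q1)
      k <- floor((max_denominator - q0) / q1)
      cands <- list(best)
      if (q1 >= 1 && q1 <= max_denominator) cands <- c(cands, list(c(p1, q1)))
      if (k >= 1) cands <- c(cands, list(c(k * p1 + p0, k * q1 + q0)))
      errs <- vapply(cands, function(f) abs(f[1] / f[2] - mu), numeric(1))
      best <- cands[[which.min(errs)]]
      break
    }
    best <- c(p2, q2)
    if (abs(p2 / q2 - mu) < 1e-12) break
    x <- 1 / (x - a)
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (!is.finite(x)) break
  }
  f <- reduce_fraction(best[1], best[2])
  c(num = unname(f["num"]), den = unname(f["den"]))
}
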