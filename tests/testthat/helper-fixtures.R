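# shared fixtures: reference compositions and small builders

ref_table_path <- function() {
  system.file("extdata", "hydrogel_edx_atomic_percent.csv", package = "eggboxr")
}

ba_raw <- function() {
  elemental_composition("Ba-alg",
    c(C = 51.16, O = 45.81, Ba = 2.74, Na = 0.14, Cl = 0.05,
      Al = 0.06, Si = 0.04))
}

# c12_composition straight from reported two-decimal coefficients
c12_from_coefficients <- function(id, coef, cation) {
  structure(list(sample_id = id,
                 coefficients = c(coef, H = 14),
                 k_c = NA_real_, hydrogen_imputed = TRUE, cation = cation,
                 metadata = list()),
            class = "c12_composition")
}

tmp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# absolute-tolerance comparison for reproducing two-decimal reported values
expect_close <- function(object, expected, tol = 0.0105) {
  expect_lt(abs(object - expected), tol)
}
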