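# shared fixtures and small oracles for the test suite

# bivariate normal lower-orthant probability by nested adaptive quadrature
# of the density (independent numerical oracle for pbvn / tetrachoric);
# accurate on the narrow high-correlation ridge where product-grid
# integrators struggle
bvn_quad2 <- function(h, k, rho, reltol = 1e-11) {
  om <- 1 - rho^2
  dens_slice <- function(x) {
    stats::integrate(function(y)
      exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * om)) /
        (2 * pi * sqrt(om)),
      -8.5, k, rel.tol = reltol, abs.tol = 1e-16)$value
  }
  stats::integrate(Vectorize(dens_slice), -8.5, h, rel.tol = reltol,
                   abs.tol = 1e-15)$value
}

# hand-built three-generation pedigree: grandparent couple (1, 2), their
# full-sib children 3 and 5 married to founders 4 and 6, sibship one =
# {7, 8}, sibship two = {9, 10}, plus 11 = half-sib of {7, 8} via mother 3
# and second partner 12
toy_pedigree <- function() {
  data.frame(
    person_id = 1:12,
    family_id = 1L,
    sex = c("M", "F", "F", "M", "M", "F", "F", "M", "F", "M", "M", "M"),
    birth_year = c(1930L, 1932L, 1958L, 1957L, 1960L, 1961L,
                   1984L, 1986L, 1985L, 1987L, 1990L, 1959L),
    father_id = c(NA, NA, 1L, NA, 1L, NA, 4L, 4L, 5L, 5L, 12L, NA),
    mother_id = c(NA, NA, 2L, NA, 2L, NA, 3L, 3L, 6L, 6L, 3L, NA),
    age_at_death_or_emigration = NA_real_)
}

# diagnosis table exercising every classification branch
toy_diagnoses <- function() {
  data.frame(
    person_id = c(1L, 2L, 2L, 3L, 4L, 4L, 5L, 5L),
    code = c("F32.1",          # 1: non-psychotic MDD only
             "F33.3", "F20",   # 2: psychotic MDD + SCZ
             "F32.3",          # 3: psychotic MDD only
             "F33.0", "F30",   # 4: MDD + bipolar
             "F32.9", "F25"),  # 5: MDD + schizoaffective
    age = c(30, 25, 28, 40, 22, 24, 33, 35))
}

toy_persons6 <- function() {
  data.frame(person_id = 1:6, family_id = 1:6,
             sex = rep(c("F", "M"), 3), birth_year = rep(1970L, 6),
             father_id = NA_integer_, mother_id = NA_integer_,
             age_at_death_or_emigration = NA_real_)
}

# convert simulate_pairs output for one kinship class into the long
# proband-relative dataset used by the aggregation model
pairs_to_long <- function(sim, trait = 1L) {
  n <- nrow(sim$a)
  pairs <- data.frame(person_a = seq_len(n), person_b = n + seq_len(n),
                      family_id = seq_len(n))
  status <- data.frame(person_id = c(pairs$person_a, pairs$person_b),
                       exposed = c(sim$a[, trait], sim$b[, trait]))
  outcome <- data.frame(person_id = status$person_id,
                        affected = status$exposed)
  pair_dataset(pairs, status, outcome)
}
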