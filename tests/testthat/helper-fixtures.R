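# Small fixtures built in code, shared across test files.

toy_lnln <- function(b0 = -2.48, b1 = 2.4835, r2 = 0.98, n_obs = 289,
                     range = c(2.5, 56), group = "mixed_hardwood") {
  allometric_equation("LN_LN", group, list(b0 = b0, b1 = b1),
                      r_squared = r2, n_obs = n_obs, dbh_range = range)
}

toy_crm <- function(a = 0.002, b = 3.6e-5, density = 500, ratio = 0.78,
                    group = "mixed_hardwood") {
  allometric_equation("VOLUME_CRM", group,
                      list(a = a, b = b, wood_density = density,
                           bole_ratio = ratio),
                      r_squared = 0.95, n_obs = 100, dbh_range = c(2.5, 90))
}

toy_trees <- function(n, dbh = NULL, group = "mixed_hardwood",
                      condition = "forest", plot_id = 1L) {
  data.frame(
    plot_id = rep_len(plot_id, n), subplot_id = rep_len(1:4, n),
    condition = rep_len(condition, n),
    species_group = rep_len(group, n), species = rep_len(group, n),
    dbh_cm = dbh %||% seq(8, 40, length.out = n),
    bole_height_m = 5 + 0.3 * (dbh %||% seq(8, 40, length.out = n))
  )
}

# registry with one equation per family for one group, coefficients chosen
# so all three families are exercisable on the same toy trees
toy_registry <- function() {
  equation_registry(list(
    toy_lnln(),
    toy_crm(),
    allometric_equation("SPECIES_SPECIFIC", "mixed_hardwood",
                        list(b0 = -2.36, b1 = 2.49), r_squared = 0.97,
                        n_obs = 120, dbh_range = c(2.5, 60),
                        species = "tulip_poplar")
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

flat_surface <- function(value = 150, n = 12, nonforest = FALSE,
                         pixel = 30) {
  g <- grid_spec(n, n, pixel)
  structure(list(
    grid = g,
    biomass = matrix(value, n, n),
    condition = matrix(if (nonforest) "nonforest" else "forest", n, n),
    params = list()
  ), class = "true_surface")
}

# exhaustive two-sample KS: max over pooled points of |F_a - F_b|
oracle_ks <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}
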