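ALLOMETRIC_FAMILIES <- c("LN_LN", "VOLUME_CRM", "SPECIES_SPECIFIC")

#' Construct an allometric equation
#'
#' An allometric equation predicts whole-tree aboveground biomass (kg, dry
#' weight) from stem measurements. Three families are supported:
#'
#' * `LN_LN`: generalized group equations of the form
#'   `biomass = exp(b0 + b1 * ln(dbh))`, requiring only DBH (cm).
#' * `VOLUME_CRM`: a component-ratio chain — bole volume from a
#'   combined-variable equation `v = a + b * dbh^2 * h` (m^3), converted to
#'   bole dry weight by `wood_density` (kg/m^3) and expanded to the whole
#'   tree by dividing by `bole_ratio`; requires bole height (m).
#' * `SPECIES_SPECIFIC`: ln-ln equations for individual species, resolved
#'   through a registry with a group-level `LN_LN` fallback.
#'
#' @param family one of `"LN_LN"`, `"VOLUME_CRM"`, `"SPECIES_SPECIFIC"`.
#' @param group species group the equation applies to (or falls back to).
#' @param coefficients named list; `b0`, `b1` for ln-ln forms, or `a`, `b`,
#'   `wood_density`, `bole_ratio` for the CRM chain.
#' @param r_squared fit statistic of the source regression, in (0, 1].
#' @param n_obs number of observations behind the source regression (>= 2).
#' @param dbh_range validity range of DBH in cm.
#' @param species species name (SPECIES_SPECIFIC only).
#' @param source free-text provenance note.
#' @return object of class `allometric_equation`.
#' @export
allometric_equation <- function(family, group, coefficients,
                                r_squared = NA_real_, n_obs = NA_integer_,
                                dbh_range = c(2.5, 100), species = NULL,
                                source = NULL) {
  family <- match.arg(family, ALLOMETRIC_FAMILIES)
  if (!is.na(r_squared) && (r_squared <= 0 || r_squared > 1)) {
    stop("r_squared must lie in (0, 1]", call. = FALSE)
  }
  if (!is.na(n_obs) && n_obs < 2) stop("n_obs must be >= 2", call. = FALSE)
  if (family %in% c("LN_LN", "SPECIES_SPECIFIC")) {
    if (!all(c("b0", "b1") %in% names(coefficients))) {
      stop("ln-ln equations need coefficients b0 and b1", call. = FALSE)
    }
  } else {
    need <- c("a", "b", "wood_density", "bole_ratio")
    if (!all(need %in% names(coefficients))) {
      stop("CRM equations need coefficients a, b, wood_density, bole_ratio",
           call. = FALSE)
    }
    if (coefficients$wood_density <= 0) {
      stop("wood_density must be positive", call. = FALSE)
    }
    if (coefficients$bole_ratio <= 0 || coefficients$bole_ratio > 1) {
      stop("bole_ratio must lie in (0, 1]", call. = FALSE)
    }
  }
  if (length(dbh_range) != 2L || dbh_range[1] <= 0 || diff(dbh_range) <= 0) {
    stop("dbh_range must be an increasing positive pair (cm)", call. = FALSE)
  }
  structure(
    list(family = family, group = group, species = species,
         coefficients = lapply(coefficients, as.numeric),
         r_squared = as.numeric(r_squared), n_obs = as.integer(n_obs),
         dbh_range = as.numeric(dbh_range), source = source),
    class = "allometric_equation"
  )
}

#' @export
print.allometric_equation <- function(x, ...) {
  cat(sprintf("<allometric_equation> %s / %s%s; dbh %.3g-%.3g cm; R2 %.3g, n %d\n",
              x$family, x$group,
              if (!is.null(x$species)) paste0(" (", x$species, ")") else "",
              x$dbh_range[1], x$dbh_range[2], x$r_squared, x$n_obs))
  invisible(x)
}

registry_key <- function(family, id) paste(family, id, sep = "::")

#' Build an equation registry
#'
#' The registry keys equations by `(family, group)` — or `(family, species)`
#' for the species-specific family — and implements the substitution rule:
#' when a species lacks its own equation, the generalized `LN_LN` equation of
#' its species group is used instead. The `LN_LN` family must therefore cover
#' every species group that appears in the data.
#'
#' @param equations list of [allometric_equation()] objects.
#' @return object of class `equation_registry`.
#' @seealso [read_equation_registry()], [default_equation_registry()]
#' @export
equation_registry <- function(equations) {
  stopifnot(is.list(equations),
            all(vapply(equations, inherits, TRUE, "allometric_equation")))
  keys <- vapply(equations, function(e) {
    registry_key(e$family,
                 if (e$family == "SPECIES_SPECIFIC") e$species else e$group)
  }, character(1))
  if (anyDuplicated(keys)) stop("duplicate registry keys", call. = FALSE)
  names(equations) <- keys
  # species -> group map for the fallback rule
  sp <- Filter(function(e) e$family == "SPECIES_SPECIFIC", equations)
  species_group <- vapply(sp, function(e) e$group, character(1))
  names(species_group) <- vapply(sp, function(e) e$species, character(1))
  structure(list(equations = equations, species_group = species_group),
            class = "equation_registry")
}

#' @export
print.equation_registry <- function(x, ...) {
  fam <- vapply(x$equations, function(e) e$family, character(1))
  cat("<equation_registry>", length(x$equations), "equations:",
      paste(sprintf("%s=%d", names(table(fam)), table(fam)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Look up an equation in a registry
#'
#' @param registry an [equation_registry()].
#' @param family equation family.
#' @param id group name (or species name for SPECIES_SPECIFIC).
#' @return an [allometric_equation()]; error if absent.
#' @export
lookup_equation <- function(registry, family, id) {
  stopifnot(inherits(registry, "equation_registry"))
  eq <- registry$equations[[registry_key(family, id)]]
  if (is.null(eq)) {
    stop(sprintf("no %s equation for '%s' in registry", family, id),
         call. = FALSE)
  }
  eq
}

#' Read an equation registry from a YAML file
#'
#' Schema: a top-level `equations` list, each entry with `family`, `group`
#' (and `species` for SPECIES_SPECIFIC), `coefficients`, `r_squared`,
#' `n_obs`, `dbh_range`, `source`.
#'
#' @param path YAML file path.
#' @return an [equation_registry()].
#' @export
read_equation_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$equations)) stop("registry file has no 'equations' key", call. = FALSE)
  eqs <- lapply(raw$equations, function(e) {
    allometric_equation(
      family = e$family, group = e$group, coefficients = e$coefficients,
      r_squared = e$r_squared %||% NA_real_, n_obs = e$n_obs %||% NA_integer_,
      dbh_range = unlist(e$dbh_range), species = e$species, source = e$source
    )
  })
  equation_registry(eqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The registry shipped with the package
#'
#' Ten generalized ln-ln group equations plus synthetic default CRM and
#' species-specific coefficient blocks (see the packaged
#' `equations_default.yaml` for provenance notes).
#'
#' @return an [equation_registry()].
#' @export
default_equation_registry <- function() {
  read_equation_registry(
    system.file("extdata", "equations_default.yaml", package = "forestAGB",
                mustWork = TRUE)
  )
}

check_dbh_range <- function(dbh, eq) {
  out <- dbh < eq$dbh_range[1] | dbh > eq$dbh_range[2]
  if (any(out)) {
    warning(sprintf("%d dbh value(s) outside the %s/%s validity range; equation applied anyway",
                    sum(out), eq$family, eq$group), call. = FALSE)
  }
  out
}

#' Predict tree biomass from a generalized ln-ln equation
#'
#' `biomass_kg = exp(b0 + b1 * ln(dbh_cm))`. Out-of-range DBH is allowed but
#' flagged (attribute `out_of_range` and a warning), matching inventory
#' practice of applying the equations to every measured tree.
#'
#' @param dbh DBH in cm (vectorized, > 0).
#' @param eq an `LN_LN` [allometric_equation()].
#' @return biomass in kg with logical attribute `out_of_range`.
#' @export
predict_biomass_lnln <- function(dbh, eq) {
  stopifnot(inherits(eq, "allometric_equation"))
  if (eq$family != "LN_LN" && eq$family != "SPECIES_SPECIFIC") {
    stop("equation is not of the ln-ln form", call. = FALSE)
  }
  if (any(!is.finite(dbh) | dbh <= 0)) stop("dbh must be positive", call. = FALSE)
  out <- check_dbh_range(dbh, eq)
  b <- exp(eq$coefficients$b0 + eq$coefficients$b1 * log(dbh))
  attr(b, "out_of_range") <- out
  b
}

#' Predict tree biomass by the volume-based component-ratio chain
#'
#' Bole volume from the combined-variable form `v = a + b * dbh^2 * h`, bole
#' dry weight `v * wood_density`, whole-tree biomass `bole / bole_ratio`.
#' A missing bole height is a hard error: the measurement is required by this
#' family and is never silently imputed.
#'
#' @param dbh DBH in cm (> 0).
#' @param bole_height stem height to the merchantable top, in m (>= 0).
#' @param eq a `VOLUME_CRM` [allometric_equation()].
#' @return biomass in kg with attribute `out_of_range`.
#' @export
predict_biomass_crm <- function(dbh, bole_height, eq) {
  stopifnot(inherits(eq, "allometric_equation"))
  if (eq$family != "VOLUME_CRM") stop("equation is not VOLUME_CRM", call. = FALSE)
  if (any(!is.finite(dbh) | dbh <= 0)) stop("dbh must be positive", call. = FALSE)
  if (length(bole_height) != length(dbh)) {
    bole_height <- rep_len(bole_height, length(dbh))
  }
  if (any(is.na(bole_height))) {
    stop("bole height is missing for one or more trees; the CRM family requires it",
         call. = FALSE)
  }
  if (any(bole_height < 0)) stop("bole_height must be >= 0", call. = FALSE)
  out <- check_dbh_range(dbh, eq)
  cf <- eq$coefficients
  volume <- cf$a + cf$b * dbh^2 * bole_height
  b <- volume * cf$wood_density / cf$bole_ratio
  attr(b, "out_of_range") <- out
  b
}

#' Predict tree biomass by species, with the group-level substitution rule
#'
#' Uses the species' own equation when the registry has one; otherwise
#' substitutes the generalized `LN_LN` equation of the species' group.
#'
#' @param dbh DBH in cm.
#' @param species species name.
#' @param registry an [equation_registry()].
#' @param group species group, used for the fallback when the registry does
#'   not map this species; optional if the registry knows the species.
#' @return list with `biomass` (kg) and `path` (`"species"` or `"fallback"`).
#' @export
predict_biomass_species <- function(dbh, species, registry, group = NULL) {
  stopifnot(inherits(registry, "equation_registry"), length(species) == 1L)
  key <- registry_key("SPECIES_SPECIFIC", species)
  eq <- registry$equations[[key]]
  if (!is.null(eq)) {
    return(list(biomass = predict_biomass_lnln(dbh, eq), path = "species"))
  }
  grp <- group %||% unname(registry$species_group[species])
  if (is.null(grp) || is.na(grp)) {
    stop(sprintf("species '%s' has no group mapping; cannot fall back", species),
         call. = FALSE)
  }
  eq <- lookup_equation(registry, "LN_LN", grp)
  list(biomass = predict_biomass_lnln(dbh, eq), path = "fallback")
}

#' Predict biomass for a tree table
#'
#' Applies the chosen family row-wise to a tree-record table (columns
#' `species_group`, `dbh_cm`, and `bole_height_m` for CRM; `species` used by
#' the SPECIES_SPECIFIC family when present).
#'
#' @param trees tree-record data.frame.
#' @param family equation family.
#' @param registry an [equation_registry()].
#' @return numeric vector of per-tree biomass (kg).
#' @export
tree_biomass <- function(trees, family = "LN_LN",
                         registry = default_equation_registry()) {
  family <- match.arg(family, ALLOMETRIC_FAMILIES)
  if (nrow(trees) == 0L) return(numeric(0))
  check_tree_table(trees, require_height = family == "VOLUME_CRM")
  out <- numeric(nrow(trees))
  if (family == "SPECIES_SPECIFIC") {
    sp <- if ("species" %in% names(trees)) trees$species else trees$species_group
    for (s in unique(sp)) {
      i <- sp == s
      grp <- unique(trees$species_group[i])[1]
      out[i] <- predict_biomass_species(trees$dbh_cm[i], s, registry,
                                        group = grp)$biomass
    }
  } else {
    for (g in unique(trees$species_group)) {
      i <- trees$species_group == g
      eq <- lookup_equation(registry, family, g)
      out[i] <- if (family == "LN_LN") {
        as.numeric(predict_biomass_lnln(trees$dbh_cm[i], eq))
      } else {
        as.numeric(predict_biomass_crm(trees$dbh_cm[i], trees$bole_height_m[i], eq))
      }
    }
  }
  out
}

#' Plot-level biomass density
#'
#' Sums per-tree biomass (kg), converts to Mg and expands by the sampled
#' area: `Mg/ha = sum(kg) / 1000 / (area_m2 / 10000)`. An empty tree list is
#' a measured zero, not missing data.
#'
#' @param trees tree-record data.frame (possibly 0 rows).
#' @param sampled_area sampled area in m^2 (> 0).
#' @param family equation family.
#' @param registry an [equation_registry()].
#' @return biomass density in Mg/ha.
#' @export
plot_biomass_density <- function(trees, sampled_area, family = "LN_LN",
                                 registry = default_equation_registry()) {
  if (length(sampled_area) != 1L || !is.finite(sampled_area) || sampled_area <= 0) {
    stop("sampled_area must be a single positive number of m^2", call. = FALSE)
  }
  if (nrow(trees) == 0L) return(0)
  kg <- tree_biomass(trees, family = family, registry = registry)
  sum(kg) / 1000 / (sampled_area / 10000)
}

#' Percent difference between two estimates
#'
#' `100 * (a - b) / b`: how much `a` exceeds the base `b`, in percent.
#'
#' @param a,b numeric values (b != 0).
#' @return percent difference.
#' @export
percent_difference <- function(a, b) {
  if (any(b == 0)) stop("base value must be nonzero", call. = FALSE)
  100 * (a - b) / b
}

#' Compare plot-mean biomass across allometric families
#'
#' Computes per-plot biomass density under each requested family, then the
#' across-plot mean and standard deviation per family and all pairwise
#' percent differences of the means (`100 * (A - B) / B`).
#'
#' @param plots list of tree-record data.frames, one per plot.
#' @param registry an [equation_registry()].
#' @param sampled_area sampled area per plot (m^2); scalar or vector.
#' @param families families to compare.
#' @return list with `table` (family, mean_mgha, sd_mgha, n_plots) and
#'   `pairwise` (family_a, family_b, pct_difference).
#' @export
compare_allometry_choices <- function(plots,
                                      registry = default_equation_registry(),
                                      sampled_area = 670,
                                      families = ALLOMETRIC_FAMILIES) {
  stopifnot(is.list(plots), length(plots) >= 1L)
  area <- rep_len(sampled_area, length(plots))
  dens <- sapply(families, function(fam) {
    vapply(seq_along(plots), function(i) {
      plot_biomass_density(plots[[i]], area[i], family = fam, registry = registry)
    }, numeric(1))
  })
  dens <- matrix(dens, ncol = length(families),
                 dimnames = list(NULL, families))
  tab <- data.frame(
    family = families,
    mean_mgha = colMeans(dens),
    sd_mgha = apply(dens, 2L, stats::sd),
    n_plots = length(plots),
    row.names = NULL
  )
  pairs <- expand.grid(family_a = families, family_b = families,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$family_a != pairs$family_b, , drop = FALSE]
  pairs$pct_difference <- percent_difference(
    tab$mean_mgha[match(pairs$family_a, tab$family)],
    tab$mean_mgha[match(pairs$family_b, tab$family)]
  )
  rownames(pairs) <- NULL
  list(table = tab, pairwise = pairs, densities = dens)
}
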