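#' Allometric equation registry
#'
#' Species-specific biomass equations are configuration, not code: each entry
#' maps a `(species, component)` pair to a power-law biomass model and a
#' carbon conversion factor. Supported forms: `"power"`,
#' \eqn{AGB = a x^b} with \eqn{x} the chosen predictor (height in m, DBH or
#' basal diameter in cm), and `"d2h"`, \eqn{a (d^2 h)^b}.
#'
#' @return an empty registry (class `"allometry_registry"`).
#' @export
allometry_registry <- function() {
  structure(list(equations = list()), class = "allometry_registry")
}

#' Register an allometric equation
#'
#' @param registry an `allometry_registry`.
#' @param species species label.
#' @param component `"above_ground"` or `"below_ground"`.
#' @param predictor `"height"`, `"dbh"`, `"basal_diameter"` or
#'   `"dbh_height"` (for the `d2h` form).
#' @param form `"power"` or `"d2h"`.
#' @param a,b power-law parameters, `a > 0`; biomass in kg per tree.
#' @param carbon_factor biomass-to-carbon fraction in `(0, 1]`.
#' @return the updated registry.
#' @export
register_equation <- function(registry, species, component, predictor,
                              form = "power", a, b, carbon_factor = 0.46) {
  stopifnot(inherits(registry, "allometry_registry"),
            component %in% c("above_ground", "below_ground"),
            form %in% c("power", "d2h"),
            a > 0, carbon_factor > 0, carbon_factor <= 1)
  key <- paste(species, component, sep = "|")
  if (!is.null(registry$equations[[key]])) {
    stop("duplicate equation for (", species, ", ", component, ")",
         call. = FALSE)
  }
  registry$equations[[key]] <- list(species = species, component = component,
                                    predictor = predictor, form = form,
                                    a = a, b = b,
                                    carbon_factor = carbon_factor)
  registry
}

#' Look up an equation
#' @inheritParams register_equation
#' @return the equation entry (list).
#' @export
lookup_equation <- function(registry, species, component) {
  eq <- registry$equations[[paste(species, component, sep = "|")]]
  if (is.null(eq)) {
    stop("no allometric equation registered for (", species, ", ", component,
         ")", call. = FALSE)
  }
  eq
}

#' Read / write a registry as JSON
#'
#' Schema: an array of objects with fields `species`, `component`,
#' `predictor`, `form`, `a`, `b`, `carbon_factor`.
#'
#' @param path JSON file path.
#' @param registry an `allometry_registry`.
#' @return `read_allometry()` returns a registry; `write_allometry()` the
#'   path, invisibly.
#' @export
read_allometry <- function(path) {
  entries <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  reg <- allometry_registry()
  for (e in entries) {
    reg <- register_equation(reg, e$species, e$component, e$predictor,
                             e$form, e$a, e$b, e$carbon_factor)
  }
  reg
}

#' @rdname read_allometry
#' @export
write_allometry <- function(registry, path) {
  jsonlite::write_json(unname(registry$equations), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Shipped example registry
#'
#' Height-based power laws (\eqn{AGB = a h^2}, carbon factor 0.46) for the
#' four mangrove species, calibrated so that simulated plots reproduce the
#' ground-survey community AGC/BGC means (e.g. *R. stylosa* AGC around
#' 96 t/hm²) at the community densities and height distributions of
#' [default_signatures()]. These are synthetic stand-ins with the same form
#' as published species-specific equations; users with locally calibrated
#' equations should load their own JSON via [read_allometry()].
#'
#' @return an `allometry_registry`.
#' @export
default_allometry <- function() {
  path <- system.file("extdata", "allometry_default.json",
                      package = "mangroveCarbon")
  read_allometry(path)
}

#' Per-tree biomass from an allometric equation
#'
#' Multi-stemmed trees are treated as `stem_count` individuals of the
#' recorded diameter (each stem measured separately).
#'
#' @param tree one-row data.frame or list with `height` (m) and, as the
#'   equation requires, `dbh` / `basal_diameter` (cm); optional `stem_count`.
#' @param eq equation entry from [lookup_equation()].
#' @return biomass in kg.
#' @export
tree_biomass <- function(tree, eq) {
  x <- switch(eq$predictor,
    height = tree$height,
    dbh = tree$dbh,
    basal_diameter = tree$basal_diameter,
    dbh_height = tree$dbh^2 * tree$height,
    stop("unknown predictor: ", eq$predictor, call. = FALSE)
  )
  if (is.null(x) || any(is.na(x))) {
    stop("tree record lacks predictor '", eq$predictor, "'", call. = FALSE)
  }
  stems <- if (is.null(tree$stem_count)) 1 else tree$stem_count
  stems * eq$a * x^eq$b
}

#' Convert plot carbon between kg/plot and t/hm²
#'
#' \eqn{t\,hm^{-2} = kg \times 10^4 / area_{m^2} / 10^3}.
#'
#' @param kg carbon mass per plot (kg).
#' @param t_hm2 carbon density (t/hm²).
#' @param plot_area plot area (m²).
#' @return converted value.
#' @export
kg_plot_to_t_hm2 <- function(kg, plot_area) kg * 10 / plot_area

#' @rdname kg_plot_to_t_hm2
#' @export
t_hm2_to_kg_plot <- function(t_hm2, plot_area) t_hm2 * plot_area / 10

#' Plot-level carbon from tree records
#'
#' Sums per-tree biomass through the species' above- and below-ground
#' equations, applies the carbon conversion factors, and normalizes from
#' kg per plot to t/hm².
#'
#' @param trees data.frame of tree records (`height`, `dbh`,
#'   `basal_diameter`, `stem_count`).
#' @param species species label (routes the equations).
#' @param registry an `allometry_registry`.
#' @param plot_area plot area (m²), default 25.
#' @return list with `agc`, `bgc` (t/hm²) and `tree_count`.
#' @export
plot_carbon <- function(trees, species, registry, plot_area = 25) {
  comp <- function(component) {
    eq <- lookup_equation(registry, species, component)
    if (nrow(trees) == 0) return(0)
    kg <- sum(vapply(seq_len(nrow(trees)),
                     function(i) tree_biomass(trees[i, ], eq), numeric(1)))
    kg_plot_to_t_hm2(eq$carbon_factor * kg, plot_area)
  }
  list(agc = comp("above_ground"), bgc = comp("below_ground"),
       tree_count = if (nrow(trees)) sum(trees$stem_count) else 0L)
}
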