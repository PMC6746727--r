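#' X-ray mass-attenuation tables with absorption-edge handling
#'
#' The package ships mass-attenuation coefficient tables (15--60 keV) for the
#' elements and compounds used in the simulated experiment, derived from
#' Cromer--Liberman photoelectric cross-sections plus form-factor
#' coherent/incoherent scattering (see `data-raw/make_attenuation_tables.py`).
#' Absorption edges inside the energy window are represented by a duplicated
#' energy row: the first row carries the below-edge value, the second the
#' above-edge value.  `attenuation_table()` loads one table and validates its
#' invariants.
#'
#' @param name Table name, e.g. `"iodine"`, `"water"`, `"whewellite"`.
#'   `list_attenuation_tables()` lists everything that is packaged.
#' @return An object of class `attenuation_table`: a list with `material`,
#'   `energy` (keV, non-decreasing), `mu_over_rho` (cm^2/g) and `edges`
#'   (duplicated edge energies, keV).
#' @examples
#' tab <- attenuation_table("iodine")
#' tab$edges   # the K edge at 33.1694 keV
#' @export
attenuation_table <- function(name) {
  path <- system.file("extdata", "attenuation", paste0(name, ".tsv"),
                      package = "kesct")
  if (path == "")
    stop("unknown material table: '", name, "'", call. = FALSE)
  d <- read.delim(path)
  e <- d$energy_keV
  v <- d$mu_over_rho_cm2_g
  if (any(diff(e) < 0)) stop("energies must be non-decreasing in ", name)
  if (any(v <= 0)) stop("non-positive mu/rho in ", name)
  dup <- e[duplicated(e)]
  if (any(table(e) > 2)) stop("energy appears more than twice in ", name)
  structure(list(material = name, energy = e, mu_over_rho = v,
                 edges = dup),
            class = "attenuation_table")
}

#' @rdname attenuation_table
#' @export
list_attenuation_tables <- function() {
  dir <- system.file("extdata", "attenuation", package = "kesct")
  sub("\\.tsv$", "", setdiff(list.files(dir, pattern = "\\.tsv$"),
                             "air_mu_en.tsv"))
}

#' Iodine K-edge energy
#'
#' @return The iodine K-shell binding energy in keV (33.1694).
#' @export
iodine_k_edge <- function() 33.1694

# --- material registry ------------------------------------------------------

default_densities <- function() c(
  iodine = 4.93, water = 0.998, air = 1.2929e-3, soft_tissue = 1.06,
  whewellite = 2.23, weddellite = 1.94, pvp = 1.2, calcium = 1.55,
  gadolinium = 7.90, carbon = 2.266, hydrogen = 8.375e-5, oxygen = 1.429e-3)

materials_registry <- function() {
  if (is.null(.kesct$materials)) {
    .kesct$materials <- new.env(parent = emptyenv())
    dens <- default_densities()
    for (nm in names(dens))
      assign(nm, material(nm, density = dens[[nm]], table = nm),
             envir = .kesct$materials)
  }
  .kesct$materials
}

#' Materials: density plus attenuation table or mixture composition
#'
#' A material couples a mass density with either a packaged attenuation
#' table or a mass-fraction-weighted mixture of other materials.  All
#' built-in materials (see [list_attenuation_tables()]) are pre-registered
#' with standard densities; `kes_material()` fetches one by name.
#'
#' @param name Material name.
#' @param density Mass density in g/cm^3 (>= 0).
#' @param table Name of the packaged attenuation table backing this
#'   material (defaults to `name`); ignored when `components` is given.
#' @param components For mixtures, a list of materials (or names); see
#'   [make_mixture()].
#' @param fractions Mass fractions matching `components`; must sum to 1.
#' @return An object of class `kesct_material`.
#' @export
material <- function(name, density, table = name, components = NULL,
                     fractions = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density < 0)
    stop("density must be a single non-negative number", call. = FALSE)
  if (is.null(components)) {
    obj <- list(name = name, density = density, table = table,
                components = NULL, fractions = NULL)
  } else {
    components <- lapply(components, function(m)
      if (is.character(m)) kes_material(m) else m)
    if (length(components) != length(fractions))
      stop("components and fractions lengths differ", call. = FALSE)
    if (any(fractions < 0 | fractions > 1))
      stop("mass fractions must lie in [0, 1]", call. = FALSE)
    if (abs(sum(fractions) - 1) > 1e-9)
      stop("mass fractions must sum to 1 (got ", sum(fractions), ")",
           call. = FALSE)
    obj <- list(name = name, density = density, table = NULL,
                components = components, fractions = fractions)
  }
  structure(obj, class = "kesct_material")
}

#' @rdname material
#' @export
kes_material <- function(name) {
  reg <- materials_registry()
  if (!exists(name, envir = reg, inherits = FALSE))
    stop("unknown material: '", name, "'", call. = FALSE)
  get(name, envir = reg, inherits = FALSE)
}

#' @rdname material
#' @param mat A `kesct_material` to (re-)register under its name.
#' @export
register_material <- function(mat) {
  stopifnot(inherits(mat, "kesct_material"))
  assign(mat$name, mat, envir = materials_registry())
  invisible(mat)
}

#' @export
print.kesct_material <- function(x, ...) {
  cat("<kesct_material> ", x$name, "  density ", x$density, " g/cm^3\n",
      sep = "")
  if (!is.null(x$components))
    cat("  mixture of:",
        paste(sprintf("%s (%.3g)", vapply(x$components, `[[`, "", "name"),
                      x$fractions), collapse = ", "), "\n")
  invisible(x)
}

# --- interpolation ----------------------------------------------------------

# log(E)-log(mu/rho) interpolation within edge-free segments.  At an energy
# that is exactly a stored node the *first* occurrence is returned, so a
# duplicated edge energy yields the below-edge branch; any energy strictly
# above the edge interpolates from the above-edge row.
interp_table <- function(tab, energy) {
  e <- tab$energy; v <- tab$mu_over_rho
  if (any(energy < e[1] - 1e-12 | energy > e[length(e)] + 1e-12))
    stop("energy outside table range [", e[1], ", ", e[length(e)],
         "] keV for ", tab$material, call. = FALSE)
  energy <- pmin(pmax(energy, e[1]), e[length(e)])
  out <- numeric(length(energy))
  exact <- match(energy, e)                       # first occurrence
  hit <- !is.na(exact)
  out[hit] <- v[exact[hit]]
  if (any(!hit)) {
    q <- energy[!hit]
    lo <- findInterval(q, e)                      # largest i with e[i] <= q
    hi <- lo + 1L
    w <- (log(q) - log(e[lo])) / (log(e[hi]) - log(e[lo]))
    out[!hit] <- exp((1 - w) * log(v[lo]) + w * log(v[hi]))
  }
  out
}

table_cache <- function(name) {
  if (is.null(.kesct$tables)) .kesct$tables <- new.env(parent = emptyenv())
  if (!exists(name, envir = .kesct$tables, inherits = FALSE))
    assign(name, attenuation_table(name), envir = .kesct$tables)
  get(name, envir = .kesct$tables, inherits = FALSE)
}

#' Mass and linear attenuation coefficients
#'
#' `mass_attenuation()` evaluates mu/rho (cm^2/g) for a material at one or
#' more energies by log-log interpolation of the packaged tables, with
#' correct branch selection at absorption edges (a query exactly at the edge
#' energy returns the below-edge value; any energy strictly above uses the
#' above-edge branch; interpolation never crosses the duplicated edge pair).
#' For mixtures the mass-fraction-weighted sum of the component coefficients
#' is returned.  `linear_attenuation()` multiplies by the material density
#' and converts to 1/mm.
#'
#' @param material A `kesct_material`, or the name of a registered material.
#' @param energy Photon energies in keV (vectorised); must lie within the
#'   packaged table range, 15--60 keV.
#' @return `mass_attenuation()`: mu/rho in cm^2/g; `linear_attenuation()`:
#'   mu in 1/mm.
#' @examples
#' mass_attenuation("iodine", c(33.0, 33.5))  # below vs above the K edge
#' linear_attenuation("water", 33.18)
#' @export
mass_attenuation <- function(material, energy) {
  if (is.character(material)) material <- kes_material(material)
  stopifnot(inherits(material, "kesct_material"))
  if (is.null(material$components))
    return(interp_table(table_cache(material$table), energy))
  out <- 0
  for (i in seq_along(material$components))
    out <- out + material$fractions[i] *
      mass_attenuation(material$components[[i]], energy)
  out
}

#' @rdname mass_attenuation
#' @export
linear_attenuation <- function(material, energy) {
  if (is.character(material)) material <- kes_material(material)
  mass_attenuation(material, energy) * material$density / 10
}

#' Mass-fraction mixtures
#'
#' Builds a mixture material whose mu/rho at any energy is the
#' mass-fraction-weighted sum of its components' mu/rho.  The mixture
#' density is supplied by the caller (it is not derivable from the
#' fractions).
#'
#' @param components List of `kesct_material` objects or registered names.
#' @param fractions Mass fractions in [0, 1], summing to 1 (tolerance 1e-9).
#' @param name Name for the mixture.
#' @param density Mixture mass density, g/cm^3.
#' @return A `kesct_material`.
#' @examples
#' stone <- make_mixture(c("whewellite", "weddellite"), c(0.9, 0.1),
#'                       "caox_stone", density = 2.2)
#' @export
make_mixture <- function(components, fractions, name = "mixture", density) {
  material(name, density = density, components = as.list(components),
           fractions = fractions)
}

#' Iodinated water (contrast-agent solution)
#'
#' Models iodine dissolved in water at a given concentration: the solute
#' adds its areal density on top of unchanged water, so the linear
#' attenuation is `(mu/rho)_I * C + (mu/rho)_w * rho_w` with `C` in g/ml.
#'
#' @param mg_per_ml Iodine concentration in mg/ml (> 0).
#' @return A `kesct_material` mixture of iodine and water with density
#'   `rho_w + C`.
#' @export
iodinated_water <- function(mg_per_ml) {
  stopifnot(mg_per_ml > 0)
  C <- mg_per_ml / 1000
  rho_w <- kes_material("water")$density
  rho <- rho_w + C
  make_mixture(c("iodine", "water"), c(C / rho, rho_w / rho),
               name = sprintf("iodinated_water_%gmgml", mg_per_ml),
               density = rho)
}
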