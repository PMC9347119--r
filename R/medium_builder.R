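#' Construct a medium recipe
#'
#' A `medium_recipe` is a table of chemical components with their
#' concentrations in mmol/L, plus the id of the water entry. Concentrations
#' act as *relative* weights when converted to uptake bounds (see
#' [recipe_to_bounds()]); no volumetric-to-specific conversion is applied.
#'
#' @param components Data frame with columns `compound_id`, `name`,
#'   `concentration` (mmol/L, strictly positive).
#' @param water_id The `compound_id` of water (default `"h2o"`), which must
#'   be present among the components.
#' @return A `medium_recipe`.
#' @export
medium_recipe <- function(components, water_id = "h2o") {
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  stopifnot(all(c("compound_id", "name", "concentration") %in%
                  names(components)))
  if (nrow(components) == 0) stop("empty recipe", call. = FALSE)
  if (any(components$concentration <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (!water_id %in% components$compound_id) {
    stop("water_id '", water_id, "' not among the components", call. = FALSE)
  }
  structure(list(components = components, water_id = water_id),
            class = "medium_recipe")
}

#' Read a medium recipe from a TSV/CSV file
#'
#' Expects columns `compound_id`, `name` and either `concentration_mmol_per_L`
#' (the default, scaled through [recipe_to_bounds()]) or, with
#' `column_mode = "maxflux"`, a `MaxFlux` column whose values are used
#' verbatim as uptake bounds downstream.
#'
#' @param path File path; the delimiter is inferred from the extension.
#' @param water_id Compound id of water.
#' @param column_mode `"concentration"` or `"maxflux"`.
#' @return A `medium_recipe`; with `column_mode = "maxflux"` the returned
#'   recipe carries an attribute `bounds` holding the verbatim fluxes.
#' @export
read_medium_recipe <- function(path, water_id = "h2o",
                               column_mode = c("concentration", "maxflux")) {
  column_mode <- match.arg(column_mode)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[tolower(names(df)) %in% c("compounds", "compound_id")] <- "compound_id"
  names(df)[tolower(names(df)) == "name"] <- "name"
  if (column_mode == "maxflux") {
    fluxcol <- names(df)[tolower(names(df)) == "maxflux"]
    if (!length(fluxcol)) stop("no MaxFlux column in ", path, call. = FALSE)
    df$concentration <- df[[fluxcol[1]]]
    rec <- medium_recipe(df[, c("compound_id", "name", "concentration")],
                         water_id = water_id)
    attr(rec, "bounds") <- stats::setNames(df[[fluxcol[1]]], df$compound_id)
    rec
  } else {
    conc <- names(df)[tolower(names(df)) %in%
                        c("concentration_mmol_per_l", "concentration")]
    if (!length(conc)) {
      stop("no concentration column in ", path, call. = FALSE)
    }
    df$concentration <- df[[conc[1]]]
    medium_recipe(df[, c("compound_id", "name", "concentration")],
                  water_id = water_id)
  }
}

#' Convert a medium recipe into uptake bounds
#'
#' Water is allowed an uptake of 1000 mmol/gDW/h. Every other component is
#' scaled linearly by its concentration relative to the most concentrated
#' non-water solute and clamped into the band \[1, 100\] mmol/gDW/h:
#' \eqn{b_i = \mathrm{clamp}(100\, c_i / c_{\max}, 1, 100)}. The map is
#' invariant to rescaling all concentrations by a common factor.
#'
#' @param recipe A [medium_recipe()]. If the recipe carries verbatim fluxes
#'   (read with `column_mode = "maxflux"`), those are returned unchanged.
#' @return A named numeric vector (`medium_bounds`): compound id ->
#'   maximum uptake flux in mmol/gDW/h.
#' @export
recipe_to_bounds <- function(recipe) {
  stopifnot(inherits(recipe, "medium_recipe"))
  verbatim <- attr(recipe, "bounds")
  if (!is.null(verbatim)) return(verbatim)
  comp <- recipe$components
  non_water <- comp[comp$compound_id != recipe$water_id, , drop = FALSE]
  if (nrow(non_water) == 0) {
    stop("recipe needs at least one non-water component", call. = FALSE)
  }
  c_max <- max(non_water$concentration)
  b <- pmin(pmax(100 * non_water$concentration / c_max, 1), 100)
  out <- stats::setNames(c(1000, b),
                         c(recipe$water_id, non_water$compound_id))
  out[comp$compound_id]
}

#' Apply medium bounds to a community model
#'
#' Sets the uptake (lower) bound of each community exchange to the negative
#' of its medium bound. Environment metabolites without a medium entry get
#' an import bound of zero -- export to the medium remains permitted, which
#' is what lets fermentation products leave while reproducing a defined
#' growth medium. Medium components without a matching community exchange
#' trigger a warning, not an error, since species models need not consume
#' every trace element. Applying the same bounds twice is a no-op.
#'
#' @param community A `community_model`.
#' @param bounds Named vector from [recipe_to_bounds()].
#' @return A new `community_model`; the input is not modified.
#' @export
apply_medium <- function(community, bounds) {
  stopifnot(inherits(community, "community_model"))
  ex <- community_exchanges(community)
  missing <- setdiff(names(bounds), ex$metabolite)
  if (length(missing)) {
    warning("medium components without a community exchange: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(ex))) {
    m <- ex$metabolite[i]
    lb <- if (m %in% names(bounds)) -bounds[[m]] else 0
    community <- set_community_exchange_bounds(community, m, lb = lb)
  }
  community
}
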