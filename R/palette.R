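#' Default land-cover nomenclature
#'
#' The 16-class sub-nomenclature used for dry-tropical coastal landscapes such
#' as the Mahavavy-Kinkony Complex: village, three crop classes, savannah, two
#' dry-forest density classes, three mangrove classes, shrubland, barren land,
#' tan (coastal geological flats), two wetland vegetation classes and inland
#' water. Class ids follow the convention that a sub-class id appends one digit
#' to its parent basic-class id (e.g. 61, 62 under basic class 6, forest).
#'
#' @return A data frame with columns `class_id` (integer), `class_name`
#'   (character) and `basic_class` (integer parent id).
#' @export
#' @examples
#' default_palette()
default_palette <- function() {
  data.frame(
    class_id = c(11L, 21L, 31L, 41L, 51L, 61L, 62L, 63L, 64L, 65L,
                 71L, 101L, 102L, 121L, 122L, 131L),
    class_name = c("Village", "Rice field", "Sugar-cane field", "Crops field",
                   "Savannah", "Dense dry forest", "Sparse dry forest",
                   "Dense mangrove", "Scattered mangrove", "Stunted mangrove",
                   "Shrubland", "Barren land", "Tan", "Phragmites", "Raffia",
                   "Water bodies"),
    basic_class = c(1L, 2L, 3L, 4L, 5L, 6L, 6L, 6L, 6L, 6L,
                    7L, 10L, 10L, 12L, 12L, 13L),
    stringsAsFactors = FALSE
  )
}

#' Default per-class biophysical parameters
#'
#' Stylized per-class parameters used by the synthetic-scene generator and the
#' carbon/infrastructure accounts: aboveground biomass carbon density (tC/ha),
#' litter fraction of aboveground stock, root:shoot ratio, soil organic carbon
#' density (tC/ha), net primary production (tC/ha/yr), a greenness weight on
#' the 0-100 scale used by the green background landscape index, and a tree
#' flag marking woody habitat classes (used for fragmentation and roundwood).
#'
#' Values are order-of-magnitude choices for a dry-tropical mosaic (dense dry
#' forest ~90 tC/ha aboveground, mangroves higher including soil pools,
#' savannah and crops low); they are deliberately configurable, not
#' measurements.
#'
#' @return Data frame keyed by `class_id`.
#' @export
default_class_params <- function() {
  p <- default_palette()
  params <- data.frame(
    class_id   = p$class_id,
    greenness  = c(10, 45, 55, 50, 65, 95, 80, 100, 85, 80,
                   70, 5, 15, 75, 85, 20),
    agb_tc_ha  = c(5, 3, 15, 5, 8, 90, 45, 120, 60, 25,
                   15, 0, 1, 10, 40, 0.5),
    litter_frac = c(0.10, 0.05, 0.08, 0.08, 0.12, 0.12, 0.12, 0.12, 0.12, 0.12,
                    0.10, 0, 0, 0.10, 0.10, 0),
    root_shoot = c(0.30, 0.30, 0.20, 0.30, 0.80, 0.45, 0.45, 0.50, 0.50, 0.50,
                   0.60, 0, 0.20, 0.50, 0.40, 0),
    soc_tc_ha  = c(30, 40, 45, 40, 35, 60, 50, 120, 100, 80,
                   40, 10, 15, 70, 90, 5),
    npp_tc_ha  = c(2, 5, 12, 6, 4, 7, 5, 9, 7, 5,
                   4, 0.2, 0.5, 6, 7, 1),
    tree = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
             TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  params
}

#' SELU types in tie-break priority order
#'
#' The seven socio-ecological landscape unit types. The order is the
#' deterministic tie-break used when two land-cover groups hold exactly the
#' same area inside a watershed: natural classes win over anthropic ones.
#'
#' @return Character vector of the seven SELU type names, highest priority
#'   first.
#' @export
selu_types <- function() {
  c("Forest landscape", "Mangrove Landscape", "Wetland", "Shrubland",
    "Agricultural landscape", "Estuary", "Human footprint")
}

#' Default class-to-SELU grouping table
#'
#' Maps every land-cover class of [default_palette()] to the SELU group whose
#' dominance defines the unit type: village to Human footprint; rice,
#' sugar-cane and mixed crops to Agricultural landscape; savannah and
#' shrubland to Shrubland; both dry-forest densities to Forest landscape; all
#' mangrove classes to Mangrove Landscape; raffia, phragmites and inland water
#' to Wetland; tan and barren land (coastal flats) to Estuary. Fully
#' overridable: pass any data frame with `class_id` and `group` columns to the
#' SELU builders.
#'
#' @return Data frame with columns `class_id` and `group`.
#' @export
default_grouping <- function() {
  data.frame(
    class_id = c(11L, 21L, 31L, 41L, 51L, 61L, 62L, 63L, 64L, 65L,
                 71L, 101L, 102L, 121L, 122L, 131L),
    group = c("Human footprint",
              "Agricultural landscape", "Agricultural landscape",
              "Agricultural landscape",
              "Shrubland",
              "Forest landscape", "Forest landscape",
              "Mangrove Landscape", "Mangrove Landscape", "Mangrove Landscape",
              "Shrubland",
              "Estuary", "Estuary",
              "Wetland", "Wetland", "Wetland"),
    stringsAsFactors = FALSE
  )
}

check_grouping <- function(grouping, class_ids) {
  missing <- setdiff(class_ids, grouping$class_id)
  if (length(missing) > 0L) {
    stop("grouping table has no entry for class id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(grouping$group), selu_types())
  if (length(bad) > 0L) {
    stop("unknown SELU group(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(grouping)
}
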