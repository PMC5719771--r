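# Layered slab phantoms.

#' Construct a slab phantom
#'
#' An ordered stack of homogeneous slabs traversed by the beam, entrance
#' surface first.
#'
#' @param materials character vector of packaged material names (or a list of
#'   [material()] objects)
#' @param thicknesses slab thicknesses in cm (all > 0)
#' @param densities optional per-slab density overrides (g/cm^3)
#' @return object of class `phantom_stack` with fields `slabs` (data.frame:
#'   material, thickness_cm, density), `materials` (list) and `total_depth`
#' @export
phantom_stack <- function(materials, thicknesses, densities = NULL) {
  if (is.character(materials)) {
    mats <- lapply(materials, get_material)
  } else {
    mats <- materials
    materials <- vapply(mats, function(m) m$name, character(1))
  }
  stopifnot(length(mats) == length(thicknesses))
  if (any(thicknesses <= 0)) stop("slab thicknesses must be > 0")
  if (is.null(densities))
    densities <- vapply(mats, function(m) m$density, numeric(1))
  for (i in seq_along(mats)) mats[[i]]$density <- densities[i]
  structure(list(
    slabs = data.frame(material = materials, thickness_cm = thicknesses,
                       density = densities, stringsAsFactors = FALSE),
    materials = mats,
    total_depth = sum(thicknesses)
  ), class = "phantom_stack")
}

#' @export
print.phantom_stack <- function(x, ...) {
  cat(sprintf("<phantom_stack> %d slabs, total depth %.1f cm\n",
              nrow(x$slabs), x$total_depth))
  print(x$slabs)
  invisible(x)
}

#' The reference thorax phantom
#'
#' 5 cm acrylic (PMMA) over 13 cm lung-equivalent material over 10 cm acrylic
#' (28 cm total; interfaces at 5 and 18 cm).
#'
#' @param lung_density lung/cork density in g/cm^3 (default 0.26)
#' @return a [phantom_stack()]
#' @export
make_reference_phantom <- function(lung_density = 0.26) {
  phantom_stack(c("pmma", "lung", "pmma"), c(5, 13, 10),
                densities = c(1.19, lung_density, 1.19))
}

#' Depths of the slab interfaces of a phantom (cm, excluding outer surfaces)
#' @param phantom a [phantom_stack()]
#' @return numeric vector
#' @export
interface_depths <- function(phantom) {
  cs <- cumsum(phantom$slabs$thickness_cm)
  cs[-length(cs)]
}

# index of the slab containing depth d (0 <= d <= total_depth);
# points exactly on an interface belong to the deeper slab
.slab_index <- function(phantom, d) {
  tops <- c(0, cumsum(phantom$slabs$thickness_cm))
  i <- findInterval(d, tops, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), nrow(phantom$slabs))
}

#' Material name at a given depth
#' @param phantom a [phantom_stack()]
#' @param d depth in cm (vectorized)
#' @return character vector of material names
#' @export
material_at_depth <- function(phantom, d) {
  if (any(d < 0 | d > phantom$total_depth)) stop("depth outside phantom")
  phantom$slabs$material[.slab_index(phantom, d)]
}

#' Radiological (water-equivalent) depth along the beam axis
#'
#' Integral of relative electron density from the entrance surface to `d`.
#'
#' @param phantom a [phantom_stack()]
#' @param d depth in cm (vectorized)
#' @return water-equivalent depth in cm
#' @export
radiological_depth <- function(phantom, d) {
  if (any(d < 0 | d > phantom$total_depth + 1e-9)) stop("depth outside phantom")
  red <- vapply(phantom$materials, rel_electron_density, numeric(1))
  tops <- c(0, cumsum(phantom$slabs$thickness_cm))
  vapply(d, function(di) {
    seg <- pmax(0, pmin(di, tops[-1]) - tops[-length(tops)])
    sum(seg * red)
  }, numeric(1))
}
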