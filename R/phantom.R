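# Table of study materials: the 15 contrast/biological elements with the
# concentrations used in the threshold-sweep study (Ca and Fe at the higher
# concentrations typical of dual-energy phantom inserts, all others matched
# to the clinical iodine level of 4 mg/mL).
.STUDY_CONCENTRATIONS <- c(
  Ca = 50, Fe = 30, I = 4, Ba = 4, Sm = 4, Eu = 4, Gd = 4, Tb = 4,
  Yb = 4, Lu = 4, Ta = 4, W = 4, Pt = 4, Au = 4, Bi = 4)

#' Construct an analytic cylindrical phantom
#'
#' A phantom is a water (or other background) cylinder of given radius with
#' non-overlapping circular inserts, each bound to a [ct_material()].
#' Geometry is analytic (circles), so forward projection uses exact chord
#' lengths.
#'
#' @param inserts A tibble/data.frame with columns `label`, `x_cm`, `y_cm`,
#'   `radius_cm`, `solute`, `concentration_mg_per_mL` (solute `NA` for a
#'   water insert).
#' @param background_radius_cm Radius of the background cylinder (cm).
#' @return An object of class `ct_phantom`.
#' @seealso [kedge_phantom()] for the 16-insert study phantom.
#' @export
ct_phantom <- function(inserts, background_radius_cm = 15) {
  inserts <- as_tibble(inserts)
  need <- c("label", "x_cm", "y_cm", "radius_cm", "solute",
            "concentration_mg_per_mL")
  if (!all(need %in% names(inserts))) {
    abort(paste("`inserts` must have columns", paste(need, collapse = ", ")))
  }
  if (any(inserts$radius_cm <= 0)) abort("insert radii must be positive")
  r_out <- sqrt(inserts$x_cm^2 + inserts$y_cm^2) + inserts$radius_cm
  if (any(r_out > background_radius_cm + 1e-12)) {
    abort("all inserts must lie fully inside the background cylinder")
  }
  n <- nrow(inserts)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      d <- sqrt((inserts$x_cm[i] - inserts$x_cm[j])^2 +
                (inserts$y_cm[i] - inserts$y_cm[j])^2)
      if (d < inserts$radius_cm[i] + inserts$radius_cm[j] - 1e-12) {
        abort(sprintf("inserts '%s' and '%s' overlap",
                      inserts$label[i], inserts$label[j]))
      }
    }
  }
  structure(list(inserts = inserts,
                 background_radius_cm = background_radius_cm),
            class = "ct_phantom")
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("<ct_phantom> %g cm water cylinder, %d inserts\n",
              2 * x$background_radius_cm, nrow(x$inserts)))
  print(x$inserts, n = Inf)
  invisible(x)
}

#' The 16-insert K-edge study phantom
#'
#' A 30 cm water cylinder holding 16 equal-radius inserts: the 15 study
#' materials (calcium 50 mg/mL, iron 30 mg/mL, all others 4 mg/mL aqueous
#' solutions) plus one water-control insert.  Inserts are ordered by atomic
#' number (water control last) and placed deterministically on two
#' concentric rings: the first six on the inner ring, the remaining ten on
#' the outer ring.
#'
#' @param insert_radius_cm Insert radius (cm), default 1.25.
#' @param ring_radii_cm Radii of the two insert rings, default `c(5, 10)`.
#' @param background_radius_cm Background cylinder radius, default 15.
#' @return A `ct_phantom`.
#' @examples
#' ph <- kedge_phantom()
#' nrow(ph$inserts)  # 16
#' @export
kedge_phantom <- function(insert_radius_cm = 1.25,
                          ring_radii_cm = c(5, 10),
                          background_radius_cm = 15) {
  els <- atten_elements()
  syms <- names(.STUDY_CONCENTRATIONS)
  z <- els$Z[match(syms, els$symbol)]
  syms <- syms[order(z)]
  labels <- c(syms, "water")
  solutes <- c(syms, NA_character_)
  concs <- c(.STUDY_CONCENTRATIONS[syms], 0)
  n_inner <- 6L
  n_outer <- 10L
  ang_in <- 2 * pi * (seq_len(n_inner) - 1) / n_inner
  ang_out <- 2 * pi * (seq_len(n_outer) - 1) / n_outer
  x <- c(ring_radii_cm[1] * cos(ang_in), ring_radii_cm[2] * cos(ang_out))
  y <- c(ring_radii_cm[1] * sin(ang_in), ring_radii_cm[2] * sin(ang_out))
  ct_phantom(
    tibble(label = labels, x_cm = x, y_cm = y,
           radius_cm = insert_radius_cm, solute = solutes,
           concentration_mg_per_mL = unname(concs)),
    background_radius_cm = background_radius_cm)
}

.insert_material <- function(phantom, i) {
  row <- phantom$inserts[i, ]
  if (is.na(row$solute)) {
    ct_material(label = row$label)
  } else {
    ct_material(row$solute, row$concentration_mg_per_mL, label = row$label)
  }
}

#' Material at a point
#'
#' Returns the material of the innermost region containing `(x, y)`:
#' an insert, the water background, or air outside the cylinder.
#'
#' @param phantom A `ct_phantom`.
#' @param x,y Coordinates in cm (scalars).
#' @return A `ct_material`.
#' @export
material_at <- function(phantom, x, y) {
  stopifnot(inherits(phantom, "ct_phantom"))
  ins <- phantom$inserts
  d2 <- (ins$x_cm - x)^2 + (ins$y_cm - y)^2
  hit <- which(d2 <= ins$radius_cm^2)
  if (length(hit)) return(.insert_material(phantom, hit[1]))
  if (x^2 + y^2 <= phantom$background_radius_cm^2) return(ct_material())
  ct_material(base = "air")
}

#' Material groupings of the study
#'
#' The three categories used for contrast reporting: common biological
#' materials and clinical contrast agents; the lanthanides (including
#' ytterbium, which also features among the nanoparticle candidates); and
#' candidate contrast agents and nanomaterials.  Gadolinium and ytterbium
#' each appear in two groups.
#'
#' @return Named list of three character vectors of element symbols.
#' @export
material_groups <- function() {
  list(
    biological_clinical = c("Ba", "Ca", "Gd", "Fe", "I"),
    lanthanides = c("Sm", "Eu", "Gd", "Tb", "Yb", "Lu"),
    candidates_nanomaterials = c("Bi", "Au", "Pt", "Ta", "W", "Yb"))
}

#' Rasterize a phantom as an integer label map
#'
#' Pixel value 0 is air, 1 the water background, and `1 + i` the i-th
#' insert (row order of `phantom$inserts`).
#'
#' @param phantom A `ct_phantom`.
#' @param grid_size Image width/height in pixels.
#' @param pixel_size_mm Pixel pitch in mm.
#' @return An integer matrix of dimension `grid_size x grid_size`.
#' @export
phantom_label_raster <- function(phantom, grid_size = 128,
                                 pixel_size_mm = 2.8125) {
  px_cm <- pixel_size_mm / 10
  ctr <- .pixel_centers_cm(grid_size, px_cm)
  X <- matrix(ctr, grid_size, grid_size)
  Y <- matrix(ctr, grid_size, grid_size, byrow = TRUE)
  lab <- matrix(0L, grid_size, grid_size)
  lab[X^2 + Y^2 <= phantom$background_radius_cm^2] <- 1L
  ins <- phantom$inserts
  for (i in seq_len(nrow(ins))) {
    m <- (X - ins$x_cm[i])^2 + (Y - ins$y_cm[i])^2 <= ins$radius_cm[i]^2
    lab[m] <- 1L + i
  }
  lab
}

#' Serialize / restore a phantom specification
#'
#' The phantom is stored as a small YAML (or JSON) document holding the
#' background radius and the insert table.
#'
#' @param phantom A `ct_phantom`.
#' @param path Output file; extension `.json` selects JSON, anything else
#'   YAML.
#' @return `read_phantom()` returns a `ct_phantom`; `write_phantom()`
#'   returns `path` invisibly.
#' @export
write_phantom <- function(phantom, path) {
  obj <- list(background_radius_cm = phantom$background_radius_cm,
              inserts = as.data.frame(phantom$inserts))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  } else {
    yaml::write_yaml(obj, path, precision = 12)
  }
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ins <- if (is.data.frame(obj$inserts)) {
    as_tibble(obj$inserts)
  } else {
    # yaml represents the table as a list of per-column vectors
    as_tibble(lapply(obj$inserts, unlist))
  }
  ins$solute <- as.character(ins$solute)
  ins$solute[ins$solute %in% c("NA", "null", "")] <- NA_character_
  for (col in c("x_cm", "y_cm", "radius_cm", "concentration_mg_per_mL")) {
    ins[[col]] <- as.numeric(ins[[col]])
  }
  ct_phantom(ins, background_radius_cm = obj$background_radius_cm)
}
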