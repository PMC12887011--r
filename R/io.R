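# TIFF persistence for sinograms and images: 32-bit float TIFF plus a
# JSON sidecar carrying the protocol, bin and provenance (TIFF tags alone
# cannot hold them).  Sinograms store views as rows.  The TIFF layer
# stores values mapped to [0, 1]; the affine map (offset, scale) lives in
# the sidecar and is undone on read.

.sidecar_path <- function(path) paste0(path, ".json")

.tiff_pack <- function(m) {
  lo <- min(m); hi <- max(m)
  scale <- if (hi > lo) hi - lo else 1
  list(data = (m - lo) / scale, offset = lo, scale = scale)
}

.tiff_unpack <- function(m, meta) {
  m * meta$scale + meta$offset
}

.protocol_to_list <- function(p) p[!vapply(p, is.null, logical(1))]

.protocol_from_list <- function(l) {
  do.call(acquisition_protocol,
          l[intersect(names(l), names(formals(acquisition_protocol)))])
}

#' Write / read a binned sinogram as float TIFF + JSON sidecar
#'
#' @param sinogram A `binned_sinogram`.
#' @param path TIFF path; metadata goes to `<path>.json`.
#' @return `read_sinogram_tiff()` returns a `binned_sinogram`;
#'   the writer returns `path` invisibly.
#' @export
write_sinogram_tiff <- function(sinogram, path) {
  pk <- .tiff_pack(unclass(sinogram))
  tiff::writeTIFF(pk$data, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(kind = "binned_sinogram",
               offset = pk$offset, scale = pk$scale,
               bin_keV = attr(sinogram, "bin_keV"),
               noise_free = attr(sinogram, "noise_free"),
               seed = attr(sinogram, "seed"),
               protocol = .protocol_to_list(attr(sinogram, "protocol")))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sinogram_tiff
#' @export
read_sinogram_tiff <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  m <- .tiff_unpack(tiff::readTIFF(path, as.is = FALSE), meta)
  structure(m, class = "binned_sinogram",
            bin_keV = as.numeric(meta$bin_keV),
            protocol = .protocol_from_list(meta$protocol),
            noise_free = isTRUE(meta$noise_free),
            seed = meta$seed)
}

#' Write / read a reconstructed image as float TIFF + JSON sidecar
#'
#' HU values are stored verbatim as 32-bit floats.
#'
#' @param image A `recon_image`.
#' @param path TIFF path; metadata goes to `<path>.json`.
#' @return `read_image_tiff()` returns a `recon_image`; the writer
#'   returns `path` invisibly.
#' @export
write_image_tiff <- function(image, path) {
  pk <- .tiff_pack(unclass(image))
  tiff::writeTIFF(pk$data, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(kind = "recon_image",
               offset = pk$offset, scale = pk$scale,
               units = attr(image, "units"),
               pixel_size_mm = attr(image, "pixel_size_mm"),
               bin_keV = attr(image, "bin_keV"),
               protocol = .protocol_to_list(attr(image, "protocol")))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  m <- .tiff_unpack(tiff::readTIFF(path, as.is = FALSE), meta)
  .as_recon_image(m, units = meta$units,
                  pixel_size_mm = meta$pixel_size_mm,
                  bin_keV = as.numeric(meta$bin_keV),
                  protocol = if (!is.null(meta$protocol))
                    .protocol_from_list(meta$protocol))
}

#' Export the phantom label map as a TIFF raster
#'
#' @param phantom A `ct_phantom`.
#' @param path TIFF path.
#' @inheritParams phantom_label_raster
#' @return `path`, invisibly.
#' @export
write_label_raster_tiff <- function(phantom, path, grid_size = 128,
                                    pixel_size_mm = 2.8125) {
  lab <- phantom_label_raster(phantom, grid_size, pixel_size_mm)
  tiff::writeTIFF(lab / max(lab), path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}
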