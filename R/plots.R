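#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_tile geom_text
#'   facet_grid labs scale_fill_viridis_c theme_minimal autoplot
#' @export
ggplot2::autoplot
NULL

# long metrics table annotated with material group (materials may repeat
# across groups, as in the study's category definitions)
.grouped_metrics <- function(sweep) {
  groups <- material_groups()
  rows <- lapply(names(groups), function(g) {
    sweep$metrics |>
      filter(.data$material %in% groups[[g]]) |>
      mutate(group = g)
  })
  bind_rows(rows)
}

#' Plot threshold-sweep results
#'
#' `type = "noise"` mirrors the noise-versus-threshold curves of the two
#' bin images; `"contrast"` the per-group contrast curves (low/high bin
#' panels); `"separability"` the per-pair separability profiles for a
#' reference material; `"matrix"` the pairwise peak-separability heat map
#' annotated with the argmax threshold.
#'
#' @param object A `kedge_sweep`.
#' @param type One of `"noise"`, `"contrast"`, `"separability"`,
#'   `"matrix"`.
#' @param reference Reference material for `type = "separability"`
#'   (default `"I"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kedge_sweep
#' @export
autoplot.kedge_sweep <- function(object, type = c("noise", "contrast",
                                                  "separability", "matrix"),
                                 reference = "I", ...) {
  type <- match.arg(type)
  if (nrow(object$metrics) == 0) abort("empty sweep result; nothing to plot")
  switch(type,
    noise = {
      d <- object$metrics |>
        distinct(.data$threshold_keV, .data$bin, .data$noise_HU)
      ggplot(d, aes(.data$threshold_keV, .data$noise_HU,
                    colour = .data$bin)) +
        geom_line() + geom_point() +
        labs(x = "upper energy threshold (keV)", y = "noise (HU)",
             colour = "bin image",
             title = "Water-background noise vs energy threshold") +
        theme_minimal()
    },
    contrast = {
      d <- .grouped_metrics(object)
      ggplot(d, aes(.data$threshold_keV, .data$contrast_HU,
                    colour = .data$material)) +
        geom_line() + geom_point(size = 0.8) +
        facet_grid(group ~ bin, scales = "free_y") +
        labs(x = "upper energy threshold (keV)", y = "contrast (HU)",
             title = "Insert contrast vs energy threshold by material group") +
        theme_minimal()
    },
    separability = {
      s <- object$separability
      d <- s[s$material_A == reference | s$material_B == reference, ]
      if (nrow(d) == 0) abort(sprintf("no pairs involve '%s'", reference))
      d$partner <- ifelse(d$material_A == reference, d$material_B,
                          d$material_A)
      ggplot(d, aes(.data$threshold_keV, .data$s_prime,
                    colour = .data$partner)) +
        geom_line() + geom_point(size = 0.8) +
        labs(x = "upper energy threshold (keV)", y = "separability s'",
             colour = "partner",
             title = sprintf("Separability of %s with other materials",
                             reference)) +
        theme_minimal()
    },
    matrix = {
      am <- object$argmax
      d <- bind_rows(am,
                     tibble(material_A = am$material_B,
                            material_B = am$material_A,
                            best_threshold_keV = am$best_threshold_keV,
                            peak_s_prime = am$peak_s_prime))
      ggplot(d, aes(.data$material_A, .data$material_B,
                    fill = .data$peak_s_prime)) +
        geom_tile() +
        geom_text(aes(label = .data$best_threshold_keV), size = 2.6) +
        scale_fill_viridis_c(name = "peak s'") +
        labs(x = NULL, y = NULL,
             title = "Optimal threshold (keV) and peak separability per pair") +
        theme_minimal()
    })
}

#' Plot a reconstructed image
#'
#' @param object A `recon_image`.
#' @param window Display window `c(lo, hi)` in image units; values are
#'   clamped.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recon_image
#' @export
autoplot.recon_image <- function(object, window = c(-110, 190), ...) {
  px <- attr(object, "pixel_size_mm") / 10
  g <- nrow(object)
  ctr <- .pixel_centers_cm(g, px)
  d <- expand.grid(x = ctr, y = ctr)
  d$value <- pmin(pmax(as.vector(unclass(object)), window[1]), window[2])
  ggplot(d, aes(.data$x, .data$y, fill = .data$value)) +
    geom_tile() +
    scale_fill_viridis_c(name = attr(object, "units")) +
    labs(x = "x (cm)", y = "y (cm)") +
    theme_minimal()
}
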