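#' Persist a sweep as CSV tables and figures
#'
#' Writes the tidy metrics table, the pairwise separability table, the
#' per-pair argmax table, a resolved-configuration JSON, and the standard
#' figures (noise curves, per-group contrast curves, pairwise matrix,
#' separability profiles for each material of the lanthanide set).  The
#' figure set can be regenerated from the CSVs alone with
#' [render_report_from_csv()].
#'
#' @param sweep A `kedge_sweep`.
#' @param dir Output directory (created if missing).
#' @param figures Also write PDF figures (default `TRUE`).
#' @return Invisibly, the vector of written file paths.
#' @export
render_report <- function(sweep, dir, figures = TRUE) {
  stopifnot(inherits(sweep, "kedge_sweep"))
  if (nrow(sweep$metrics) == 0 || nrow(sweep$separability) == 0) {
    abort("empty sweep result; refusing to render an empty report")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(metrics = file.path(dir, "metrics.csv"),
             separability = file.path(dir, "separability.csv"),
             argmax = file.path(dir, "argmax.csv"),
             config = file.path(dir, "config.json"))
  utils::write.csv(sweep$metrics, paths["metrics"], row.names = FALSE)
  utils::write.csv(sweep$separability, paths["separability"],
                   row.names = FALSE)
  utils::write.csv(sweep$argmax, paths["argmax"], row.names = FALSE)
  jsonlite::write_json(sweep$config, paths["config"], auto_unbox = TRUE,
                       digits = NA)
  if (figures) paths <- c(paths, .report_figures(sweep, dir))
  invisible(paths)
}

.report_figures <- function(sweep, dir) {
  figs <- c(noise = "fig_noise.pdf", contrast = "fig_contrast.pdf",
            matrix = "fig_pair_matrix.pdf")
  out <- character()
  for (ty in names(figs)) {
    f <- file.path(dir, figs[[ty]])
    ggplot2::ggsave(f, autoplot(sweep, type = ty), width = 8, height = 6)
    out[paste0("fig_", ty)] <- f
  }
  lan <- intersect(material_groups()$lanthanides,
                   unique(sweep$metrics$material))
  for (m in lan) {
    f <- file.path(dir, sprintf("fig_separability_%s.pdf", m))
    ggplot2::ggsave(f, autoplot(sweep, type = "separability", reference = m),
                    width = 8, height = 6)
    out[paste0("fig_separability_", m)] <- f
  }
  out
}

#' Rebuild a sweep object (and figures) from persisted CSV tables
#'
#' @param dir Directory previously written by [render_report()].
#' @param figures Regenerate the PDF figures (default `FALSE`).
#' @return A `kedge_sweep` assembled from the persisted tables (without
#'   phantom or images).
#' @export
render_report_from_csv <- function(dir, figures = FALSE) {
  metrics <- as_tibble(utils::read.csv(file.path(dir, "metrics.csv")))
  separ <- as_tibble(utils::read.csv(file.path(dir, "separability.csv")))
  argmax <- as_tibble(utils::read.csv(file.path(dir, "argmax.csv")))
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  sweep <- structure(list(metrics = metrics, separability = separ,
                          argmax = argmax, phantom = NULL, config = config,
                          images = NULL),
                     class = "kedge_sweep")
  if (figures) .report_figures(sweep, dir)
  sweep
}
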