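#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a threshold-sweep result
#'
#' @param x A `kedge_sweep`.
#' @param table Which table: `"metrics"` (default), `"separability"`, or
#'   `"argmax"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @method tidy kedge_sweep
#' @export
tidy.kedge_sweep <- function(x, table = c("metrics", "separability", "argmax"),
                             ...) {
  table <- match.arg(table)
  x[[table]]
}

#' @rdname tidy.kedge_sweep
#' @method glance kedge_sweep
#' @export
glance.kedge_sweep <- function(x, ...) {
  noise <- x$metrics |> distinct(.data$threshold_keV, .data$bin,
                                 .data$noise_HU)
  tibble(
    n_thresholds = length(x$config$thresholds),
    n_materials = length(unique(x$metrics$material)),
    n_pairs = nrow(x$argmax),
    noise_free = x$config$noise_free,
    low_noise_at_min_T = noise$noise_HU[noise$bin == "low" &
      noise$threshold_keV == min(noise$threshold_keV)],
    high_noise_at_max_T = noise$noise_HU[noise$bin == "high" &
      noise$threshold_keV == max(noise$threshold_keV)],
    seed = x$config$seed %||% NA_integer_,
    elapsed_s = x$config$elapsed_s)
}

#' Tidy a separability result
#'
#' @param x A `separability_result`.
#' @param ... Unused.
#' @return One-row tibble with the index, the per-class lambda moments
#'   and the template weights.
#' @method tidy separability_result
#' @export
tidy.separability_result <- function(x, ...) {
  tibble(s_prime = x$s_prime, sign = x$sign,
         lambda_mean_A = x$lambda_mean_A, lambda_mean_B = x$lambda_mean_B,
         lambda_var_A = x$lambda_var_A, lambda_var_B = x$lambda_var_B,
         n_A = x$n_A, n_B = x$n_B,
         template = list(x$template_w))
}
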