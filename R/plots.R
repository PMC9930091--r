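# ggplot2 displays for the result types.

#' @exportS3Method ggplot2::autoplot
autoplot.release_series <- function(object, ...) {
  d <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("release_apparent_pct", "release_corrected_pct"),
    names_to = "kind", values_to = "release_pct"
  )
  d$kind <- ifelse(d$kind == "release_apparent_pct", "apparent",
                   "volume-corrected")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$release_pct,
                                  colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (h)", y = "Cumulative release (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rate_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$sqrt_t, .data$release)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$k,
                         colour = "steelblue") +
    ggplot2::labs(
      x = expression(sqrt(time) ~ (h^{1 / 2})),
      y = "Cumulative release (%)",
      subtitle = sprintf("k = %.2f %% h^-1/2, R2 = %.3f",
                         object$k, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rheology_trace <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object),
                           cols = c("g_prime_pa", "g_double_prime_pa"),
                           names_to = "modulus", values_to = "pa")
  d$modulus <- ifelse(d$modulus == "g_prime_pa", "G'", "G''")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s / 60, .data$pa,
                                  colour = .data$modulus)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Modulus (Pa)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ivivr_table <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object),
                           cols = c("in_vitro_pct", "in_vivo_pct"),
                           names_to = "environment", values_to = "release_pct")
  d$environment <- ifelse(d$environment == "in_vitro_pct",
                          "in vitro", "in vivo")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$release_pct,
                                  colour = .data$environment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (h)", y = "Corrected release (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one slice of a relaxation map
#'
#' @param map A [correct_t1()] result with array fields.
#' @param slice Slice index along the third axis.
#' @return A ggplot raster of T1 in seconds.
#' @export
plot_t1_slice <- function(map, slice = 1L) {
  stopifnot(inherits(map, "relaxation_map"))
  d <- dim(map$t1)
  sl <- map$t1[, , slice]
  df <- tibble(
    x = rep(seq_len(d[1]), d[2]),
    y = rep(seq_len(d[2]), each = d[1]),
    t1 = as.vector(sl)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$t1)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "T1 (s)", na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
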