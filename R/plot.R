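#' Plot a flow waveform
#'
#' @param object A [flow_waveform()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.flow_waveform <- function(object, ...) {
  ylab <- switch(waveform_quantity(object),
                 mean_velocity = "mean velocity (cm/s)",
                 flow = "flow (mL/s)",
                 "value")
  ggplot(as_tibble(object), aes(x = .data$time_s, y = .data$value)) +
    geom_line(linewidth = 0.4) +
    labs(x = "time (s)", y = ylab) +
    theme_minimal()
}

#' Plot a sampling pattern (ky versus time, coloured by role)
#'
#' @param object A `sampling_pattern`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sampling_pattern <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$t_ms, y = .data$ky, colour = .data$role)) +
    geom_point(size = 0.6) +
    facet_wrap(~ encoding, labeller = label_both) +
    labs(x = "time (ms)", y = "ky index", colour = NULL) +
    theme_minimal()
}

#' Bland-Altman plot
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot with bias and limits of agreement.
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot(object$data, aes(x = .data$mean, y = .data$diff)) +
    geom_point() +
    geom_hline(yintercept = object$bias, linetype = 1) +
    geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
               linetype = 3) +
    labs(x = "mean of methods", y = "difference (a - b)") +
    theme_minimal()
}

#' Plot one frame of an image or velocity series
#'
#' @param x An [image_series()] (magnitude is shown), [velocity_series()]
#'   or [phase_series()].
#' @param frame Frame index.
#' @return A ggplot raster of the frame.
#' @export
plot_frame <- function(x, frame = 1L) {
  img <- series_frame(x, frame)
  if (is.complex(img)) img <- Mod(img)
  d <- tibble(x = rep(seq_len(nrow(img)), times = ncol(img)),
              y = rep(seq_len(ncol(img)), each = nrow(img)),
              value = as.vector(img))
  fill <- if (inherits(x, "velocity_series")) {
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick")
  } else {
    scale_fill_gradient(low = "black", high = "white")
  }
  ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() + fill + coord_equal() +
    labs(x = NULL, y = NULL, fill = NULL) +
    theme_void()
}

#' Plot CG convergence of a reconstruction
#'
#' @param object A `kt_recon` object.
#' @param ... Unused.
#' @return A ggplot of relative residual versus iteration.
#' @exportS3Method ggplot2::autoplot
autoplot.kt_recon <- function(object, ...) {
  d <- tidy(object)
  d$encoding <- ifelse(is.na(d$encoding), "joint", as.character(d$encoding))
  ggplot(d, aes(x = .data$iteration, y = .data$residual,
                colour = .data$encoding)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "CG iteration", y = "relative residual", colour = NULL) +
    theme_minimal()
}
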