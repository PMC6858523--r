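# ggplot2 views of the tabular result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a broadened density of states
#' @param object a [dos_curve()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot slite_dos
#' @export
autoplot.slite_dos <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$energy, y = .data$dos)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "orbital energy (eV)", y = "density of states (1/eV)")
}

#' Plot training history
#' @param object a [train_model()] fit.
#' @param ... unused.
#' @return a ggplot object with train/validation loss curves (log scale).
#' @method autoplot slite_fit
#' @export
autoplot.slite_fit <- function(object, ...) {
  h <- object$history
  df <- rbind(
    data.frame(epoch = h$epoch, loss = h$train_total, set = "train"),
    data.frame(epoch = h$epoch, loss = h$val_total, set = "validation")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "combined loss", colour = NULL)
}

#' Plot a molecular-dynamics trajectory
#' @param object a [langevin_md()] trajectory.
#' @param ... unused.
#' @return a ggplot object with energies and instantaneous temperature.
#' @method autoplot slite_trajectory
#' @export
autoplot.slite_trajectory <- function(object, ...) {
  fr <- object$frames
  df <- rbind(
    data.frame(time = fr$time, value = fr$epot, what = "potential (eV)"),
    data.frame(time = fr$time, value = fr$etot, what = "total (eV)"),
    data.frame(time = fr$time, value = fr$temperature, what = "T (K)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (fs)", y = NULL)
}

#' Plot a gap-optimisation trace
#' @param object an [optimize_gap()] result.
#' @param ... unused.
#' @return a ggplot object of accepted-step gaps.
#' @method autoplot slite_gapopt
#' @export
autoplot.slite_gapopt <- function(object, ...) {
  df <- data.frame(step = seq_along(object$trace) - 1L, gap = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$gap)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "accepted step", y = "HOMO-LUMO gap (eV)",
                  title = paste("gap", object$mode, "-", object$status))
}

#' @importFrom ggplot2 .data
NULL
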