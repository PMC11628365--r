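# ggplot2 presentation of result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_raster
#'   geom_path geom_point labs scale_fill_viridis_c theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a free-energy grid
#'
#' 1D grids are drawn as a profile with a SEM ribbon; 2D grids as a raster
#' of free energy, masked nodes blank.
#'
#' @param object a `fes_grid`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fes_grid <- function(object, ...) {
  td <- tidy(object)
  nms <- names(object$axes)
  if (length(nms) == 1) {
    ggplot(td[td$sampled, ], aes(x = .data[[nms[1]]], y = .data$fes)) +
      geom_ribbon(aes(ymin = .data$fes - .data$sem,
                      ymax = .data$fes + .data$sem), alpha = 0.3) +
      geom_line() +
      labs(y = "free energy (kcal/mol)") +
      theme_minimal()
  } else if (length(nms) == 2) {
    ggplot(td[td$sampled, ],
           aes(x = .data[[nms[1]]], y = .data[[nms[2]]], fill = .data$fes)) +
      geom_raster() +
      scale_fill_viridis_c(name = "F (kcal/mol)") +
      theme_minimal()
  } else {
    abort("autoplot supports 1D and 2D grids; tidy() higher dimensions yourself")
  }
}

#' Plot a minimum-energy path profile
#'
#' @param object a `mep_result`.
#' @param ... unused.
#' @return a ggplot of free energy against path step.
#' @export
autoplot.mep_result <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(x = .data$step, y = .data$fes)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "path node", y = "free energy (kcal/mol)",
         subtitle = sprintf("%s barrier: %.2f kcal/mol", object$mode,
                            object$barrier)) +
    theme_minimal()
}

#' Plot a NEB energy profile
#'
#' @param opt result of [optimize_band()].
#' @return a ggplot of per-image energy.
#' @export
plot_band_profile <- function(opt) {
  td <- tibble::tibble(image = seq_along(opt$energies), energy = opt$energies)
  ggplot(td, aes(x = .data$image, y = .data$energy)) +
    geom_line() + geom_point() +
    labs(y = "energy (kcal/mol)") +
    theme_minimal()
}

#' Plot a free-energy profile tibble
#'
#' @param fep tibble from [fep_along_path()] or [metad_fes_estimate()].
#' @param x name of the CV column (default `"s"`).
#' @return a ggplot.
#' @export
plot_fep <- function(fep, x = "s") {
  p <- ggplot(fep[is.finite(fep$fes), ], aes(x = .data[[x]], y = .data$fes))
  if ("sem" %in% names(fep))
    p <- p + geom_ribbon(aes(ymin = .data$fes - .data$sem,
                             ymax = .data$fes + .data$sem), alpha = 0.3)
  p + geom_line() + labs(y = "free energy (kcal/mol)") + theme_minimal()
}
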