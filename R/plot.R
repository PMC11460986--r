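#' Log-log scaling plot with margins and competition shading
#'
#' Draws the observed biomass densities on log-log axes with the
#' total-predator regression line, each species' single-species
#' regression (dashed), the CCA-derived margin lines (solid, coloured)
#' and shading between margin and regression — the competition gap.
#'
#' @param x A `preypower_analysis` from [run_full_analysis()].
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.preypower_analysis <- function(x, ...) {
  b <- x$biomass
  has_joint <- !is.null(x$margins)
  lx <- log10(b$prey_biomass)
  ys <- c(b$predator_biomass, b$tiger_biomass, b$leopard_biomass)
  ys <- ys[!is.na(ys) & ys > 0]
  graphics::plot(lx, log10(b$predator_biomass),
                 xlab = expression(log[10] ~ "prey biomass (kg/km"^2 * ")"),
                 ylab = expression(log[10] ~ "predator biomass (kg/km"^2 * ")"),
                 ylim = range(log10(ys)), pch = 1, ...)
  cf <- coef(x$fits$total)
  graphics::abline(cf[["logc"]], cf[["k"]], lwd = 2)

  cols <- c(tiger = "firebrick", leopard = "steelblue")
  for (sp in c("tiger", "leopard")) {
    fit <- x$fits[[sp]]
    if (is.null(fit)) next
    ysp <- b[[paste0(sp, "_biomass")]]
    ok <- !is.na(ysp) & ysp > 0
    graphics::points(lx[ok], log10(ysp[ok]), pch = substr(toupper(sp), 1, 1),
                     col = cols[[sp]], cex = 0.8)
    cfs <- coef(fit)
    if (has_joint && sp %in% names(x$competition)) {
      gap <- x$competition[[sp]]
      gx <- log10(gap$x)
      keep <- gap$margin > 0 & gap$regression > 0
      graphics::polygon(c(gx[keep], rev(gx[keep])),
                        c(log10(gap$margin[keep]),
                          rev(log10(gap$regression[keep]))),
                        col = grDevices::adjustcolor(cols[[sp]], 0.2),
                        border = NA)
      graphics::lines(gx[keep], log10(gap$margin[keep]), col = cols[[sp]],
                      lwd = 2)
    }
    graphics::abline(cfs[["logc"]], cfs[["k"]], col = cols[[sp]], lty = 2)
  }
  graphics::legend("topleft", bty = "n", lwd = c(2, 2, 1),
                   lty = c(1, 1, 2), col = c("black", cols[["tiger"]], "gray30"),
                   legend = c("total regression", "margins (solid, by colour)",
                              "single-species regressions (dashed)"))
  invisible(x)
}
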