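# Photon attenuation data for the kerma engine: water mass attenuation
# (mu/rho) and mass energy-absorption (mu_en/rho) coefficients on a coarse
# energy grid, interpolated log-log. The packaged table is a fixture of
# standard-magnitude water values adequate for the engine's documented
# kerma-level fidelity; users can supply their own CSV.

#' Load an attenuation model from a coefficient table
#'
#' @param path CSV with columns `energy_MeV`, `mu_over_rho`
#'   (cm^2/g), `mu_en_over_rho` (cm^2/g); defaults to the packaged water
#'   table.
#' @return an object of class `attenuation_model` with vectorized
#'   `$mu_rho(E)` and `$muen_rho(E)` (log-log interpolation, clamped at the
#'   table ends).
#' @export
attenuation_model <- function(path = system.file("extdata",
                                                 "water_attenuation.csv",
                                                 package = "fajtrace")) {
  tab <- read.csv(path)
  stopifnot(all(c("energy_MeV", "mu_over_rho", "mu_en_over_rho") %in%
                  names(tab)))
  le <- log(tab$energy_MeV)
  lmu <- log(tab$mu_over_rho)
  lmuen <- log(tab$mu_en_over_rho)
  interp <- function(ly) {
    function(E) exp(approx(le, ly, xout = log(E), rule = 2)$y)
  }
  structure(list(table = tab, mu_rho = interp(lmu),
                 muen_rho = interp(lmuen)),
            class = "attenuation_model")
}
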