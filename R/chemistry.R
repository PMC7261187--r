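# Droplet chemistry: when the oil-water emulsion forms, the master mix
# volume is doubled, halving the hairpin concentration, so the number of
# substrate molecules per ~270 pl drop is
#   conc(M) / dilution * volume(L) * Avogadro.

#' Droplet parameters
#'
#' @param diameter_um Droplet diameter in micrometres (metadata; the stated
#'   volume is used directly, not recomputed from the diameter).
#' @param volume_L Droplet volume in litres (default 270 pl).
#' @param master_mix_dilution Dilution of the master mix on emulsion
#'   formation (default 2).
#' @param avogadro Avogadro constant.
#' @return List of validated parameters.
#' @export
droplet_params <- function(diameter_um = 80, volume_L = 270e-12,
                           master_mix_dilution = 2, avogadro = 6.02e23) {
  p <- list(diameter_um = diameter_um, volume_L = volume_L,
            master_mix_dilution = master_mix_dilution, avogadro = avogadro)
  if (any(unlist(p) <= 0)) stop("droplet parameters must be positive")
  p
}

#' Substrate molecules per droplet
#'
#' `conc_nM * 1e-9 / dilution * volume_L * avogadro`, vectorized over the
#' master-mix concentration. At the defaults, 0.5 nM gives about 4.1e4
#' molecules per drop (40 000 at one significant figure).
#'
#' @param conc_nM Hairpin concentration in the master mix, nanomolar
#'   (non-negative).
#' @param params [droplet_params()].
#' @return Numeric vector of molecules per droplet.
#' @export
molecules_per_droplet <- function(conc_nM, params = droplet_params()) {
  if (any(conc_nM < 0)) stop("concentration must be non-negative")
  conc_nM * 1e-9 / params$master_mix_dilution * params$volume_L *
    params$avogadro
}

#' @rdname molecules_per_droplet
#' @details `molecules_per_droplet_rounded()` reports one significant
#'   figure, the precision at which per-drop molecule numbers are usually
#'   quoted.
#' @export
molecules_per_droplet_rounded <- function(conc_nM, params = droplet_params()) {
  signif(molecules_per_droplet(conc_nM, params), 1)
}

#' Fraction of substrates recovered per droplet
#'
#' Aligned reads per drop divided by the estimated number of substrate
#' molecules per drop at the given loading concentration.
#'
#' @param aligned_reads_per_drop Named numeric vector (cell/drop -> aligned
#'   read count).
#' @param conc_nM Loading concentration in nM (must be positive).
#' @param params [droplet_params()].
#' @return Named numeric vector of recovery fractions.
#' @export
recovery_fraction <- function(aligned_reads_per_drop, conc_nM,
                              params = droplet_params()) {
  if (length(conc_nM) != 1L || conc_nM <= 0)
    stop("conc_nM must be a single positive value")
  aligned_reads_per_drop / molecules_per_droplet(conc_nM, params)
}
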