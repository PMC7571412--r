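#' Serial-transfer generation accounting
#'
#' In daily serial-dilution culture, a saturated culture diluted 1:D must
#' regrow by a factor of D to re-saturate, i.e. it undergoes log2(D)
#' doublings (generations) per day. A standard 1:1000 transfer therefore
#' yields 9.97 generations per day, and 25 days of transfers yield about
#' 250 generations; 1:250 and 1:4000 dilutions yield about 200 and 300
#' generations respectively over the same 25 days.
#'
#' @param dilution dilution factor D (> 1), e.g. 1000 for a 1:1000 transfer
#' @return generations (doublings) per transfer cycle, `log2(dilution)`
#' @export
generations_per_day <- function(dilution) {
  stopifnot(is.numeric(dilution), all(dilution > 1))
  log2(dilution)
}

#' Total generations over a serial-transfer experiment
#'
#' @param dilution dilution factor D per transfer
#' @param days number of daily transfer cycles
#' @return expected generations, `days * log2(dilution)`
#' @export
total_generations <- function(dilution, days = 25) {
  stopifnot(is.numeric(days), all(days >= 0))
  days * generations_per_day(dilution)
}

#' Bottleneck size at transfer
#'
#' Number of cells transferred into fresh medium each day:
#' saturation density times culture volume divided by the dilution factor.
#'
#' @param dilution dilution factor D
#' @param saturation_density cells/ml at saturation (default 3.0e8)
#' @param volume culture volume in ml (default 0.6)
#' @return expected cells at the bottleneck
#' @export
bottleneck_size <- function(dilution, saturation_density = 3.0e8,
                            volume = 0.6) {
  stopifnot(dilution > 1, saturation_density > 0, volume > 0)
  saturation_density * volume / dilution
}

#' Expected cells per strain at pooled-assay inoculation
#'
#' Cells transferred at a 1:1000 assay dilution, split over the strains in
#' the pool: with defaults, 3.0e8 * 0.6 / 1000 / 20 = 9,000 cells/strain.
#'
#' @param n_strains strains per assay pool (default 20)
#' @inheritParams bottleneck_size
#' @export
cells_per_strain_at_inoculation <- function(n_strains = 20, dilution = 1000,
                                            saturation_density = 3.0e8,
                                            volume = 0.6) {
  stopifnot(n_strains >= 1)
  bottleneck_size(dilution, saturation_density, volume) / n_strains
}
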