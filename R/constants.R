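# SI constants used throughout; k_B deliberately at 3-digit precision,
# the convention of the loss-model literature.
.kB <- 1.38e-23          # Boltzmann constant, J/K
.mu0 <- 4 * pi * 1e-7    # vacuum permeability, T m / A

#' Physical constants used by the loss model
#'
#' Returns the Boltzmann constant and the vacuum permeability as used in all
#' internal physics. `k_B` is fixed at 1.38e-23 J/K (the rounded value
#' conventional in the magnetic-fluid loss literature) and `mu0` at
#' `4 * pi * 1e-7` T m/A.
#'
#' @return Named list with elements `k_B` (J/K) and `mu0` (T m/A).
#' @examples
#' mfh_constants()
#' @export
mfh_constants <- function() {
  list(k_B = .kB, mu0 = .mu0)
}
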