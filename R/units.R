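#' Unit conversion constants
#'
#' Atomic units (Hartree energy, bohr, a.u. time and field) are used
#' internally everywhere.  These constants convert the common spectroscopic
#' input units.
#'
#' * `hartree_eV`: 1 hartree = 27.2114 eV
#' * `au_time_fs`: 1 a.u. of time = 0.02418884 fs
#' * `cm1_hartree`: 1 cm^-1 in hartree (1/219474.63)
#' * `au_field_Vm`: 1 a.u. of electric field = 5.142e11 V/m
#' * `c_au`: speed of light in atomic units (1/alpha = 137.036)
#'
#' @format A named list of scalars.
#' @export
au <- list(
  hartree_eV  = 27.211386,
  au_time_fs  = 0.02418884,
  cm1_hartree = 1 / 219474.63,
  au_field_Vm = 5.142e11,
  c_au        = 137.035999
)

#' @rdname au
#' @param x numeric value(s) to convert.
#' @export
ev_to_au <- function(x) x / au$hartree_eV

#' @rdname au
#' @export
cm1_to_au <- function(x) x * au$cm1_hartree

#' @rdname au
#' @export
au_to_cm1 <- function(x) x / au$cm1_hartree

#' @rdname au
#' @export
fs_to_au <- function(x) x / au$au_time_fs

#' @rdname au
#' @export
au_to_fs <- function(x) x * au$au_time_fs

#' @rdname au
#' @export
vm_to_au <- function(x) x / au$au_field_Vm
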