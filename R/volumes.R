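#' Blood volume from tHb-mass and haemoglobin concentration
#'
#' `BV = tHb-mass * 100 / (hb_g_dl * cell_factor)`, with \[Hb\] converted
#' from g/l to g/dl at this boundary only. The cell factor (~0.91) is the
#' whole-body to venous hematocrit ratio: venous \[Hb\] overstates the
#' body-average concentration, so dividing by it scales the venous value to a
#' whole-body one.
#'
#' @param thb_mass_g total haemoglobin mass, g.
#' @param hb_g_l venous haemoglobin concentration, g/l.
#' @param cell_factor body-to-venous hematocrit ratio, dimensionless.
#'   Default 0.91.
#' @return blood volume, ml.
#' @export
blood_volume <- function(thb_mass_g, hb_g_l, cell_factor = 0.91) {
  if (any(thb_mass_g <= 0) || any(hb_g_l <= 0) || any(cell_factor <= 0))
    ocor_abort("ocor_domain_error", "all inputs must be positive")
  thb_mass_g * 100 / ((hb_g_l / 10) * cell_factor)
}

#' Red-cell volume from blood volume and venous hematocrit
#'
#' `RCV = BV * hct * cell_factor` (the cell factor converts the venous
#' hematocrit to a whole-body one).
#'
#' @param bv_ml blood volume, ml.
#' @param hct venous hematocrit, fraction in (0, 1).
#' @param cell_factor body-to-venous hematocrit ratio. Default 0.91.
#' @return red-cell volume, ml.
#' @export
red_cell_volume <- function(bv_ml, hct, cell_factor = 0.91) {
  if (any(hct <= 0) || any(hct >= 1))
    ocor_abort("ocor_domain_error", "hct must be a fraction in (0, 1)")
  bv_ml * hct * cell_factor
}

#' Plasma volume as blood volume minus red-cell volume
#'
#' @param bv_ml blood volume, ml.
#' @param rcv_ml red-cell volume, ml.
#' @return plasma volume, ml.
#' @export
plasma_volume <- function(bv_ml, rcv_ml) {
  if (any(rcv_ml > bv_ml))
    ocor_abort("ocor_inconsistent", "red-cell volume exceeds blood volume")
  bv_ml - rcv_ml
}

#' All volume derivatives for one subject
#'
#' @param thb_mass_g total haemoglobin mass, g.
#' @param hb_g_l venous haemoglobin concentration, g/l.
#' @param hct venous hematocrit, fraction.
#' @param cell_factor body-to-venous hematocrit ratio. Default 0.91.
#' @return one-row data.frame: `bv_ml`, `rcv_ml`, `pv_ml`, `cell_factor`,
#'   satisfying `bv_ml == rcv_ml + pv_ml` exactly.
#' @export
volume_set <- function(thb_mass_g, hb_g_l, hct, cell_factor = 0.91) {
  bv <- blood_volume(thb_mass_g, hb_g_l, cell_factor)
  rcv <- red_cell_volume(bv, hct, cell_factor)
  data.frame(bv_ml = bv, rcv_ml = rcv, pv_ml = plasma_volume(bv, rcv),
             cell_factor = cell_factor)
}
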