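#' Gravimetric water content
#'
#' Oven-drying water content as the percentage of mass lost:
#' `100 * (m_wet - m_dry) / m_wet`, with masses already corrected for the
#' container.
#'
#' @param m_wet,m_dry Sample masses in grams, `0 < m_dry <= m_wet`.
#' @return Water content in percent.
#' @export
water_content_pct <- function(m_wet, m_dry) {
  if (any(m_dry <= 0) || any(m_wet <= 0))
    spst_error("masses must be positive", "sproutspec_domain_error")
  if (any(m_dry > m_wet))
    spst_error("dry mass exceeds wet mass (negative loss)",
               "sproutspec_negative_loss")
  100 * (m_wet - m_dry) / m_wet
}

#' Thiosulfate standardization against potassium iodate
#'
#' `N_thio = V_iodate * N_iodate * 0.1`. The 0.1 factor is 1 over the
#' 10 mL thiosulfate aliquot titrated; for other aliquot volumes use
#' [titrant_normality()].
#'
#' @param v_iodate Iodate titrant volume in mL.
#' @param n_iodate Iodate normality in eq/L.
#' @return Thiosulfate normality in eq/L.
#' @export
standardize_thiosulfate <- function(v_iodate, n_iodate) {
  check_nonneg(v_iodate, n_iodate)
  v_iodate * n_iodate * 0.1
}

#' Iodine standardization against thiosulfate
#'
#' `N_iodine = V_thio * N_thio * 0.1` (10 mL iodine aliquot assumed).
#'
#' @param v_thio Thiosulfate titrant volume in mL.
#' @param n_thio Thiosulfate normality in eq/L.
#' @return Iodine normality in eq/L.
#' @export
standardize_iodine <- function(v_thio, n_thio) {
  check_nonneg(v_thio, n_thio)
  v_thio * n_thio * 0.1
}

#' General N1 V1 = N2 V2 standardization
#'
#' @param n_titrant,v_titrant Normality (eq/L) and volume (mL) of the
#'   standard titrant consumed.
#' @param v_aliquot Volume (mL) of the solution being standardized.
#' @return Normality of the standardized solution in eq/L.
#' @export
titrant_normality <- function(n_titrant, v_titrant, v_aliquot) {
  check_nonneg(n_titrant, v_titrant)
  if (any(v_aliquot <= 0))
    spst_error("aliquot volume must be positive", "sproutspec_domain_error")
  n_titrant * v_titrant / v_aliquot
}

#' Ascorbic acid equivalent weight against iodine (mg per meq)
#'
#' Ascorbic acid (molar mass 176.13 g/mol) is oxidised by iodine in a
#' two-electron reaction, so its equivalent weight is 176.13 / 2.
#' @export
ASCORBIC_EQ_WEIGHT <- 176.13 / 2

#' Ascorbic acid mass from an iodometric titre
#'
#' `mg = N_titrant * (V_sample - V_blank) * 88.065`, the mass of ascorbic
#' acid in the titrated aliquot. `titrant_normality` is the normality of
#' the iodine titrant as standardized through the thiosulfate chain.
#'
#' @param titrant_normality Titrant normality in eq/L.
#' @param v_sample,v_blank Titre volumes in mL (`v_sample >= v_blank`).
#' @return Milligrams of ascorbic acid in the aliquot.
#' @export
ascorbic_mass_mg <- function(titrant_normality, v_sample, v_blank = 0) {
  check_nonneg(titrant_normality, v_sample, v_blank)
  if (any(v_sample < v_blank))
    spst_error("sample titre below blank titre (negative titre)",
               "sproutspec_negative_titre")
  titrant_normality * (v_sample - v_blank) * ASCORBIC_EQ_WEIGHT
}

#' Convert aliquot mass to mg per 100 g of starting material
#'
#' Scales a per-aliquot mass up to the whole extract and normalises to
#' 100 g of beans: `mg * (extract_total_ml / aliquot_ml) * (100 / bean_mass_g)`.
#' The defaults reflect the 25 mL aliquot of a 200 mL extract prepared
#' from 100 g of sprouts; the bean's own water contribution to the extract
#' volume is ignored.
#'
#' @param mg_in_aliquot Ascorbic acid mass in the aliquot, mg.
#' @param aliquot_ml Aliquot volume (default 25 mL).
#' @param extract_total_ml Total extract volume (default 200 mL).
#' @param bean_mass_g Starting bean mass (default 100 g).
#' @return mg per 100 g.
#' @export
to_mg_per_100g <- function(mg_in_aliquot, aliquot_ml = 25,
                           extract_total_ml = 200, bean_mass_g = 100) {
  if (any(c(aliquot_ml, extract_total_ml, bean_mass_g) <= 0))
    spst_error("aliquot, extract and mass must be positive",
               "sproutspec_config_error")
  mg_in_aliquot * (extract_total_ml / aliquot_ml) * (100 / bean_mass_g)
}

check_nonneg <- function(...) {
  vals <- c(...)
  if (any(vals < 0))
    spst_error("volumes and normalities must be non-negative",
               "sproutspec_domain_error")
  invisible(TRUE)
}
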