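# dGEMRIC-style GAG quantification: pre-/post-contrast T1 of cells and
# media -> Gd-DTPA(2-) concentrations -> Donnan fixed-charge density ->
# glycosaminoglycan concentration.

#' Pre-/post-contrast T1 panel with physical constants
#'
#' Bundles the four T1 measurements (cells and media, before and after
#' Gd-DTPA(2-) equilibration) with the constants of the conversion
#' chain: contrast relaxivity at 1.5 T (3.9 L mmol^-1 s^-1), the sodium
#' concentration of the medium (154 mM), the GAG monomer molar mass
#' (502.5 g/mol) and its charge (-2 per monomer).
#'
#' @param pre_t1_cells_ms,post_t1_cells_ms cell-compartment T1, ms.
#' @param pre_t1_media_ms,post_t1_media_ms medium T1, ms.
#' @param relaxivity_per_mM_per_s contrast relaxivity, L mmol^-1 s^-1.
#' @param na_media_mM sodium concentration of the medium, mM.
#' @param gag_molar_mass_g_per_mol GAG monomer molar mass, g/mol.
#' @param charge_per_gag moles of charge per mole of GAG (magnitude).
#' @return a `gd_panel` list.
#' @export
gd_panel <- function(pre_t1_cells_ms, post_t1_cells_ms,
                     pre_t1_media_ms, post_t1_media_ms,
                     relaxivity_per_mM_per_s = 3.9,
                     na_media_mM = 154,
                     gag_molar_mass_g_per_mol = 502.5,
                     charge_per_gag = 2) {
  t1s <- c(pre_t1_cells_ms, post_t1_cells_ms, pre_t1_media_ms, post_t1_media_ms)
  if (any(!is.finite(t1s)) || any(t1s <= 0)) stop("all T1 values must be > 0")
  if (post_t1_cells_ms > pre_t1_cells_ms ||
      post_t1_media_ms > pre_t1_media_ms) {
    stop("post-contrast T1 must not exceed pre-contrast T1 (contrast shortens T1)")
  }
  if (relaxivity_per_mM_per_s <= 0) stop("relaxivity must be > 0")
  if (na_media_mM <= 0) stop("na_media_mM must be > 0")
  structure(
    list(pre_t1_cells_ms = pre_t1_cells_ms,
         post_t1_cells_ms = post_t1_cells_ms,
         pre_t1_media_ms = pre_t1_media_ms,
         post_t1_media_ms = post_t1_media_ms,
         relaxivity_per_mM_per_s = relaxivity_per_mM_per_s,
         na_media_mM = na_media_mM,
         gag_molar_mass_g_per_mol = gag_molar_mass_g_per_mol,
         charge_per_gag = charge_per_gag),
    class = "gd_panel"
  )
}

#' Contrast-agent concentration from the pre/post T1 pair
#'
#' Gd-DTPA(2-) shortens T1 proportionally to its concentration via the
#' relaxivity R:
#' \deqn{[Gd] = (1/R)\,(1/T_{1,post} - 1/T_{1,pre}),}
#' with T1 in seconds, giving mmol/L.
#'
#' @param pre_t1_ms,post_t1_ms T1 before/after contrast, ms (`post <= pre`).
#' @param relaxivity relaxivity, L mmol^-1 s^-1.
#' @return concentration in mM, `>= 0`.
#' @export
gd_concentration <- function(pre_t1_ms, post_t1_ms, relaxivity = 3.9) {
  if (pre_t1_ms <= 0 || post_t1_ms <= 0) stop("T1 values must be > 0")
  if (relaxivity <= 0) stop("relaxivity must be > 0")
  if (post_t1_ms > pre_t1_ms) {
    stop("negative concentration - check panel (post-contrast T1 exceeds pre)")
  }
  (1 / (post_t1_ms / 1000) - 1 / (pre_t1_ms / 1000)) / relaxivity
}

#' Donnan fixed-charge density from the Gd partition
#'
#' The negatively charged contrast agent is excluded from regions of
#' fixed negative charge, so its cells/media partition encodes the
#' fixed-charge density via Donnan equilibrium (square-root form, with
#' the empirical factor 2):
#' \deqn{FCD = -2\,[Na^+]\left(\sqrt{[Gd]_c/[Gd]_m} -
#'   \sqrt{[Gd]_m/[Gd]_c}\right).}
#' FCD is 0 iff the two concentrations are equal, and positive when
#' cells exclude Gd (`gd_cells < gd_media`) under this sign convention.
#'
#' @param gd_cells_mM,gd_media_mM Gd concentrations, mM (`> 0`).
#' @param na_media_mM sodium concentration of the medium, mM.
#' @return fixed-charge density, mM.
#' @export
fcd <- function(gd_cells_mM, gd_media_mM, na_media_mM = 154) {
  if (gd_cells_mM <= 0 || gd_media_mM <= 0) {
    stop("Gd concentrations must be strictly positive")
  }
  if (na_media_mM <= 0) stop("na_media_mM must be > 0")
  ratio <- gd_cells_mM / gd_media_mM
  -2 * na_media_mM * (sqrt(ratio) - sqrt(1 / ratio))
}

#' Invert the Donnan relation: Gd ratio from a target FCD
#'
#' Closed-form inverse of [fcd()]: solves
#' `s - 1/s = -FCD/(2 Na)` for `s = sqrt(gd_cells/gd_media)`
#' (the bracket is monotone in the ratio, so the inverse is unique).
#'
#' @param fcd_mM fixed-charge density, mM.
#' @param na_media_mM sodium concentration, mM.
#' @return the ratio `gd_cells / gd_media`.
#' @export
fcd_to_gd_ratio <- function(fcd_mM, na_media_mM = 154) {
  u <- -fcd_mM / (2 * na_media_mM)
  s <- (u + sqrt(u^2 + 4)) / 2
  s^2
}

#' GAG concentration from fixed-charge density
#'
#' With `charge` moles of charge per mole of GAG monomer, `|FCD|/charge`
#' is the GAG monomer concentration in mmol/L; multiplying by the molar
#' mass gives mg/L and the factor 1e-3 converts to mg/mL:
#' \deqn{GAG = |FCD| / charge \cdot M \cdot 10^{-3}.}
#'
#' @param fcd_mM fixed-charge density, mM.
#' @param molar_mass GAG monomer molar mass, g/mol.
#' @param charge moles of charge per mole of GAG (magnitude, `> 0`).
#' @return GAG concentration, mg/mL.
#' @export
gag_concentration <- function(fcd_mM, molar_mass = 502.5, charge = 2) {
  if (molar_mass <= 0) stop("molar_mass must be > 0")
  if (charge <= 0) stop("charge must be > 0")
  abs(fcd_mM) / charge * molar_mass * 1e-3
}

#' Full T1-to-GAG conversion chain
#'
#' Chains [gd_concentration()] (cells, then media), [fcd()] and
#' [gag_concentration()] for one panel. When both compartments show no
#' contrast uptake (pre = post on both sides) the partition carries no
#' information and FCD and GAG are reported as 0.
#'
#' @param panel a [gd_panel()].
#' @return list with `gd_cells_mM`, `gd_media_mM`, `fcd_mM`,
#'   `gag_mg_per_mL`, and `constants` echoing the panel constants.
#' @export
gag_pipeline <- function(panel) {
  if (!inherits(panel, "gd_panel")) stop("expected a gd_panel")
  gd_cells <- tryCatch(
    gd_concentration(panel$pre_t1_cells_ms, panel$post_t1_cells_ms,
                     panel$relaxivity_per_mM_per_s),
    error = function(e) stop("Gd (cells) step failed: ", conditionMessage(e)))
  gd_media <- tryCatch(
    gd_concentration(panel$pre_t1_media_ms, panel$post_t1_media_ms,
                     panel$relaxivity_per_mM_per_s),
    error = function(e) stop("Gd (media) step failed: ", conditionMessage(e)))
  if (gd_cells == 0 && gd_media == 0) {
    f <- 0
  } else {
    f <- tryCatch(
      fcd(gd_cells, gd_media, panel$na_media_mM),
      error = function(e) stop("FCD step failed: ", conditionMessage(e)))
  }
  g <- gag_concentration(f, panel$gag_molar_mass_g_per_mol,
                         panel$charge_per_gag)
  list(gd_cells_mM = gd_cells, gd_media_mM = gd_media,
       fcd_mM = f, gag_mg_per_mL = g,
       constants = panel[c("relaxivity_per_mM_per_s", "na_media_mM",
                           "gag_molar_mass_g_per_mol", "charge_per_gag")])
}

#' Batch GAG conversion for a table of panels
#'
#' @param panels data frame with columns `pre_t1_cells_ms`,
#'   `post_t1_cells_ms`, `pre_t1_media_ms`, `post_t1_media_ms` and
#'   optionally `label`.
#' @param ... constant overrides passed to [gd_panel()].
#' @return data frame with one row per panel: label, the four inputs,
#'   `gd_cells_mM`, `gd_media_mM`, `fcd_mM`, `gag_mg_per_mL`.
#' @export
gag_batch <- function(panels, ...) {
  need <- c("pre_t1_cells_ms", "post_t1_cells_ms",
            "pre_t1_media_ms", "post_t1_media_ms")
  if (!all(need %in% names(panels))) {
    stop("panels must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(panels)), function(i) {
    p <- gd_panel(panels$pre_t1_cells_ms[i], panels$post_t1_cells_ms[i],
                  panels$pre_t1_media_ms[i], panels$post_t1_media_ms[i], ...)
    r <- gag_pipeline(p)
    data.frame(
      label = if ("label" %in% names(panels)) panels$label[i] else as.character(i),
      panels[i, need],
      gd_cells_mM = r$gd_cells_mM, gd_media_mM = r$gd_media_mM,
      fcd_mM = r$fcd_mM, gag_mg_per_mL = r$gag_mg_per_mL,
      row.names = NULL
    )
  })
  do.call(rbind, out)
}
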