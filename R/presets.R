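#' Cell-type parameter presets
#'
#' Fully specified synthetic parameter sets for the two regimes the study
#' contrasts. `PSC_like` (stellate-cell regime): fast receptor activation,
#' fast nuclear import of phospho-STAT1 with nuclear dephosphorylation of
#' nearly equal magnitude, and slow nuclear export, producing a pronounced
#' nuclear accumulation of STAT1 (the total nuclear:cytoplasmic ratio peaks
#' near 3.5 within 540 min). `PC_like` (carcinoma regime): receptor
#' activation and phospho-STAT1 nuclear import more than ten-fold slower and
#' fast nuclear export, so STAT1 is phosphorylated but stays cytoplasmic
#' (ratio below 1.5 throughout).
#'
#' Initial conditions `stat1_uc0`/`stat1_un0` are computed with
#' [consistent_initial_stat1()] so the pre-stimulus state is an exact steady
#' state.
#'
#' @param cell_type `"PSC_like"` or `"PC_like"`.
#' @return A `pathway_parameters` object.
#' @examples
#' make_preset("PSC_like")[["k_act"]] / make_preset("PC_like")[["k_act"]]
#' @export
make_preset <- function(cell_type = c("PSC_like", "PC_like")) {
  cell_type <- match.arg(cell_type)
  base <- c(
    k_act = 0.01, k_inact = 0.01, R_tot = 1, k_phos = 1, k_inh = 2,
    k_impD = 0.05, k_impU = 0.01, k_exp = 0.017, k_deph = 0.05,
    k_tc_socs = 0.01, d_m_socs = 0.03, k_tl_socs = 0.05, d_socs = 0.02,
    b_m_stat = 0.02, k_tc_stat = 0.005, d_m_stat = 0.02, k_tl_stat = 0.01,
    d_stat = 0.001, tau_socs = 20, tau_stat = 60,
    s_pstat = 1, s_stat = 1, s_socs = 1, stat1_uc0 = 0, stat1_un0 = 0
  )
  if (cell_type == "PC_like") {
    base[c("k_act", "k_impD", "k_impU", "k_exp")] <-
      c(5e-4, 0.004, 0.02, 0.06)
  }
  ic <- consistent_initial_stat1(base)
  base[c("stat1_uc0", "stat1_un0")] <- ic
  p <- pathway_parameters(base)
  attr(p, "cell_type") <- cell_type
  p
}
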