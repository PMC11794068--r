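# Engine-free reference implementation of the Japan pricing model: the model
# algebra transcribed literally as straight-line arithmetic, with explicit
# delay and stock state. Shares no code with the simulation engine; used to
# cross-check sd_simulate() at every save point.

japan_oracle <- function(t_end = 50, dt = 1,
                         init = c("default", "zero", "equilibrium")) {
  init <- match.arg(init)
  n_steps <- as.integer(round(t_end / dt))

  # constants (criterion scores)
  serious_c <- 1; nhs_c <- 1; safety_c <- 1; rct_c <- 2; other_c <- 1
  favouring_c <- 1; becoming_c <- 1; faster_c <- 1; combination_c <- 1
  invasive_c <- 1; easy_c <- 1; stable_c <- 1
  newmech_c <- 2; major_c <- 2; signif_c <- 2; japanprem_c <- 2
  base_c <- 5

  # delay initial outputs; the SAKIGAKE premium and efficacy inputs are
  # algebraically constant, so their equilibrium values are known directly
  sak0 <- newmech_c + signif_c + japanprem_c + major_c
  d_sig <- switch(init,
                  zero = 0,
                  equilibrium = signif_c,
                  default = if (0.5 >= dt) 0 else signif_c)
  d_sak <- switch(init,
                  zero = 0,
                  equilibrium = sak0,
                  default = if (5 >= dt) 0 else sak0)
  d_rare <- d_sak; d_small <- d_sak; d_child <- d_sak
  stock <- 0

  cols <- c(
    "serious diseases without standard treatment score",
    "additional clinical significance of nhs accreditation score",
    "safety better than comparator score", "evidence from rct score",
    "evidence from other score", "favouring patient groups with poor outcomes score",
    "becoming a standard treatment option score", "faster onset/longing effects score",
    "combination to enhance effectiveness score",
    "reducing invasiveness of drug delivery score", "easy administration score",
    "stable blood level score", "new mechanism score", "major disease score",
    "significant improvement in efficacy score",
    "japan premiere/global synchronisation score", "special designation base",
    "serious diseases without standard treatment",
    "additional clinical significance of nhs accreditation",
    "safety better than comparator", "evidence from rct", "evidence from other",
    "favouring patient groups with poor outcomes",
    "becoming a standard treatment option", "faster onset/longing effects",
    "combination to enhance effectiveness", "reducing invasiveness of drug delivery",
    "easy administration", "stable blood level", "new mechanism", "major disease",
    "significant improvement in efficacy", "japan premiere/global synchronisation",
    "new action part", "new target", "validity better than comparator",
    "no standard in disease areas", "rare disease drug", "small market size",
    "children's drug", "new clinically useful mechanism",
    "more effective/safe than comparable drugs", "may improve disease or injury",
    "formulation improvements to enhance utility", "value premium",
    "marketability premium i", "marketability premium ii", "pediatrics premium",
    "sakigake premium", "new drug pricing decision variation",
    "new drug pricing decision evaluation")
  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = length(cols),
                dimnames = list(NULL, cols))

  for (k in 0:n_steps) {
    # score auxiliaries pass their constants through
    serious <- serious_c; nhs <- nhs_c; safety <- safety_c; rct <- rct_c
    other <- other_c; favouring <- favouring_c; becoming <- becoming_c
    faster <- faster_c; combination <- combination_c; invasive <- invasive_c
    easy <- easy_c; stable <- stable_c; newmech <- newmech_c; major <- major_c
    signif <- signif_c; japanprem <- japanprem_c

    new_action <- 2 + newmech
    new_target <- 1 + newmech
    validity <- 2 + d_sig + combination
    nostd <- 1 + serious
    rare <- base_c + d_rare
    small <- base_c + d_small
    child <- base_c + d_child
    ncum <- nhs + new_action + new_target + serious
    mes <- nhs + safety + validity + rct + other
    may <- nhs + becoming + favouring + nostd + combination + faster
    form <- invasive + easy + stable + nhs
    value <- form + may + ncum + mes
    mi <- rare; mii <- small; ped <- child
    sak <- newmech + signif + japanprem + major
    flow <- 1.8 * value + 1.15 * mi + 1.05 * mii + 1.125 * ped + 1.15 * sak

    out[k + 1L, ] <- c(
      serious_c, nhs_c, safety_c, rct_c, other_c, favouring_c, becoming_c,
      faster_c, combination_c, invasive_c, easy_c, stable_c, newmech_c,
      major_c, signif_c, japanprem_c, base_c,
      serious, nhs, safety, rct, other, favouring, becoming, faster,
      combination, invasive, easy, stable, newmech, major, signif, japanprem,
      new_action, new_target, validity, nostd, rare, small, child,
      ncum, mes, may, form, value, mi, mii, ped, sak, flow, stock)

    if (k < n_steps) {
      d_sig <- d_sig + (dt / 0.5) * (signif - d_sig)
      d_rare <- d_rare + (dt / 5) * (sak - d_rare)
      d_small <- d_small + (dt / 5) * (sak - d_small)
      d_child <- d_child + (dt / 5) * (sak - d_child)
      stock <- stock + dt * flow
    }
  }
  list(times = (0:n_steps) * dt, values = out)
}
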