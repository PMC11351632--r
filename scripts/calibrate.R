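#!/usr/bin/env Rscript
# Fits the per-age sticking hazards of the transport model so that the six
# canonical configurations reproduce the reference outcome statistics:
#   oocyte reached-%  (normal):  98 / 95 / 92     (20s / 30s / 40s)
#   oocyte reached-%  (endo):    91 / 82.5 / 74
#   sperm  reached-%  (normal):  84 / 63 / 33     (model operating point)
#   sperm  endometriosis reduction rate: 4.8 / 33.3 / 81.8 %
# The fitted hazards are printed; they are frozen into default_params().
# Multiplicative hazard updates: survival ~ exp(-h * T_eff) with T_eff
# approximately hazard-independent, so h <- h * log(target)/log(current)
# converges in a few rounds.
#
# Usage: Rscript scripts/calibrate.R [--quick]

suppressMessages({
  if (requireNamespace("oviductsim", quietly = TRUE)) {
    library(oviductsim)
  } else {
    devtools::load_all(".", quiet = TRUE)
  }
})

quick <- "--quick" %in% commandArgs(trailingOnly = TRUE)
n_oo <- if (quick) 800L else 2000L
n_sp <- if (quick) 2000L else 4000L
rounds <- if (quick) 2L else 3L

targets <- list(
  oocyte_normal = c("20s" = 98, "30s" = 95, "40s" = 92),
  oocyte_endo   = c("20s" = 91, "30s" = 82.5, "40s" = 74),
  sperm_normal  = c("20s" = 84, "30s" = 63, "40s" = 33),
  sperm_rate    = c("20s" = 4.8, "30s" = 33.3, "40s" = 81.8))

run_pct <- function(kind, age, endo, params, n, seed) {
  d <- simulation_design(kind, n_agents = n, n_replicates = 1L, seed = seed,
                         age_group = age, with_endometriosis = endo)
  r <- run_transport(d, params = params)
  100 * mean(r$agents$status == "reached_goal")
}

fit <- list()
for (age in c("20s", "30s", "40s")) {
  p <- default_params(age)
  kinds <- list(
    list(kind = "oocyte", n = n_oo, field = "oocyte",
         tgt_n = targets$oocyte_normal[[age]],
         tgt_e = targets$oocyte_endo[[age]]),
    list(kind = "sperm", n = n_sp, field = "sperm",
         tgt_n = targets$sperm_normal[[age]],
         tgt_e = targets$sperm_normal[[age]] *
           (1 - targets$sperm_rate[[age]] / 100)))
  for (kk in kinds) {
    # 1) base wall hazard against the normal-tube target
    for (it in seq_len(rounds + 1L)) {
      pct <- run_pct(kk$kind, age, FALSE, p, kk$n, seed = 100 + it)
      if (it > rounds) break
      ratio <- log(kk$tgt_n / 100) / log(max(pct, 0.5) / 100)
      p[[kk$field]]$h_wall <- p[[kk$field]]$h_wall * ratio
    }
    cat(sprintf("%s %s normal: %.1f%% (target %.1f) h_wall = %.4g\n",
                age, kk$kind, pct, kk$tgt_n, p[[kk$field]]$h_wall))
    # 2) lesion hazard against the endometriosis target, base fixed
    for (it in seq_len(rounds + 1L)) {
      pct_e <- run_pct(kk$kind, age, TRUE, p, kk$n, seed = 200 + it)
      if (it > rounds) break
      surv_extra_cur <- max(pct_e, 0.2) / max(pct, 0.5)
      surv_extra_tgt <- kk$tgt_e / kk$tgt_n
      ratio <- log(surv_extra_tgt) / log(min(surv_extra_cur, 0.999))
      p[[kk$field]]$h_lesion <- p[[kk$field]]$h_lesion * ratio
    }
    cat(sprintf("%s %s endo:   %.1f%% (target %.1f) h_lesion = %.4g\n",
                age, kk$kind, pct_e, kk$tgt_e, p[[kk$field]]$h_lesion))
    fit[[paste(age, kk$field, sep = "_")]] <-
      c(h_wall = p[[kk$field]]$h_wall, h_lesion = p[[kk$field]]$h_lesion)
  }
}

cat("\nFitted hazards (freeze into default_params):\n")
for (nm in names(fit))
  cat(sprintf("  %-12s h_wall = %.4g   h_lesion = %.4g\n",
              nm, fit[[nm]]["h_wall"], fit[[nm]]["h_lesion"]))
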