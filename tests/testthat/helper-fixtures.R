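# Synthetic transport_result objects built directly from outcome counts,
# used to test the aggregation layer independently of the simulator.
fake_result <- function(kind = "oocyte", age = "20s", endo = FALSE,
                        reached_per_rep, n_per_rep = 100L) {
  n_rep <- length(reached_per_rep)
  agents <- do.call(rbind, lapply(seq_len(n_rep), function(r) {
    n_reached <- reached_per_rep[r]
    status <- c(rep("reached_goal", n_reached),
                rep("stuck", n_per_rep - n_reached))
    data.frame(id = seq_len(n_per_rep), replicate = r, kind = kind,
               status = status, mode = "n/a",
               stuck_at = ifelse(status == "stuck", "wall", "none"),
               t_final = 10, final_s = 0, stringsAsFactors = FALSE)
  }))
  design <- simulation_design(kind, n_agents = n_per_rep,
                              n_replicates = n_rep, age_group = age,
                              with_endometriosis = endo)
  structure(list(design = design, agents = agents), class = "transport_result")
}

# Quiet parameter set: no flow drive, no noise, no sticking; isolates the
# deterministic part of the agent update rule.
quiet_params <- function(age = "20s") {
  p <- default_params(age)
  p$compliance <- 0
  p$c_cal <- 0
  p$sperm$sigma_r <- 0; p$sperm$sigma_theta <- 0
  p$sperm$h_wall <- 0; p$sperm$h_lesion <- 0
  p$oocyte$sigma_r <- 0; p$oocyte$sigma_theta <- 0
  p$oocyte$h_wall <- 0; p$oocyte$h_lesion <- 0
  p
}
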