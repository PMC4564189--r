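#!/usr/bin/env Rscript
# Simulate the four single-molecule primer-extension conditions of the
# polymerase-exchange experiment: the fast replicative polymerase alone
# (5 nM), with a 60-fold molar excess of the slow TLS polymerase (300 nM),
# with a 180-fold excess of its clamp-binding-deficient catalytic domain
# (900 nM; disrupts active Pol III synthesis but cannot synthesize
# processively itself), and with the displacement-dead T120P variant of
# that domain (900 nM; no disruption).
#
# Writes per-condition trajectory and ground-truth CSVs plus a manifest
# under results/.

suppressPackageStartupMessages(library(flowstretch))

seed <- 20260930
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

# Binding rates during a pause are proportional to concentration with a
# species-specific rate constant: Pol III at 0.01 /s/nM (5 nM -> 0.05/s,
# ~20 s waits) and Pol IV at 1.7e-4 /s/nM, two orders weaker per molecule
# (Pol III's affinity for the clamp-loaded primer terminus is far higher),
# so that at the 60-fold molar excess both polymerases contribute events.
# The clamp-less catalytic domain does not bind the clamp and contributes
# no synthesis events, only a displacement hazard on active Pol III equal
# to its intrinsic termination hazard (measured effect: half processivity).
k_bind_pol3 <- 0.01
k_bind_pol4 <- 1.7e-4
base <- sim_config(n_molecules = 60)

conditions <- list(
  pol3_alone = {
    c0 <- base
    c0$pause_exit_rates <- c(pol3 = k_bind_pol3 * 5, pol4 = 0)
    c0
  },
  pol3_pol4 = {
    c0 <- base
    c0$pause_exit_rates <- c(pol3 = k_bind_pol3 * 5,
                             pol4 = k_bind_pol4 * 300)
    # full-length Pol IV at 60-fold excess also displaces active Pol III
    c0$displacement_hazard <- c0$pol3_term_hazard
    c0$concentrations["pol4"] <- 300
    c0
  },
  pol3_pol4CD = {
    c0 <- base
    c0$pause_exit_rates <- c(pol3 = k_bind_pol3 * 5, pol4 = 0)
    c0$displacement_hazard <- c0$pol3_term_hazard
    c0$concentrations["pol4"] <- 900
    c0
  },
  pol3_pol4CD_T120P = {
    c0 <- base
    c0$pause_exit_rates <- c(pol3 = k_bind_pol3 * 5, pol4 = 0)
    c0$displacement_hazard <- 0
    c0$concentrations["pol4"] <- 900
    c0
  })

cat("Simulating", length(conditions), "conditions x",
    base$n_molecules, "molecules ...\n")
sim <- simulate_experiment(conditions, seed = seed)

traj_path <- file.path(out_dir, "trajectories.csv")
truth_path <- file.path(out_dir, "truth_events.csv")
write_trajectories_csv(trajectories_df(sim), traj_path)
utils::write.csv(truth_events_df(sim), truth_path, row.names = FALSE)

for (lab in names(conditions))
  write_config_yaml(sim[[lab]]$config,
                    file.path(out_dir, paste0("config_", lab, ".yaml")))

write_report_json(
  run_manifest("01_simulate", seed = seed,
               outputs = c(traj_path, truth_path)),
  file.path(out_dir, "manifest_01_simulate.json"))

tot <- tapply(truth_events_df(sim)$nt_end - truth_events_df(sim)$nt_start,
              truth_events_df(sim)$condition, sum)
cat("Done.  Total true synthesis per condition (bp):\n")
print(round(tot))
cat("Molar excess of the catalytic domain over Pol III:",
    fold_excess(900, 5), "fold\n")
cat("Wrote", traj_path, "and", truth_path, "\n")
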