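#!/usr/bin/env Rscript
# Step 1: simulate a desk-scale pegboard session.
#
# One participant runs a scaled version of the two-block design (baseline,
# then digital anesthesia of the nondominant hand): both hands, one round,
# two series per round, eight pegs per phase. Full-scale sessions (4 rounds
# x 5 series) have the same structure and just take proportionally longer.
# Streams land in scratch/ (large, regenerable); the manifest and ground
# truth go to results/.

suppressMessages({library(gazehand); library(dplyr); library(readr)})
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

seed <- 20260918
sch <- build_schedule(exp1_design()) %>% filter(round == 1, series <= 2)
cat("schedule:", nrow(sch), "trials over",
    nrow(distinct(sch, block, hand, series, phase)), "phases\n")

ses <- simulate_session(sch, sim_params(), seed = seed)
write_session(ses, "scratch/session_exp1")
write_csv(ses$truth$cell_params, "results/01_injected_params.csv")
cat("injected parameters by cell:\n")
print(as.data.frame(distinct(ses$truth$cell_params, condition, treated,
                             gaze_lead_ms, kappa)))
cat("wrote scratch/session_exp1 (streams) and results/01_injected_params.csv\n")
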