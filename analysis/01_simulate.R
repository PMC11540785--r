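#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Draws 30 participants with a latent lower-limb strength factor, their
# demographics, and the five raw muscle parameters (vertical jump, 1RM leg
# extension/curl, isometric leg extension/curl), then derives the
# weight-normalized ratios and the composite strength index (z-score sum).
# Writes results/cohort.csv and the frozen standardizer.

suppressMessages(library(exostrength))

dir.create("results", showWarnings = FALSE)
cfg <- simulation_config(n_participants = 30, master_seed = 20260924)

cohort <- generate_muscle_parameters(generate_cohort(cfg), cfg)
cohort <- weight_normalize(cohort)
std <- fit_standardizer(cohort)
cohort$total_performance <- total_performance(cohort, std)

utils::write.csv(cohort, "results/cohort.csv", row.names = FALSE)
write_standardizer(std, "results/standardizer.csv")

cat("Simulated cohort: n =", nrow(cohort), "\n")
cat(sprintf("  sex: %d male / %d female\n", sum(cohort$sex == "male"),
            sum(cohort$sex == "female")))
for (v in c("weight", "height", "age", "vj", "rm_le_lc_weight",
            "iso_le_lc_weight"))
  cat(sprintf("  %-18s %8.2f +/- %.2f\n", v, mean(cohort[[v]]),
              sd(cohort[[v]])))
cat(sprintf("  composite index mean %.2e (by construction 0), SD %.2f\n",
            mean(cohort$total_performance), sd(cohort$total_performance)))

# one illustrative session bundle on disk (squat, constant 60 RPM)
s <- generate_session(cohort[1, ], exercise_protocol("squat", "const"),
                      fatigue_model(), cfg)
write_session(s, "results/example_session_squat_const.csv")
cat(sprintf("Example session written: %d planted reps over %g s\n",
            length(s$rep_times), s$protocol$duration_s))
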