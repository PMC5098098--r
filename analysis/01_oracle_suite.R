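#!/usr/bin/env Rscript
# Step 1 — verify the forward solver before any experiment runs.
#
# Gates: homogeneous-cylinder resistance vs the closed form d/(sigma*pi*a^2),
# exact zero reactance for a purely resistive medium, reciprocity under
# drive/sense exchange, electrode current conservation, and a Richardson
# refinement study whose empirical order should sit near 2.

suppressMessages(library(eimsim))

man <- run_experiment("oracle_suite", out_dir = "results",
                      resolution = "medium")
rep <- brute_force_fine_grid(oracle_case_homogeneous())
cat("\nRefinement study (homogeneous cylinder):\n")
print(rep$levels)
cat(sprintf("empirical order %.2f; extrapolated R %.4f ohm vs closed form %.4f ohm\n",
            rep$order[length(rep$order)], Re(rep$Z_ref),
            oracle_case_homogeneous()$R_ref))
cat("Artifacts:", paste(man$outputs, collapse = ", "), "\n")
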