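#!/usr/bin/env Rscript
# Cycle-length sweep: simulate cycle lengths 28-56 days under the two
# clinical G-CSF settings (none, and start 5 / duration 5) and write the
# median kpiL and kpiB curves. By default a coarse sweep (every 4 days);
# pass --step 1 for the full 29-length sweep.
#
# Usage: Rscript analysis/03_cycle_length.R [--seed 1] [--step 4] [--out results]

suppressPackageStartupMessages(library(cytotwin))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- which(args == flag); if (length(i)) args[i + 1] else default
}
seed <- as.integer(arg("--seed", "1"))
step <- as.integer(arg("--step", "4"))
out <- arg("--out", "results")
tab <- arg("--cohort-table", file.path(out, "cohort_synthetic.tsv"))
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohorts <- if (file.exists(tab)) {
  sp <- split_cohort(load_cohort(tab)); list(hdac = sp$HDAC, idac = sp$IDAC)
} else make_virtual_trial(seed = seed)

lengths <- unique(c(seq(28, 56, by = step), 42))
grid <- enumerate_study(gcsf = data.frame(offset = integer(0),
                                          duration = integer(0)),
                        cycle_lengths = lengths)
grid <- grid[grid$part == 2, ]
message("simulating ", nrow(grid), " settings x 65 twins x 2 arms ...")
kpi <- run_kpi_table(grid, cohorts$hdac, cohorts$idac, progress = TRUE)

cl_L <- kpi_cycle_length_curves(kpi, "kpiL")
cl_B <- kpi_cycle_length_curves(kpi, "kpiB")
wt <- function(d, f) write.table(d, file.path(out, f), sep = "\t",
                                 quote = FALSE, row.names = FALSE)
wt(cl_L, "cycle_curves_kpiL.tsv")
wt(cl_B, "cycle_curves_kpiB.tsv")

for (co in c("HDAC", "IDAC")) {
  sub <- cl_B[cl_B$cohort == co & cl_B$arm == "AC123" & cl_B$gcsf == "none", ]
  sub <- sub[order(sub$cycle_length), ]
  cat(sprintf("%s AC123 no-G-CSF: cycle-1 kpiB %.2f at %d d -> %.2f at %d d\n",
              co, sub$median[1], sub$cycle_length[1],
              sub$median[nrow(sub)], sub$cycle_length[nrow(sub)]))
}
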