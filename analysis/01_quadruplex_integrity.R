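#!/usr/bin/env Rscript
# Structural integrity of an RNA G-quadruplex: Hoogsteen hydrogen-bond
# counting and G-quartet detection on the idealized five-tetrad tetrameric
# fixture, the in-silico stand-in for an isolated TERRA10 rG4.
#
# Finding: the fixture carries exactly 8 Hoogsteen bonds per quartet - 40
# for five stacked quartets - and tetrad detection recovers all five levels
# with the i -> i+6 within-strand stacking offset used in construction.

suppressMessages(library(g4kit))
dir.create("results", showWarnings = FALSE)

frm <- build_ideal_g4(g4_fixture_spec(n_tetrads = 5, topology = "tetrameric"))
traj <- trajectory(list(frm, frm, frm), dt = 100)  # static, dt in ps

counts <- count_hoogsteen(traj)
per_mol <- count_hoogsteen(traj, per_molecule = TRUE)
cat(sprintf("Hoogsteen bonds per frame (five-tetrad fixture): %s\n",
            paste(counts$count, collapse = ", ")))
cat(sprintf("Per-strand split, frame 1: %s (sum %d)\n",
            paste(per_mol$count[per_mol$frame == 1], collapse = " + "),
            sum(per_mol$count[per_mol$frame == 1])))

tets <- detect_tetrads(frm)
cat(sprintf("Detected G-quartets: %d (stack levels %s)\n", length(tets),
            paste(sort(vapply(tets, function(t) t$stack_level, integer(1))),
                  collapse = ",")))

stack <- tetrad_stack_report(tets, frm)
cat(sprintf("Within-strand stacking offsets: %s\n",
            paste(unique(stack$offset), collapse = ", ")))

# sensitivity of the count to scaling n_tetrads: 8 bonds per quartet
scaling <- do.call(rbind, lapply(1:6, function(n) {
  f <- build_ideal_g4(g4_fixture_spec(n_tetrads = n))
  data.frame(n_tetrads = n,
             hoogsteen = count_hoogsteen(trajectory(list(f)))$count,
             tetrads = length(detect_tetrads(f)))
}))
print(scaling, row.names = FALSE)

write.csv(counts, "results/hoogsteen_counts.csv", row.names = FALSE)
write.csv(stack, "results/tetrad_stack_report.csv", row.names = FALSE)
write.csv(scaling, "results/hoogsteen_scaling.csv", row.names = FALSE)
cat("written: results/hoogsteen_counts.csv, tetrad_stack_report.csv,",
    "hoogsteen_scaling.csv\n")
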