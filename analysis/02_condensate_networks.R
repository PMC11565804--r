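#!/usr/bin/env Rscript
# Contact-network, crowder and shape analyses of a synthetic protein-rG4
# condensate, emulating a crowded multi-chain simulation box: each RNA is
# engineered with 3 protein partners (the multivalency reported for
# condensed-phase rG4s), PEG-like crowders sit within 6 A of the assembly,
# and a shell fixture exercises the hollow-core estimator.
#
# Finding: the contact graph recovers the constructed 3 partners per RNA,
# every crowder registers within the 6 A proximity cutoff, and the
# ring/shell fixture yields a hollow-core diameter matching its inner
# radius by construction.

suppressMessages(library(g4kit))
dir.create("results", showWarnings = FALSE)

traj <- generate_condensate_frames(n_protein = 9, n_rna = 3, n_crowder = 4,
                                   contacts_per_rna = 3, n_frames = 10,
                                   displacement_D = 0, dt = 0.1, seed = 42)

g <- contact_graph(traj$frames[[1]], contact_criteria(cutoff = 8))
deg <- contact_partners(g, "rna")
cat(sprintf("Protein partners per RNA (8 A cutoff): %s\n",
            paste(deg, collapse = ", ")))

mv <- multivalency_series(traj)
cat(sprintf("Mean partners per RNA over %d frames: %.2f\n",
            n_frames(traj), mean(mv$mean_partners[mv$side == "rna"])))

cr <- crowder_proximity(traj, contact_criteria(cutoff = 6))
cat(sprintf("Crowders within 6 A of protein/RNA, per frame: %s\n",
            paste(cr$count, collapse = ", ")))

# hollow shell fixture: molecule centers on a shell of inner radius 30 A
shell <- generate_condensate_frames(n_protein = 30, n_rna = 0, n_crowder = 0,
                                    contacts_per_rna = 0,
                                    core_inner_radius = 30, n_frames = 1,
                                    seed = 7)
prof <- radial_density_profile(shell$frames[[1]], species = "protein",
                               n_bins = 20, center = c(0, 0, 0))
core <- estimate_core_diameter(prof)
cat(sprintf("Hollow-core diameter of the shell fixture: %.1f A (%.1f nm)\n",
            core, core / 10))

# conformational clustering of one protein chain over a mobile trajectory
mob <- generate_condensate_frames(n_protein = 1, n_rna = 1, n_crowder = 0,
                                  contacts_per_rna = 1, n_frames = 12,
                                  displacement_D = 1e-8, dt = 0.1, seed = 3)
cl <- cluster_conformations(mob, rmsd_cutoff = 0.2)
cat(sprintf("GROMOS clustering (0.2 nm): %d cluster(s); representative frame %d\n",
            length(cl$centers), cl$centers[1]))

write.csv(g$edges, "results/contact_edges.csv", row.names = FALSE)
write.csv(mv, "results/multivalency_series.csv", row.names = FALSE)
write.csv(cr, "results/crowder_proximity.csv", row.names = FALSE)
write.csv(prof, "results/radial_density_profile.csv", row.names = FALSE)
write.csv(data.frame(frame = seq_along(cl$assignments),
                     cluster = cl$assignments),
          "results/cluster_assignments.csv", row.names = FALSE)
cat("written: results/contact_edges.csv, multivalency_series.csv,",
    "crowder_proximity.csv, radial_density_profile.csv,",
    "cluster_assignments.csv\n")
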