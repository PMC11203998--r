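#!/usr/bin/env Rscript
# Stage 2 — steered pull of the toy ligand out of the pocket with the
# moving restraint (the stage that seeds the metadynamics walkers): the
# harmonic centre moves 0.4 -> 4.5 nm over 5 ns while the spring stiffens
# 0 -> 1000 kJ/mol/nm^2, with the funnel restraint active throughout.
# The pulled trajectory supplies walker start points spaced 0.3 nm apart
# along the funnel axis.

library(funnelmetad)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)
seed <- 1L

pot <- build_funnel_pocket_3d(20, 0.3, 1000)
fun <- funnel_geometry()
sch <- smd_schedule_preset("hold")

# 5 ns pull at dt = 1 fs
ip <- integrator_params("baoab", dt = 0.001, friction = 5,
                        temperature = 310, n_steps = 5e6, save_stride = 500)
r <- run_metad(c(0, 0, 0.4), pot, ip, funnel = fun, restraint = sch,
               seed = seed)
write_colvar(r$colvar, file.path(out_dir, "smd_colvar.tsv"))

# walker seeds: the saved frame nearest each target CV1 position
starts <- walker_start_positions(10)
seed_frames <- vapply(starts, function(s)
  which.min(abs(r$colvar$cv1 - s)), integer(1))
seeds <- r$colvar[seed_frames, c("time", "cv1", "x", "y", "z")]
seeds$target_cv1 <- starts
utils::write.table(seeds, file.path(out_dir, "walker_seeds.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
message(sprintf("-- pull reached CV1 = %.2f nm; %d walker seeds at %s nm",
                max(r$colvar$cv1), length(starts),
                paste(sprintf("%.1f", starts), collapse = ", ")))
message(sprintf("   final restraint centre %.2f nm, kappa %.0f kJ/mol/nm^2",
                moving_restraint(0, sch, 5000)$center,
                moving_restraint(0, sch, 5000)$kappa))

write_manifest(file.path(out_dir, "02_manifest.yaml"), "smd", seed,
               extra = list(cv1_final = r$colvar$cv1[nrow(r$colvar)]))
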