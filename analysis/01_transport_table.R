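#!/usr/bin/env Rscript
# Transport properties of the dye and drug panel.
#
# Regenerates the hard-sphere / Stokes-Einstein transport table for the
# six molecules characterized on the device: hydrodynamic radius from
# molecular weight and bulk density, diffusivity at T = 310.15 K with
# mu = 1.01e-3 Pa s, and the time to diffuse across the 150 um mixing
# channel. The slowest molecule (the visualization dye, ~34 s) sets the
# flow rate at which the serpentine mixers fully mix.

suppressMessages(library(mcggtools))

dir.create("results", showWarnings = FALSE)

tab <- transport_table(study_molecules(),
                       transport_conditions(temperature = 310.15,
                                            viscosity = 1.01e-3),
                       distance = 150e-6)
utils::write.csv(tab, "results/transport_table.csv", row.names = FALSE)

cat("Transport table (x = 150 um):\n")
print(cbind(tab[, 1:3],
            radius_A = round(tab$radius_m * 1e10, 2),
            D_e10_m2_s = round(tab$diffusivity_m2_s * 1e10, 2),
            t_s = round(tab$crossing_time_s, 1)), row.names = FALSE)

slowest <- tab[which.max(tab$crossing_time_s), ]
cat(sprintf("\nSlowest crossing: %s at %.1f s -> sets the complete-mixing flow rate.\n",
            slowest$name, slowest$crossing_time_s))
cat(sprintf("Temozolomide crosses %.1fx faster than the dye.\n",
            slowest$crossing_time_s /
              tab$crossing_time_s[tab$name == "Temozolomide"]))

# Mean linear velocity when two 1 uL/min inlets feed the four parallel
# 150 x 50 um perfusion channels: near-capillary flow (~1.1 mm/s).
v <- mean_velocity(2e-9 / 60, 4, 150e-6, 50e-6)
cat(sprintf("Perfusion linear velocity at 1 uL/min per inlet: %.2f mm/s\n",
            v * 1e3))
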