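#!/usr/bin/env Rscript
# Compute the pitch-roll potential energy landscape of the standardized
# body resting on one ground contact (yaw fixed at 0), on a 2-degree grid,
# and locate its basins: the flat resting orientations should be the global
# minima, with barriers toward on-the-side poses.

library(righting)

dir.create("results", showWarnings = FALSE)

mesh <- default_body_mesh()
m_body <- 28.4e-6 - total_leg_mass(default_leg_morphometrics())
grid <- seq(-pi, pi - pi / 90, by = pi / 90)

t0 <- Sys.time()
L <- pe_landscape(mesh, m_body, pitch = grid, roll = grid)
write_pe_landscape(L, "results/pe_landscape.csv")

imin <- arrayInd(which.min(L$PE), dim(L$PE))
imax <- arrayInd(which.max(L$PE), dim(L$PE))
message(sprintf("grid %dx%d computed in %.1f s", length(grid), length(grid),
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
message(sprintf("PE minimum %.3g uJ at pitch %.0f deg, roll %.0f deg",
                1e6 * min(L$PE), L$pitch[imin[1]] * 180 / pi,
                L$roll[imin[2]] * 180 / pi))
message(sprintf("PE maximum %.3g uJ at pitch %.0f deg, roll %.0f deg",
                1e6 * max(L$PE), L$pitch[imax[1]] * 180 / pi,
                L$roll[imax[2]] * 180 / pi))
message(sprintf("barrier from flat rest: %.3g uJ",
                1e6 * (max(L$PE) - min(L$PE))))
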