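#!/usr/bin/env Rscript
# Random-circuit-perturbation ensembles on the core and coupled
# topologies (1,000 models x 3 replicates), with phase frequencies and
# topology comparison t-tests.
#
# Finding: both ensembles are dominated by monostable phases; the hybrid
# state appears in a few percent of models.  In this reimplementation the
# coupled topology does NOT increase the {E,H} or {E,H,M} frequencies
# relative to the core (the direction reported for the original ensemble
# tool is reversed here; see the methods vignette for the analysis).

library(emtnfatc)
dir.create("results", showWarnings = FALSE)

pf <- phase_frequencies(list(core = core_topology(),
                             coupled = wildtype_topology()),
                        n_models = 1000, replicates = 3, seed = 42)
print(pf$summary)
print(pf$tests)
write.csv(pf$summary, "results/phase_frequencies.csv", row.names = FALSE)
write.csv(pf$tests, "results/phase_tests.csv", row.names = FALSE)
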