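#!/usr/bin/env Rscript
# Step 5: verification benchmarks of the numerical core: constant-strain
# patch test, uniaxial compression closed form, principal-stress eigen
# oracle, and a rigid sphere pressed into an elastic block against the Hertz
# closed form.

library(dlmfem)

dir.create("results", showWarnings = FALSE)
suite <- verify_suite()
print(suite, row.names = FALSE, digits = 4)
write.csv(suite, "results/verification.csv", row.names = FALSE)

hz <- benchmark_hertz()
cat(sprintf("\nHertz detail: p_peak %.4f MPa vs p0 %.4f MPa (%.1f%% error); contact radius %.2f mm (theory %.2f mm); total force %.1f N\n",
            hz$p_peak, hz$p0_hertz, 100 * hz$rel_error, hz$a_fe, hz$a_hertz,
            hz$total_force))
if (!all(suite$pass)) stop("verification benchmark failed")
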