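# Shared fixtures for the test suite. Everything is built in code; the
# physiology objects and a couple of reference simulations are cached per
# session because they are reused across files.

rat_phys <- physiology_at_age("rat")
human_phys <- physiology_at_age("human")

# single oral 40 mg/kg bw in the rat, 182 days: the classical excretion /
# half-life design
rat_40mgkg_sim <- local({
  simulate_cd(single_oral(mg_per_kg(40), species = "rat"), rat_params(),
              rat_phys, duration = days(182),
              times = days(seq(0, 182, by = 0.5)))
})

# a degenerate one-compartment parameterisation: uniform partitioning,
# effectively instantaneous tissue exchange, no binding, urinary-only
# elimination
one_compartment_params <- function(species = "rat", k_urine = 0.001) {
  cd_params(species,
            P_lung = 1, P_brain = 1, P_skin = 1, P_adipose = 1, P_liver = 1,
            P_rest = 1,
            PA_brain = 1e4, PA_skin = 1e4, PA_adipose = 1e4, PA_liver = 1e4,
            BIND = 0, LIBMAXCD1 = 0,
            CL_bile = 0, k_ent = 0, k_urine = k_urine, KBILE = 0)
}
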