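#!/usr/bin/env Rscript
# Step 3: traffic-light zone coding and AIDA classification of the
# synthetic cohort, plus the class-by-outcome gradient (class 0 should be
# almost entirely non-cesarean, class 4 almost entirely cesarean).

library(aidalabor)

cohort <- read_cohort("results/synthetic_cohort.csv")
profiles <- zone_profile(cohort)
write.csv(profiles, "results/zone_profiles.csv", row.names = FALSE)

icd <- binary_outcome(cohort$delivery_outcome) == "ICD"
gradient <- data.frame(
  aida_class = sort(unique(profiles$aida_class)),
  n = as.vector(table(profiles$aida_class)),
  icd_fraction = as.vector(tapply(icd, profiles$aida_class, mean)))
write.csv(gradient, "results/class_outcome_gradient.csv", row.names = FALSE)

message("AIDA class distribution and cesarean fraction per class:")
print(gradient, digits = 3)
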