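#!/usr/bin/env Rscript

# Step 1: simulate the study population.
#
# Generates the default synthetic cohort: 1000 users who disclose intake of
# an antidepressant and 1000 controls, four years of timestamped posts,
# treatment assignment confounded by follower count and baseline symptom
# burden, heterogeneous post-treatment improvement, and planted side-effect
# phrases in the post-treatment language of improved vs non-improved users.
# Writes the corpus (JSONL + sidecars) under results/corpus/.

suppressPackageStartupMessages(library(pharmvig))

dir.create("results/corpus", showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = 20260924L)
corpus <- generate_population(cfg)
write_corpus(corpus, "results/corpus/timelines.jsonl")

tr <- corpus$truth
cat(sprintf("users: %d (%d treated), posts: %d\n",
            nrow(tr), sum(tr$is_treatment), nrow(corpus$posts)))
cat(sprintf("baseline symptom rate: mean %.3f (sd %.3f)\n",
            mean(tr$baseline_rate), sd(tr$baseline_rate)))
cat(sprintf("improvement effect among treated: mean %.3f (sd %.3f)\n",
            mean(tr$delta[tr$is_treatment]), sd(tr$delta[tr$is_treatment])))
smd <- abs(mean(tr$log_followers[tr$is_treatment]) -
           mean(tr$log_followers[!tr$is_treatment])) /
  sqrt((var(tr$log_followers[tr$is_treatment]) +
        var(tr$log_followers[!tr$is_treatment])) / 2)
cat(sprintf("planted confounding, log-followers SMD: %.3f\n", smd))
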