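#!/usr/bin/env Rscript

# Step 3: side-effect language of the contrasting cohorts.
#
# Prints the SAGE contrastive keywords of the most- vs least-improved
# cohorts and the normalized co-occurrence prevalence of n-grams around the
# side-effect seed terms, and checks recovery of the planted phrases.

suppressPackageStartupMessages(library(pharmvig))

res <- run_pipeline("results/corpus/timelines.jsonl",
                    pipeline_config(seed = 42L),
                    outdir = NULL)
drug <- names(res$keywords)[1]
kw <- res$keywords[[drug]]

cat(sprintf("drug: %s\n\nkeywords salient in the MOST improved cohort:\n", drug))
print(kw$a[, c("term", "eta", "rank")], row.names = FALSE)
cat("\nkeywords salient in the LEAST improved cohort:\n")
print(kw$b[, c("term", "eta", "rank")], row.names = FALSE)

cfg <- sim_config()
cat(sprintf("\nplanted improved terms in top-20: %d/5\n",
            sum(cfg$planted_terms_improved %in% kw$a$term)))
cat(sprintf("planted worsened terms in top-20: %d/5\n",
            sum(cfg$planted_terms_worsened %in% kw$b$term)))

cat("\nco-occurrence prevalence around side-effect seeds (top rows):\n")
print(head(res$prevalence[[drug]]$comparison, 12), row.names = FALSE)

dir.create("results/keywords", showWarnings = FALSE, recursive = TRUE)
write.table(rbind(transform(kw$a, cohort = "most_improved"),
                  transform(kw$b, cohort = "least_improved")),
            "results/keywords/sage_keywords.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res$prevalence[[drug]]$comparison,
            "results/keywords/prevalence_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
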