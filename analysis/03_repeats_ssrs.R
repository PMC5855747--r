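#!/usr/bin/env Rscript
# Step 3: SSR landscape and long repeats.
#
# Scans the simulated genome for microsatellites under the copy-number
# cutoffs (mono >= 8, di >= 4, tri- through hexa >= 3) and for long
# repeats of the four orientation classes (>= 30 bp, >= 90% identity),
# then summarizes by motif class, genomic region, functional context,
# repeat type and length bin. Because the background was screened, every
# hit should match a planted feature from the truth table; the script
# reports recall/precision against it.
#
# Outputs: results/{ssr_hits,ssr_summary_*,repeat_hits,repeat_summary_*}.tsv

library(plastomekit)

rec <- read_plastome("results/simulated/genome.fasta", format = "gff3")
ir <- detect_ir(rec)
part <- partition_from_ir(rec, ir)
truth <- utils::read.delim("results/simulated/truth_features.tsv")

ssr <- find_ssrs(rec, part)
write_tsv_report(ssr, "results/ssr_hits.tsv")
for (facet in c("motif_len", "region", "context"))
  write_tsv_report(repeat_summary(ssr, by = facet),
                   paste0("results/ssr_summary_", facet, ".tsv"))

reps <- find_long_repeats(rec, ir = ir)
write_tsv_report(reps, "results/repeat_hits.tsv")
for (facet in c("type", "length_bin"))
  write_tsv_report(repeat_summary(reps, by = facet),
                   paste0("results/repeat_summary_", facet, ".tsv"))

planted_ssr <- truth[truth$kind == "ssr", ]
planted_rep <- truth[truth$kind == "repeat", ]
ssr_recall <- mean(planted_ssr$start %in% ssr$start)
rep_recall <- mean(planted_rep$start %in% reps$start1)
message(sprintf("SSRs: %d found / %d planted (recall %.0f%%)",
                nrow(ssr), nrow(planted_ssr), 100 * ssr_recall))
message(sprintf("long repeats: %d found / %d planted (recall %.0f%%)",
                nrow(reps), nrow(planted_rep), 100 * rep_recall))
message(sprintf("precision: SSR %.0f%%, repeats %.0f%%",
                100 * mean(ssr$start %in% planted_ssr$start),
                100 * mean(reps$start1 %in% planted_rep$start)))
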