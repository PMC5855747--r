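#!/usr/bin/env Rscript
# Step 1: build the ground-truth study system.
#
# Generates a full-size quadripartite plastome matching the studied
# genome's dimensions (LSC 86,315 bp; SSC 18,491 bp; IRs 26,577 bp each;
# region GC 35.1/31.8/42.7%), carrying the complete 112-gene inventory
# with 17 IR-duplicated genes, plus planted SSRs, long repeats of all four
# classes, and an rps16-style primer construct bracketing 550 bp. The
# background is screened so that every SSR/repeat the scanners later find
# is planted, i.e. has known coordinates.
#
# Outputs: results/simulated/{genome.fasta,genome.gff3,genome.gb,
#          truth_features.tsv,partition.bed}

library(plastomekit)

seed <- 20260920L
dir.create("results/simulated", recursive = TRUE, showWarnings = FALSE)

spec <- plastome_spec(
  ssrs = data.frame(
    motif = c("A", "T", "AT", "TA", "AAT", "ATC"),
    copies = c(9, 10, 5, 4, 3, 3),
    region = c("LSC", "LSC", "LSC", "SSC", "LSC", "SSC")),
  repeats = data.frame(
    type = c("forward", "palindromic", "reverse", "complement"),
    length = c(35, 40, 32, 36),
    identity = c(1, 1, 1, 0.917),
    region = c("LSC", "LSC", "SSC", "LSC")),
  primers = data.frame(
    forward = "ACTTCGTTTGAGACGGTGTG",
    reverse = "AAAAACCCCGATTTCTTTGA",
    product_length = 550, region = "LSC"),
  seed = seed)

message("generating + screening the genome (takes a minute or two) ...")
g <- generate_plastome(spec)
rec <- g$record
message(sprintf("genome: %d bp, %d gene copies, residual accidental: %d",
                nchar(rec$sequence), nrow(gene_spans(rec$annotations)),
                if (is.null(g$truth$residual_accidental)) 0L
                else nrow(g$truth$residual_accidental)))

write_plastome(rec, "results/simulated/genome.fasta",
               "results/simulated/genome.gff3")
write_genbank(rec, "results/simulated/genome.gb")
write_partition_bed(g$truth$partition, rec$id,
                    "results/simulated/partition.bed")
write_tsv_report(g$truth$features, "results/simulated/truth_features.tsv")
message("wrote results/simulated/")
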