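#!/usr/bin/env Rscript
# Stage 1 — generate the study inputs with known ground truth.
#
# Emulates the three real-world inputs of the screen: a ClinVar-style PLP
# panel on a toy multi-exon gene, a multi-species alignment of that gene's
# contig with shared alleles planted in chosen species, and ancient-human
# read sets with planted heterozygous carriers. Everything is seeded and
# written as plain text under results/synthetic/ together with the
# generators' truth tables, so stages 2-3 can be checked cell-for-cell.

suppressPackageStartupMessages(library(plptrace))

seed <- 20260
out <- "results/synthetic"
dir.create(file.path(out, "sams"), recursive = TRUE, showWarnings = FALSE)

message("Generating a 400-variant PLP panel (published type mix) ...")
pan <- make_panel(400, noise_frac = 0.15, seed = seed)
kept <- filter_plp(pan$variants)
ann <- annotate_panel(kept, pan$transcript)
write_panel(ann, file.path(out, "panel.tsv"))
writeLines(pan$genome, file.path(out, "contig.txt"))
message("  ", nrow(pan$variants), " records -> ", nrow(kept),
        " after the PLP filter")

# plant three shared SNVs in chosen species and one equal/unequal gap pair
snvs <- ann[nchar(ann$ref) == 1 & nchar(ann$alt) == 1, ]
planted <- data.frame(variant_id = snvs$variant_id[1:3],
                      pos = snvs$pos[1:3], alt = snvs$alt[1:3],
                      species = c("sp1,sp2", "sp3", "sp4"),
                      stringsAsFactors = FALSE)
tree <- "((sp1:0.1,sp2:0.1):0.1,(sp3:0.15,sp4:0.15):0.05);"
cfg <- simulation_config(
  seed = seed, root_seq = pan$genome, chrom = "chrP", tree = tree,
  subst_rate = 0.05, gap_rate = 0.005,
  planted_shared = planted,
  ancient = list(n_samples = 25, coverage = 10, read_len = 76,
                 damage_rate = 0.1,
                 carriers = data.frame(
                   sample_id = sprintf("anc%03d", 1:5),
                   variant_id = snvs$variant_id[c(1, 1, 2, 2, 3)],
                   stringsAsFactors = FALSE)))

message("Simulating the multi-species alignment ...")
sim <- simulate_alignment(cfg)
writeLines(sim$maf, file.path(out, "alignment.maf"))
write.table(sim$truth, file.path(out, "alignment_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(tree, file.path(out, "tree.nwk"))
write.table(data.frame(species = paste0("sp", 1:4),
                       clade = c("PrimateLike", "PrimateLike",
                                 "AvesLike", "FishLike")),
            file.path(out, "clades.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
message("  planted SHARED cells: ",
        sum(sim$truth$state == "SHARED"), " of ", nrow(sim$truth))

message("Simulating 25 ancient read sets (5 carriers, 10% terminal damage) ...")
anc <- simulate_ancient(cfg, pan$genome, snvs[1:3, ])
for (id in names(anc$sams))
  writeLines(anc$sams[[id]], file.path(out, "sams", paste0(id, ".sam")))
write.table(anc$metadata, file.path(out, "samples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(anc$truth, file.path(out, "ancient_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  expected damage-free matches: ", sum(anc$truth$expected))
message("Inputs written under ", out)
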