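#!/usr/bin/env Rscript
# Stage 3 — ancient-sample screen.
#
# Runs the base-quality-filtered pileup over every simulated ancient read
# set against the SNV panel, reports the matches with their supporting
# evidence, verifies damage-free expectations from the truth table, and
# partitions any extra (damage-induced) matches by substitution class.

suppressPackageStartupMessages(library(plptrace))

inp <- "results/synthetic"
out <- "results/ancient"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- read.delim(file.path(inp, "panel.tsv"), stringsAsFactors = FALSE)
meta <- read.delim(file.path(inp, "samples.tsv"), stringsAsFactors = FALSE)
truth <- read.delim(file.path(inp, "ancient_truth.tsv"),
                    stringsAsFactors = FALSE)
snv_panel <- panel[panel$variant_id %in% unique(truth$variant_id), ]

message("Screening ", nrow(meta), " samples against ", nrow(snv_panel),
        " panel variants (min base quality 1) ...")
matches <- do.call(rbind, lapply(meta$sample_id, function(id) {
  s <- read_sam(file.path(inp, "sams", paste0(id, ".sam")), sample_id = id,
                age_bp = meta$age_bp[meta$sample_id == id],
                age_sd = meta$age_sd[meta$sample_id == id],
                site = meta$site[meta$sample_id == id])
  match_variants(s, snv_panel, min_bq = 1, min_alt_reads = 1)
}))
matches <- matches[order(-matches$age_bp, matches$sample_id, matches$pos), ]
write.table(matches, file.path(out, "matches.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE, na = "")

expected <- truth[truth$expected, ]
got_keys <- paste(matches$sample_id,
                  panel$variant_id[match(variant_key(matches),
                                         variant_key(panel))])
exp_keys <- paste(expected$sample_id, expected$variant_id)
message("  expected (damage-free) matches found: ",
        sum(exp_keys %in% got_keys), "/", length(exp_keys))
extra <- matches[!got_keys %in% exp_keys, ]
if (nrow(extra) > 0) {
  cls <- table(paste0(extra$ref, ">", extra$alt))
  message("  damage-induced extra matches by class: ",
          paste(names(cls), cls, sep = "=", collapse = ", "))
}

s <- summarize_matches(matches)
jsonlite::write_json(s, file.path(out, "summary.json"), auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("Ancient-screen reports written under ", out)
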