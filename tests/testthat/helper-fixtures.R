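# toy transcript with a hand-designed CDS so codon arithmetic is checkable:
# CDS = ATG GAT TGG AAA CCC GGG TTT ACA GCT TGA (10 codons), split 20 + 10
# over two exons; exon1 11-46 (5'UTR 11-20, coding 21-40), intron 47-60,
# exon2 61-100 (coding 61-70, 3'UTR 71-100)
toy_contig <- function() {
  seq <- rep("T", 120)
  cds <- strsplit("ATGGATTGGAAACCCGGGTTTACAGCTTGA", "")[[1]]
  seq[21:40] <- cds[1:20]
  seq[61:70] <- cds[21:30]
  seq[41:46] <- c("G", "C", "A", "A", "C", "G")   # exon1 3' edge + donor run
  seq[47:60] <- strsplit("GTAAGTACGTACAG", "")[[1]]  # intron
  paste(seq, collapse = "")
}

toy_transcript <- function(strand = "+") {
  ref <- toy_contig()
  if (strand == "+") {
    transcript_model("TOY", "chrToy", "+",
                     exons = data.frame(start = c(11L, 61L), end = c(46L, 100L)),
                     cds_start = 21L, cds_end = 70L,
                     domains = data.frame(label = c("DOM"), start_res = 3L,
                                          end_res = 5L, stringsAsFactors = FALSE),
                     ref_seq = ref)
  } else {
    # mirrored transcript on the reverse-complemented contig
    L <- nchar(ref)
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", ref), "")[[1]]), collapse = "")
    mirror <- function(p) L - p + 1L
    transcript_model("TOY", "chrToy", "-",
                     exons = data.frame(start = mirror(c(100L, 46L)),
                                        end = mirror(c(61L, 11L))),
                     cds_start = mirror(70L), cds_end = mirror(21L),
                     domains = data.frame(label = c("DOM"), start_res = 3L,
                                          end_res = 5L, stringsAsFactors = FALSE),
                     ref_seq = rc)
  }
}

# hand-written two-species MAF block (reference hg, species pan/mus)
toy_maf_lines <- function() {
  c("##maf version=1",
    "",
    "a score=1.0",
    "s hg.chr1  10 13 + 100 GCAGCTGAAA-ATA",
    "s pan.chr1  0 13 + 50  GCAGCTGAAA-ATA",
    "s mus.chr5  5 13 + 80  GCA-CTGTAACATA",
    "")
}

# one-read SAM text builder
sam_lines <- function(..., chrom = "chrS", len = 100L) {
  c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", chrom, len), ...)
}

sam_read <- function(qname, pos, cigar, seq, qual, chrom = "chrS",
                     flag = 0L, mapq = 30L) {
  paste(qname, flag, chrom, pos, mapq, cigar, "*", 0L, 0L, seq, qual,
        sep = "\t")
}

# phred+33 quality string from integer vector
qstr <- function(q) intToUtf8(q + 33L)
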