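# Small in-code fixtures shared across test files.

toy_annotation <- function() {
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:10),
    chromosome = rep(c("GM10", "GM02"), c(6, 4)),
    strand = "+",
    start = c(seq(1e5, by = 1e5, length.out = 6),
              seq(2e5, by = 2e5, length.out = 4)),
    end = c(seq(1e5, by = 1e5, length.out = 6),
            seq(2e5, by = 2e5, length.out = 4)) + 5000,
    exon_total_length = 1500,
    exon_count = 1L)
  suppressWarnings(genome_annotation(genes))
}

write_toy_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "GM01\ttest\tgene\t1000\t5000\t.\t+\t.\tID=geneA;family=MIKCc;subfamily=SEP",
    "GM01\ttest\texon\t1000\t2000\t.\t+\t.\tID=geneA.e1;Parent=geneA",
    "GM01\ttest\texon\t3000\t5000\t.\t+\t.\tID=geneA.e2;Parent=geneA",
    "GM01\ttest\tgene\t9000\t12000\t.\t-\t.\tID=geneB",
    "GM01\ttest\texon\t9000\t12000\t.\t-\t.\tID=geneB.e1;Parent=geneB"),
    path)
  path
}

# one valid 6-anchor block, one 4-anchor block (too short)
write_toy_collinearity <- function(path) {
  writeLines(c(
    "############### Parameters ###############",
    "# MATCH_SIZE: 5",
    "############### Statistics ###############",
    "## Alignment 0: score=300.0 e_value=0 N=6 GM10&GM02 plus",
    sprintf("0-%3d: a%d b%d 1e-50", 0:5, 1:6, 1:6),
    "## Alignment 1: score=200.0 e_value=0 N=4 GM10&GM03 plus",
    sprintf("1-%3d: a%d c%d 1e-40", 0:3, 1:4, 1:4)),
    path)
  path
}

rel_matrix <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  famfates:::expression_matrix(m, "RELATIVE")
}
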