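# Shared fixtures: deterministic toy genes and an independent brute-force
# PseAAC oracle (coded directly from the definition, no package internals).

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# one codon per amino acid, for building a CDS that translates to a given
# protein ("*" = TAA stop)
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT",
              "*" = "TAA")

cds_for_protein <- function(protein) {
  aa <- strsplit(paste0(protein, "*"), "")[[1]]
  paste(CODON_OF[aa], collapse = "")
}

# A single-transcript toy chromosome: lead + (CDS, optionally split by one
# intron) + tail.  `cds` is given in coding orientation; for strand "-" it
# is reverse-complemented onto the genome.
toy_gene <- function(cds, strand = "+", lead = strrep("G", 30),
                     tail = strrep("ACGT", 25), intron = NULL,
                     intron_after = NULL, chrom = "chrT") {
  gcds <- if (strand == "-") revcomp_chr(cds) else cds
  if (!is.null(intron)) {
    body <- paste0(substr(gcds, 1, intron_after), intron,
                   substring(gcds, intron_after + 1))
    ex_s <- c(nchar(lead), nchar(lead) + intron_after + nchar(intron))
    ex_e <- c(nchar(lead) + intron_after, nchar(lead) + nchar(body))
  } else {
    body <- gcds
    ex_s <- nchar(lead)
    ex_e <- nchar(lead) + nchar(body)
  }
  genome <- stats::setNames(paste0(lead, body, tail), chrom)
  tx <- transcript("TX1", chrom, strand, ex_s, ex_e,
                   ex_s[1], ex_e[length(ex_e)], gene = "G1")
  list(genome = genome, tx = tx)
}

snv <- function(pos, ref, alt, chrom = "chrT")
  list(chrom = chrom, pos = pos, ref = ref, alt = alt, id = "v1")

# a coding_change built directly, bypassing the genome projection
fake_cc <- function(wild, mutant, class = "missense",
                    first = which(strsplit(wild, "")[[1]] !=
                                    strsplit(mutant, "")[[1]])[1]) {
  structure(list(transcript_id = "TXF", gene = "GF", chrom = "chrT",
                 pos = 1L, ref = "A", alt = "C",
                 wild_protein = wild, mutant_protein = mutant,
                 variant_class = class, first_changed_aa = as.integer(first),
                 protein_len_wild = nchar(wild),
                 protein_len_mut = nchar(mutant)),
            class = "coding_change")
}

rand_aa <- function(n) paste(sample(AA_ALPHABET20, n, replace = TRUE),
                             collapse = "")

# independent raw scale copies (Tanford hydrophobicity, Hopp-Woods
# hydrophilicity)
ORACLE_H1 <- c(A =  0.62, C =  0.29, D = -0.90, E = -0.74, F =  1.19,
               G =  0.48, H = -0.40, I =  1.38, K = -1.50, L =  1.06,
               M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
               S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y =  0.26)
ORACLE_H2 <- c(A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
               G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
               M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
               S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)

# brute-force tier correlation factors straight from the definition
oracle_tau <- function(sequence, lambda, average = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  norm <- function(r) {
    x <- r[AA_ALPHABET20]
    (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
  }
  h1 <- norm(ORACLE_H1); h2 <- norm(ORACLE_H2)
  tau <- numeric(2 * lambda)
  if (lambda > 0) for (k in seq_len(lambda)) {
    s1 <- 0; s2 <- 0
    for (i in seq_len(L - k)) {
      s1 <- s1 + h1[[aa[i]]] * h1[[aa[i + k]]]
      s2 <- s2 + h2[[aa[i]]] * h2[[aa[i + k]]]
    }
    if (average) { s1 <- s1 / (L - k); s2 <- s2 / (L - k) }
    tau[2 * k - 1] <- s1; tau[2 * k] <- s2
  }
  tau
}

# brute-force amphiphilic PseAAC straight from the definition
oracle_pseaac <- function(sequence, lambda, w, average = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  L <- length(aa)
  norm <- function(r) {
    x <- r[AA_ALPHABET20]
    (x - mean(x)) / sqrt(sum((x - mean(x))^2) / 20)
  }
  h1 <- norm(ORACLE_H1); h2 <- norm(ORACLE_H2)
  tau <- numeric(2 * lambda)
  if (lambda > 0) for (k in seq_len(lambda)) {
    s1 <- 0; s2 <- 0
    for (i in seq_len(L - k)) {
      s1 <- s1 + h1[[aa[i]]] * h1[[aa[i + k]]]
      s2 <- s2 + h2[[aa[i]]] * h2[[aa[i + k]]]
    }
    if (average) { s1 <- s1 / (L - k); s2 <- s2 / (L - k) }
    tau[2 * k - 1] <- s1; tau[2 * k] <- s2
  }
  f <- vapply(AA_ALPHABET20, function(a) sum(aa == a), 0) / L
  D <- sum(f) + w * sum(tau)
  unname(c(f / D, w * tau / D))
}
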