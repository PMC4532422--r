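# Independent oracles used to cross-check the implementation.  These are
# deliberately naive re-derivations (hand-coded tables, brute-force loops,
# closed forms) that share no code with the package internals.

# vertebrate mitochondrial codon table, written out by hand
ORACLE_MITO_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "*", AGG = "*",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_revcomp <- function(bases) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[bases]))
}

# brute-force effect of a substitution: rebuild the whole CDS with and
# without the substituted base, translate both, compare the affected residue
oracle_coding_effect <- function(seq_vec, cds_start, cds_end, strand, pos, alt) {
  mutate_translate <- function(s) {
    cds <- s[cds_start:cds_end]
    if (strand == "-") cds <- oracle_revcomp(cds)
    while (length(cds) %% 3 != 0) cds <- c(cds, "A")  # polyadenylated stop
    codons <- apply(matrix(cds, nrow = 3), 2, paste, collapse = "")
    unname(ORACLE_MITO_CODE[codons])
  }
  ref_aa <- mutate_translate(seq_vec)
  s2 <- seq_vec
  s2[pos] <- alt
  alt_aa <- mutate_translate(s2)
  if (identical(ref_aa, alt_aa)) "synonymous" else "nonsynonymous"
}

# brute-force tally of quality-filtered observations
oracle_pileup_tally <- function(obs, baseq_min, mapq_min) {
  tal <- list()
  for (i in seq_len(nrow(obs))) {
    o <- obs[i, ]
    if (o$base_quality < baseq_min) next
    if (o$mapping_quality < mapq_min) next
    if (!o$base %in% c("A", "C", "G", "T")) next
    p <- ((o$position - 1) %% 16569) + 1
    key <- paste(p, o$strand)
    if (is.null(tal[[key]])) tal[[key]] <- c(A = 0, C = 0, G = 0, T = 0)
    tal[[key]][o$base] <- tal[[key]][o$base] + 1
  }
  tal
}

# caller decision rule, re-derived: call iff the best shared minor allele
# (same allele on both strands) reaches the threshold on each strand
oracle_call_decision <- function(fwd, rev, threshold) {
  df <- sum(fwd); dr <- sum(rev)
  if (df == 0 || dr == 0) return(FALSE)
  pooled <- fwd + rev
  major <- names(pooled)[which.max(pooled)]
  best <- -Inf
  for (b in setdiff(names(pooled), major)) {
    if (pooled[[b]] == 0) next
    best <- max(best, min(fwd[[b]] / df, rev[[b]] / dr))
  }
  is.finite(best) && best >= threshold
}

# closed-form 2x2 Pearson chi-square, no continuity correction
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# closed-form one-sample t against 0
oracle_t_onesample <- function(x) {
  n <- length(x)
  se <- sqrt(sum((x - mean(x))^2) / (n - 1)) / sqrt(n)
  t <- mean(x) / se
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# product-moment correlation from the definition
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# shared small genome for tests (generated once per test run)
test_genome <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- synthetic_genome(seed = 20151)
    g
  }
})

test_annotation <- local({
  a <- NULL
  function() {
    if (is.null(a)) a <<- read_region_annotation()
    a
  }
})

# IUPAC symbol for a ref/alt transition pair
het_symbol <- function(ref) if (ref %in% c("A", "G")) "R" else "Y"
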