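#' Normalize a coordinate onto the circular genome
#'
#' Positions at or below 0 and above 16,569 wrap modulo the genome length, so
#' reads spanning the origin and window arithmetic near the edges stay valid.
#'
#' @param position Integer vector (any value).
#' @return Integer vector in 1..16569.
#' @examples
#' normalize_circular(c(16570, 0, 3))  # 1 16569 3
#' @export
normalize_circular <- function(position) {
  p <- (as.integer(position) - 1L) %% MT_GENOME_LENGTH
  p + 1L
}

empty_pileup <- function(ref_bases) {
  n <- MT_GENOME_LENGTH
  data.frame(
    pos = rep(seq_len(n), each = 2L),
    ref = rep(ref_bases, each = 2L),
    strand = rep(c("+", "-"), times = n),
    A = 0L, C = 0L, G = 0L, T = 0L, depth = 0L,
    stringsAsFactors = FALSE
  )
}

#' Build a strand-resolved pileup from read observations
#'
#' Tallies per-base observations into per-position, per-strand counts of the
#' four nucleotides.  Observations failing either quality filter contribute
#' nothing; `N` calls are excluded from counts and depth.  Every genome
#' position is emitted (two rows, `+` then `-`), including zero-depth sites,
#' so downstream coverage diagnostics see the full coordinate space.
#'
#' @param observations data.frame with columns `position`, `base`
#'   (A/C/G/T/N), `base_quality` (PHRED), `mapping_quality`, `strand`
#'   (`"+"`/`"-"` or `"forward"`/`"reverse"`).
#' @param genome A [mito_genome()] supplying reference bases.
#' @param baseq_min,mapq_min Quality thresholds; both default to 30, the
#'   stringency under which the high-coverage counts feeding the caller were
#'   defined.
#' @return A pileup data.frame with columns
#'   `pos ref strand A C G T depth` (one row per position per strand).
#' @export
build_pileup <- function(observations, genome, baseq_min = 30, mapq_min = 30) {
  if (baseq_min < 0 || mapq_min < 0) stop("quality thresholds must be >= 0")
  pu <- empty_pileup(genome$sequence)
  if (nrow(observations)) {
    obs <- observations
    obs$strand <- normalize_strand(obs$strand)
    obs$position <- normalize_circular(obs$position)
    keep <- obs$base_quality >= baseq_min & obs$mapping_quality >= mapq_min &
      obs$base %in% BASES
    obs <- obs[keep, , drop = FALSE]
    if (nrow(obs)) {
      for (b in BASES) {
        t_f <- tabulate(obs$position[obs$base == b & obs$strand == "+"],
                        nbins = MT_GENOME_LENGTH)
        t_r <- tabulate(obs$position[obs$base == b & obs$strand == "-"],
                        nbins = MT_GENOME_LENGTH)
        pu[[b]][pu$strand == "+"] <- t_f
        pu[[b]][pu$strand == "-"] <- t_r
      }
      pu$depth <- pu$A + pu$C + pu$G + pu$T
    }
  }
  class(pu) <- c("mito_pileup", "data.frame")
  pu
}

normalize_strand <- function(strand) {
  s <- as.character(strand)
  s[s %in% c("forward", "fwd", "F")] <- "+"
  s[s %in% c("reverse", "rev", "R")] <- "-"
  if (!all(s %in% c("+", "-"))) stop("strand must be +/- or forward/reverse")
  s
}

#' Read and write the strand-resolved pileup TSV
#'
#' The on-disk dialect is a tab-separated table with the header
#' `pos ref strand A C G T depth`, one row per position per strand, written
#' bit-exactly (integers, no quoting).
#'
#' @param path File path.
#' @return `read_pileup_tsv()` returns the pileup data.frame;
#'   `write_pileup_tsv()` returns `path` invisibly.
#' @export
read_pileup_tsv <- function(path) {
  pu <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(pos = "integer", ref = "character",
                                  strand = "character", A = "integer",
                                  C = "integer", G = "integer", T = "integer",
                                  depth = "integer"))
  need <- c("pos", "ref", "strand", "A", "C", "G", "T", "depth")
  if (!identical(names(pu)[seq_along(need)], need)) {
    stop("pileup TSV must have header: ", paste(need, collapse = " "))
  }
  bad <- with(pu, depth != A + C + G + T)
  if (any(bad)) stop("pileup depth != sum of base counts at pos ",
                     paste(utils::head(pu$pos[bad]), collapse = ","))
  class(pu) <- c("mito_pileup", "data.frame")
  pu
}

#' @rdname read_pileup_tsv
#' @param pileup A pileup data.frame.
#' @export
write_pileup_tsv <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Strand-resolved pileup from a BAM file
#'
#' Thin wrapper over `Rsamtools::pileup()` applying the same base-quality and
#' mapping-quality filters as [build_pileup()] to reads aligned against the
#' mitochondrial reference.  Insertions, deletions and N calls are not
#' counted.
#'
#' @param bam Path to an indexed BAM file.
#' @param genome A [mito_genome()] (reference bases for the output).
#' @param seqname Reference sequence name in the BAM (default: first).
#' @param baseq_min,mapq_min Quality thresholds (defaults 30/30).
#' @return A pileup data.frame as from [build_pileup()].
#' @export
bam_pileup <- function(bam, genome, seqname = NULL, baseq_min = 30, mapq_min = 30) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("bam_pileup() requires the Rsamtools package")
  }
  bf <- Rsamtools::BamFile(bam)
  if (is.null(seqname)) seqname <- names(Rsamtools::scanBamHeader(bf)$targets)[1]
  pp <- Rsamtools::PileupParam(
    max_depth = .Machine$integer.max, min_base_quality = as.integer(baseq_min),
    min_mapq = as.integer(mapq_min), min_nucleotide_depth = 0L,
    distinguish_strands = TRUE, distinguish_nucleotides = TRUE,
    include_deletions = FALSE, include_insertions = FALSE
  )
  res <- Rsamtools::pileup(bf, pileupParam = pp)
  res <- res[res$seqnames == seqname & res$nucleotide %in% BASES, , drop = FALSE]
  pu <- empty_pileup(genome$sequence)
  strand <- ifelse(res$strand == "+", "+", "-")
  for (b in BASES) {
    for (s in c("+", "-")) {
      sel <- res$nucleotide == b & strand == s
      cnt <- integer(MT_GENOME_LENGTH)
      if (any(sel)) cnt[normalize_circular(res$pos[sel])] <- res$count[sel]
      pu[[b]][pu$strand == s] <- cnt
    }
  }
  pu$depth <- pu$A + pu$C + pu$G + pu$T
  class(pu) <- c("mito_pileup", "data.frame")
  pu
}

# split a pileup into aligned forward/reverse matrices (rows = positions 1..L)
pileup_matrices <- function(pileup) {
  fwd <- pileup[pileup$strand == "+", , drop = FALSE]
  rev <- pileup[pileup$strand == "-", , drop = FALSE]
  fwd <- fwd[order(fwd$pos), , drop = FALSE]
  rev <- rev[order(rev$pos), , drop = FALSE]
  if (!identical(fwd$pos, rev$pos)) stop("pileup strands cover different positions")
  list(pos = fwd$pos, ref = fwd$ref,
       fwd = as.matrix(fwd[, BASES]), rev = as.matrix(rev[, BASES]),
       depth_fwd = fwd$depth, depth_rev = rev$depth)
}
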