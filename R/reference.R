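#' Construct a mitochondrial reference genome object
#'
#' Wraps a full-length mitochondrial sequence as a circular reference.  The
#' human rCRS (NC_012920) is the expected coordinate standard: 16,569 bp,
#' 1-based positions throughout.
#'
#' @param sequence Character scalar of A/C/G/T/N, length 16,569.
#' @param name Identifier for the reference, default `"rCRS"`.
#' @return An object of class `mito_genome` with fields `sequence` (character
#'   vector of single bases), `length`, `circular` (always `TRUE`) and `name`.
#' @examples
#' g <- synthetic_genome(seed = 1)
#' g$length
#' @export
mito_genome <- function(sequence, name = "rCRS") {
  if (length(sequence) == 1L) sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  if (length(sequence) != MT_GENOME_LENGTH) {
    stop("mitochondrial reference must be exactly ", MT_GENOME_LENGTH,
         " bp, got ", length(sequence))
  }
  bad <- setdiff(unique(sequence), c(BASES, "N"))
  if (length(bad)) stop("invalid bases in reference: ", paste(bad, collapse = ", "))
  structure(
    list(sequence = sequence, length = MT_GENOME_LENGTH,
         circular = TRUE, name = name),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome>", x$name, "-", x$length, "bp, circular\n")
  invisible(x)
}

#' Read a mitochondrial reference from FASTA
#'
#' @param path Path to a FASTA file whose first record is the full
#'   mitochondrial sequence.
#' @return A [mito_genome()] object named after the FASTA header word.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no sequences in ", path)
  mito_genome(as.character(ss[[1]]), name = strsplit(names(ss)[1], "\\s+")[[1]][1])
}

#' Extract reference bases at (circular) positions
#'
#' @param genome A [mito_genome()].
#' @param positions Integer vector; values outside 1..16569 are wrapped
#'   circularly.
#' @return Character vector of single bases.
#' @export
genome_base <- function(genome, positions) {
  genome$sequence[normalize_circular(positions)]
}

# ---- gene-region annotation -------------------------------------------------

#' Load a gene-region annotation table
#'
#' The annotation is a tab-separated table with columns `name`, `start`,
#' `end`, `region_class` (one of protein/tRNA/rRNA/control), `strand` and,
#' for protein rows, the true coding span `cds_start`/`cds_end`.  Rows must
#' tile positions 1..16569 exactly once; the control region may wrap the
#' origin (`start > end`).  The packaged default carries the standard
#' NC_012920 feature boundaries with intergenic spacers assigned to the
#' upstream feature and gene overlaps owned by the upstream gene.
#'
#' @param path Path to the TSV; defaults to the packaged rCRS annotation.
#' @return A data.frame of class `region_annotation`.
#' @export
read_region_annotation <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rcrs_regions.tsv", package = "mitohet")
  ann <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "start", "end", "region_class", "strand", "cds_start", "cds_end")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  ok <- ann$region_class %in% c("protein", "tRNA", "rRNA", "control")
  if (!all(ok)) stop("unknown region_class: ", paste(unique(ann$region_class[!ok]), collapse = ", "))
  validate_partition(ann)
  class(ann) <- c("region_annotation", "data.frame")
  ann
}

region_positions <- function(start, end) {
  if (start <= end) start:end else c(start:MT_GENOME_LENGTH, 1:end)
}

validate_partition <- function(ann) {
  cov <- integer(MT_GENOME_LENGTH)
  for (i in seq_len(nrow(ann))) {
    p <- region_positions(ann$start[i], ann$end[i])
    cov[p] <- cov[p] + 1L
  }
  if (any(cov != 1L)) {
    stop("annotation is not a partition of 1..", MT_GENOME_LENGTH, ": ",
         sum(cov == 0L), " uncovered, ", sum(cov > 1L), " multiply covered")
  }
  invisible(TRUE)
}

# hypervariable segments of the control region (sub-labels, not partition rows)
HVS_SEGMENTS <- data.frame(
  name = c("HVS-I", "HVS-II", "HVS-III"),
  start = c(16024L, 73L, 438L),
  end = c(16365L, 340L, 574L),
  stringsAsFactors = FALSE
)

#' Locate the gene region containing a position
#'
#' Every rCRS position belongs to exactly one annotated region; control-region
#' positions additionally carry a hypervariable-segment sub-label (HVS-I/II/III)
#' when applicable.
#'
#' @param position 1-based rCRS coordinate (scalar).
#' @param annotation A [read_region_annotation()] table.
#' @return One-row data.frame with the region's fields plus a `subregion`
#'   column (`NA` outside the hypervariable segments).
#' @examples
#' ann <- read_region_annotation()
#' locate_gene(12390, ann)$name   # MT-ND5
#' locate_gene(310, ann)$subregion  # HVS-II
#' @export
locate_gene <- function(position, annotation) {
  if (!is.numeric(position) || length(position) != 1L || is.na(position) ||
      position < 1 || position > MT_GENOME_LENGTH || position != round(position)) {
    stop("position must be a single integer in 1..", MT_GENOME_LENGTH,
         " (got ", deparse(substitute(position)), " = ",
         paste(position, collapse = ","), ")")
  }
  position <- as.integer(position)
  hit <- which(
    ifelse(annotation$start <= annotation$end,
           position >= annotation$start & position <= annotation$end,
           position >= annotation$start | position <= annotation$end)
  )
  out <- annotation[hit[1L], , drop = FALSE]
  out$subregion <- NA_character_
  if (out$region_class == "control") {
    sub <- HVS_SEGMENTS$name[position >= HVS_SEGMENTS$start & position <= HVS_SEGMENTS$end]
    if (length(sub)) out$subregion <- sub[1L]
  }
  rownames(out) <- NULL
  out
}

#' Relative length of a gene region
#'
#' The region span (circularly, for wrapping regions) divided by the genome
#' length; over a complete disjoint annotation these fractions sum to 1.
#'
#' @param region Region name, or a one-row annotation slice.
#' @param annotation A [read_region_annotation()] table (used when `region`
#'   is a name).
#' @return Fraction of the genome in (0, 1].
#' @export
relative_gene_length <- function(region, annotation = NULL) {
  if (is.character(region)) {
    if (is.null(annotation)) annotation <- read_region_annotation()
    i <- match(region, annotation$name)
    if (is.na(i)) stop("unknown region name: ", region)
    region <- annotation[i, , drop = FALSE]
  }
  len <- ifelse(region$start <= region$end,
                region$end - region$start + 1L,
                MT_GENOME_LENGTH - region$start + 1L + region$end)
  len / MT_GENOME_LENGTH
}

# ---- variant nomenclature ---------------------------------------------------

#' Parse a variant label in m.-notation
#'
#' Understands the compact mitochondrial nomenclature used for profile tables:
#' `m.<ref><pos><obs>` for substitutions, where `<obs>` is a plain base for a
#' homoplasmic substitution or a two-base IUPAC ambiguity code (R/Y/K/S/W/M)
#' for a point heteroplasmy; `m.<pos>.<n><base>` for an insertion (e.g.
#' `m.309.1C`); and `m.<ref><pos>d` for a single-base deletion.
#'
#' @param text Label such as `"m.T5789Y"`.
#' @return A list of class `variant_label` with fields `position`, `ref_base`,
#'   `observed` (IUPAC symbol or base), `alleles` (bases encoded by
#'   `observed`), `kind` (substitution/insertion/deletion) and, for
#'   insertions, `inserted`.
#' @examples
#' v <- parse_variant_label("m.T5789Y")
#' v$alleles         # "C" "T"
#' format_variant_label(v)
#' @export
parse_variant_label <- function(text) {
  if (!is.character(text) || length(text) != 1L) stop("label must be a single string")
  x <- sub("^m\\.", "", text)
  if (grepl("^[0-9]+\\.[0-9]+[ACGT]$", x)) {
    pos <- as.integer(sub("^([0-9]+)\\..*$", "\\1", x))
    ins <- sub("^[0-9]+\\.[0-9]+([ACGT])$", "\\1", x)
    check_label_pos(pos, text)
    out <- list(position = pos, ref_base = NA_character_, observed = ins,
                alleles = ins, kind = "insertion",
                inserted = as.integer(sub("^[0-9]+\\.([0-9]+)[ACGT]$", "\\1", x)))
  } else if (grepl("^[ACGT][0-9]+d$", x)) {
    pos <- as.integer(sub("^[ACGT]([0-9]+)d$", "\\1", x))
    check_label_pos(pos, text)
    out <- list(position = pos, ref_base = substr(x, 1L, 1L),
                observed = "d", alleles = character(0), kind = "deletion",
                inserted = NA_integer_)
  } else if (grepl("^[ACGT][0-9]+[ACGTRYKSWM]$", x)) {
    ref <- substr(x, 1L, 1L)
    obs <- substr(x, nchar(x), nchar(x))
    pos <- as.integer(substr(x, 2L, nchar(x) - 1L))
    check_label_pos(pos, text)
    if (obs %in% names(IUPAC2)) {
      alleles <- IUPAC2[[obs]]
      if (!ref %in% alleles) {
        stop("malformed label '", text, "': reference ", ref,
             " is not encoded by IUPAC symbol ", obs)
      }
    } else {
      alleles <- obs
    }
    out <- list(position = pos, ref_base = ref, observed = obs,
                alleles = alleles, kind = "substitution", inserted = NA_integer_)
  } else {
    stop("malformed variant label '", text,
         "': expected m.<ref><pos><obs>, m.<pos>.<n><base> or m.<ref><pos>d")
  }
  structure(out, class = "variant_label")
}

check_label_pos <- function(pos, text) {
  if (is.na(pos) || pos < 1L || pos > MT_GENOME_LENGTH) {
    stop("variant label '", text, "' position out of range 1..", MT_GENOME_LENGTH)
  }
}

#' Format a variant label back to canonical m.-notation
#'
#' @param label A [parse_variant_label()] result.
#' @return Character scalar; round-trips with the parser.
#' @export
format_variant_label <- function(label) {
  switch(label$kind,
    substitution = paste0("m.", label$ref_base, label$position, label$observed),
    insertion = paste0("m.", label$position, ".", label$inserted, label$observed),
    deletion = paste0("m.", label$ref_base, label$position, "d"),
    stop("unknown label kind: ", label$kind)
  )
}

#' @export
print.variant_label <- function(x, ...) {
  cat("<variant_label>", format_variant_label(x), "-", x$kind, "\n")
  invisible(x)
}

# ---- coding-effect classification -------------------------------------------

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

vertebrate_mito_code <- local({
  code <- NULL
  function() {
    if (is.null(code)) code <<- Biostrings::getGeneticCode("SGC1")
    code
  }
})

translate_codon <- function(codon) {
  unname(vertebrate_mito_code()[paste(codon, collapse = "")])
}

# codon (as H-strand positions and coding-strand bases) containing `position`
codon_at <- function(genome, region, position) {
  if (region$strand == "+") {
    idx <- position - region$cds_start          # 0-based offset into the CDS
    ci <- idx %/% 3L
    pos3 <- region$cds_start + 3L * ci + 0:2
    bases <- ifelse(pos3 > region$cds_end, "A", genome_base(genome, pmin(pos3, MT_GENOME_LENGTH)))
    within <- pos3 <= region$cds_end
    list(positions = pos3, bases = bases, offset = idx %% 3L, within = within)
  } else {
    idx <- region$cds_end - position
    ci <- idx %/% 3L
    pos3 <- region$cds_end - 3L * ci - 0:2      # coding order on the light strand
    bases <- ifelse(pos3 < region$cds_start, "A",
                    unname(COMPLEMENT[genome_base(genome, pmax(pos3, 1L))]))
    list(positions = pos3, bases = bases, offset = idx %% 3L,
         within = pos3 >= region$cds_start)
  }
}

#' Classify the coding effect of a variant
#'
#' Substitutions in protein-coding regions are translated under the vertebrate
#' mitochondrial genetic code against the reference codon (incomplete
#' terminal codons are completed with A, the post-transcriptional
#' polyadenylation convention); single-base insertions or deletions in
#' protein regions are frameshifts; variants elsewhere return their region
#' class.  For light-strand genes the substituted base is complemented before
#' translation.
#'
#' @param label A [parse_variant_label()] result (or label string).
#' @param genome A [mito_genome()].
#' @param annotation A [read_region_annotation()] table.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"rRNA"`, `"tRNA"`,
#'   `"control"`, `"frameshift"`.
#' @examples
#' g <- synthetic_genome(seed = 1)
#' ann <- read_region_annotation()
#' lab <- parse_variant_label(paste0("m.", genome_base(g, 15355), 15355, "R"))
#' classify_coding_effect(lab, g, ann)
#' @export
classify_coding_effect <- function(label, genome, annotation) {
  if (is.character(label)) label <- parse_variant_label(label)
  region <- locate_gene(label$position, annotation)
  if (region$region_class != "protein") return(region$region_class)
  if (label$kind %in% c("insertion", "deletion")) return("frameshift")
  # spacer bases inside a protein-classified row are non-coding
  if (label$position < region$cds_start || label$position > region$cds_end) {
    return("control")
  }
  alt <- setdiff(label$alleles, label$ref_base)
  if (!length(alt)) return("synonymous")
  cod <- codon_at(genome, region, label$position)
  refcod <- cod$bases
  altcod <- refcod
  altbase <- alt[1L]
  if (region$strand == "-") altbase <- unname(COMPLEMENT[altbase])
  altcod[cod$offset + 1L] <- altbase
  if (translate_codon(refcod) == translate_codon(altcod)) "synonymous" else "nonsynonymous"
}
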