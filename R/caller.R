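#' Calling threshold for point heteroplasmies
#'
#' @param minor_fraction_min Minimum minor-allele fraction, required on each
#'   strand separately; default 0.01 (the 1% detection limit appropriate at
#'   ~35,000x coverage).  Must lie in (0, 0.5].
#' @return A list of class `call_threshold`.
#' @export
call_threshold <- function(minor_fraction_min = 0.01) {
  if (!is.numeric(minor_fraction_min) || minor_fraction_min <= 0 ||
      minor_fraction_min > 0.5) {
    stop("minor_fraction_min must be in (0, 0.5]")
  }
  structure(list(minor_fraction_min = minor_fraction_min, per_strand = TRUE),
            class = "call_threshold")
}

empty_calls <- function() {
  data.frame(
    sample = character(0), pos = integer(0), ref = character(0),
    major = character(0), minor = character(0),
    level_pct = numeric(0), minor_pct = numeric(0),
    minor_fwd_pct = numeric(0), minor_rev_pct = numeric(0),
    depth_fwd = integer(0), depth_rev = integer(0),
    filters = character(0), stringsAsFactors = FALSE
  )
}

#' Call a single site from strand-resolved counts
#'
#' A point heteroplasmy is emitted only when one and the same minor allele
#' reaches the detection threshold on the forward strand AND on the reverse
#' strand ("dual-strand confirmation").  Reported fractions use pooled
#' counts from both strands.
#'
#' @param fwd,rev Named counts (`A`,`C`,`G`,`T`) for the forward and reverse
#'   strand.
#' @param ref Reference base at the site.
#' @param pos 1-based position (carried into the call).
#' @param threshold A [call_threshold()] or a bare fraction.
#' @return A list with `status` (`"call"`, `"no_call"` or
#'   `"insufficient_coverage"`) and, for calls, `call`: a one-row data.frame
#'   with columns `pos ref major minor level_pct minor_pct minor_fwd_pct
#'   minor_rev_pct depth_fwd depth_rev`.
#' @examples
#' call_site(c(A = 34650, C = 0, G = 350, T = 0),
#'           c(A = 34650, C = 0, G = 350, T = 0), ref = "A", pos = 100)
#' @export
call_site <- function(fwd, rev, ref, pos = NA_integer_, threshold = call_threshold()) {
  if (is.numeric(threshold)) threshold <- call_threshold(threshold)
  fwd <- fwd[BASES]; rev <- rev[BASES]
  fwd[is.na(fwd)] <- 0; rev[is.na(rev)] <- 0
  df <- sum(fwd); dr <- sum(rev)
  if (df == 0 || dr == 0) {
    return(list(status = "insufficient_coverage", call = NULL,
                reason = "zero depth on at least one strand"))
  }
  pooled <- fwd + rev
  major <- BASES[which.max(pooled)]
  t <- threshold$minor_fraction_min
  cand <- setdiff(BASES[pooled > 0], major)
  if (!length(cand)) return(list(status = "no_call", call = NULL,
                                 reason = "monomorphic site"))
  minmf <- pmin(fwd[cand] / df, rev[cand] / dr)
  ok <- minmf >= t
  if (!any(ok)) return(list(status = "no_call", call = NULL,
                            reason = "minor component below threshold on at least one strand"))
  cand <- cand[ok]; minmf <- minmf[ok]
  ord <- order(-pooled[cand], -minmf, cand)
  minor <- cand[ord[1L]]
  dp <- df + dr
  nonref <- setdiff(BASES, ref)
  level <- 100 * max(pooled[nonref]) / dp
  call <- data.frame(
    pos = as.integer(pos), ref = ref, major = major, minor = minor,
    level_pct = level,
    minor_pct = 100 * pooled[[minor]] / dp,
    minor_fwd_pct = 100 * fwd[[minor]] / df,
    minor_rev_pct = 100 * rev[[minor]] / dr,
    depth_fwd = as.integer(df), depth_rev = as.integer(dr),
    stringsAsFactors = FALSE
  )
  rownames(call) <- NULL
  list(status = "call", call = call, reason = NA_character_)
}

#' Call point heteroplasmies across a pileup
#'
#' Applies [call_site()] to every position of a strand-resolved pileup.
#' Positions with zero depth on either strand are skipped (they cannot be
#' dual-strand confirmed); use the pileup itself for coverage QC.
#'
#' @param pileup A pileup data.frame (see [build_pileup()]).
#' @param threshold A [call_threshold()] or bare fraction (default 0.01).
#' @param sample Sample identifier attached to each call.
#' @return A calls data.frame with columns `sample pos ref major minor
#'   level_pct minor_pct minor_fwd_pct minor_rev_pct depth_fwd depth_rev
#'   filters` (empty `filters` string = PASS).
#' @export
call_heteroplasmies <- function(pileup, threshold = call_threshold(),
                                sample = NA_character_) {
  if (is.numeric(threshold)) threshold <- call_threshold(threshold)
  m <- pileup_matrices(pileup)
  df <- m$depth_fwd; dr <- m$depth_rev
  t <- threshold$minor_fraction_min
  pooled <- m$fwd + m$rev
  usable <- df > 0 & dr > 0
  # a site can only yield a call if some allele other than the pooled major
  # reaches t on both strands; cheap prescreen keeps the scan linear
  maj_idx <- max.col(pooled, ties.method = "first")
  n <- length(m$pos)
  pooled_minor <- pooled
  pooled_minor[cbind(seq_len(n), maj_idx)] <- -1L
  ffrac <- m$fwd / pmax(df, 1L)
  rfrac <- m$rev / pmax(dr, 1L)
  minmf <- pmin(ffrac, rfrac)
  minmf[cbind(seq_len(n), maj_idx)] <- -1
  hit <- which(usable & apply(minmf >= t & pooled_minor > 0, 1L, any))
  if (!length(hit)) return(empty_calls())
  rows <- lapply(hit, function(i) {
    res <- call_site(m$fwd[i, ], m$rev[i, ], ref = m$ref[i], pos = m$pos[i],
                     threshold = threshold)
    res$call
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_calls())
  calls <- do.call(rbind, rows)
  calls <- cbind(sample = sample, calls, filters = "", stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  calls
}

#' Level of the mutated (non-reference) nucleotide
#'
#' The table convention for heteroplasmy levels: the pooled percentage of the
#' most frequent allele other than the rCRS reference.  Unlike the minor
#' component this may exceed 50%.
#'
#' @param fwd,rev Named base counts per strand (either may be all zero, but
#'   not both).
#' @param ref Reference base.
#' @return Percentage in \[0, 100\].
#' @export
variant_level <- function(fwd, rev, ref) {
  fwd <- fwd[BASES]; rev <- rev[BASES]
  fwd[is.na(fwd)] <- 0; rev[is.na(rev)] <- 0
  pooled <- fwd + rev
  dp <- sum(pooled)
  if (dp == 0) stop("zero pooled depth: level undefined")
  100 * max(pooled[setdiff(BASES, ref)]) / dp
}

#' Classify a heteroplasmy as low- or high-level
#'
#' Low-level means a minor component below 10%; the boundary at which Sanger
#' electropherograms stop resolving secondary peaks reliably.
#'
#' @param minor_pct Minor-component percentage(s) (0, 50\].
#' @param boundary Percentage boundary, default 10.
#' @return Character vector, `"low"` or `"high"`.
#' @export
classify_level <- function(minor_pct, boundary = 10) {
  ifelse(minor_pct < boundary, "low", "high")
}

#' Read and write the calls TSV
#'
#' Tab-separated, one row per call, with the column set produced by
#' [call_heteroplasmies()].  Percentages are written at full precision;
#' round only for display.
#'
#' @param path File path.
#' @return `read_calls_tsv()` returns the calls data.frame.
#' @export
read_calls_tsv <- function(path) {
  calls <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(sample = "character", filters = "character"))
  calls$filters[is.na(calls$filters)] <- ""
  calls
}

#' @rdname read_calls_tsv
#' @param calls A calls data.frame.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
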