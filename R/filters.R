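#' Artifact-filter configuration
#'
#' Defaults encode the envelope of the systematic-artifact cases seen in
#' high-coverage mitochondrial sequencing: phantom positions recur as
#' low-level (<5%) calls across many samples and share a local sequence
#' context (a 9-mer); they show a one-strand coverage drop while the other
#' strand stays flat; satellite positions immediately next to a phantom
#' anchor track its level across samples; long-range PCR primer annealing
#' zones and the circular origin produce mapping artifacts.
#'
#' @param min_samples Minimum number of samples with a low-level call at a
#'   position before it counts as recurrent (default 8).
#' @param max_level_pct Level bound (minor-component %) under which a call at
#'   a flagged position is considered a potential artifact (default 5).
#' @param context_window Width of the flanking sequence context compared
#'   between flagged positions; odd, default 9.
#' @param drop_ratio_max Flag a strand whose depth at the site is at most this
#'   fraction of the flanking median (default 0.8).
#' @param stable_min The other strand must retain at least this fraction of
#'   its flanking median (default 0.9).
#' @param flank Number of flanking positions per side for the coverage-drop
#'   median (default 5; at least 3).
#' @param cor_min Minimum Pearson correlation between anchor and neighbor
#'   levels before the neighbor is flagged (default 0.9).
#' @param neighbor_dist Maximum distance (bp) from an anchor for a position to
#'   be tested as a correlated neighbor (default 3).
#' @param edge_margin Calls within this many bases of the origin (position
#'   1/16569) get a circular-edge flag (default 5).
#' @param zones data.frame of exclusion zones (`start`, `end`, `reason`);
#'   default the long-range PCR primer annealing zone 2523-2667.
#' @param filters Which filter stages to run, in order.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_samples = 8L, max_level_pct = 5, context_window = 9L,
                          drop_ratio_max = 0.8, stable_min = 0.9, flank = 5L,
                          cor_min = 0.9, neighbor_dist = 3L, edge_margin = 5L,
                          zones = data.frame(start = 2523L, end = 2667L,
                                             reason = "long-range PCR primer annealing",
                                             stringsAsFactors = FALSE),
                          filters = c("phantom_context", "strand_drop",
                                      "correlated_neighbor", "primer_zone",
                                      "circular_edge")) {
  known <- c("phantom_context", "strand_drop", "correlated_neighbor",
             "primer_zone", "circular_edge")
  bad <- setdiff(filters, known)
  if (length(bad)) stop("unknown filter name(s): ", paste(bad, collapse = ", "))
  if (context_window %% 2L == 0L) stop("context_window must be odd")
  if (flank < 3L) stop("flank must be >= 3")
  structure(list(min_samples = min_samples, max_level_pct = max_level_pct,
                 context_window = context_window, drop_ratio_max = drop_ratio_max,
                 stable_min = stable_min, flank = flank, cor_min = cor_min,
                 neighbor_dist = neighbor_dist, edge_margin = edge_margin,
                 zones = zones, filters = filters),
            class = "filter_config")
}

#' Sequence context around a position
#'
#' The flanking window rendered with the focal base bracketed, e.g.
#' `GG[T]ATGCAC` for a 9-mer; windows crossing the origin wrap circularly.
#'
#' @param genome A [mito_genome()].
#' @param position 1-based position (vectorized).
#' @param window Odd window width.
#' @return Character vector of context strings.
#' @export
sequence_context <- function(genome, position, window = 9L) {
  half <- (window - 1L) %/% 2L
  vapply(position, function(p) {
    idx <- normalize_circular((p - half):(p + half))
    b <- genome$sequence[idx]
    paste0(paste(b[seq_len(half)], collapse = ""), "[", b[half + 1L], "]",
           paste(b[(half + 2L):window], collapse = ""))
  }, character(1))
}

#' Flag recurrent low-level positions (phantom-mutation candidates)
#'
#' Positions called at low level (minor component at most `max_level_pct`) in
#' at least `min_samples` distinct samples are flagged as potential phantom
#' mutations; flagged positions sharing an identical flanking sequence
#' context are grouped together, the signature of a context-driven
#' systematic error.
#'
#' @param calls Cohort-wide calls data.frame (must span >= 2 samples).
#' @param genome A [mito_genome()] for context extraction, or `NULL` (no
#'   context grouping).
#' @param min_samples,max_level_pct,context_window See [filter_config()].
#' @return data.frame with columns `position flag_kind recurrence
#'   mean_level_pct context context_group affected_samples`.
#' @export
flag_recurrent_context <- function(calls, genome = NULL, min_samples = 8L,
                                   max_level_pct = 5, context_window = 9L) {
  if (length(unique(calls$sample)) < 2L) {
    stop("phantom flagging is cohort-level: calls must span >= 2 samples")
  }
  low <- calls[calls$minor_pct <= max_level_pct, , drop = FALSE]
  if (!nrow(low)) return(empty_flags())
  rec <- tapply(low$sample, low$pos, function(s) length(unique(s)))
  flagged <- as.integer(names(rec)[rec >= min_samples])
  if (!length(flagged)) return(empty_flags())
  out <- data.frame(
    position = flagged, flag_kind = "phantom_context",
    recurrence = as.integer(rec[as.character(flagged)]),
    mean_level_pct = vapply(flagged, function(p)
      mean(low$minor_pct[low$pos == p]), numeric(1)),
    context = NA_character_, context_group = NA_integer_,
    affected_samples = vapply(flagged, function(p)
      paste(sort(unique(low$sample[low$pos == p])), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(genome)) {
    out$context <- sequence_context(genome, out$position, context_window)
    out$context_group <- as.integer(factor(out$context, levels = unique(out$context)))
  }
  rownames(out) <- NULL
  out
}

empty_flags <- function() {
  data.frame(position = integer(0), flag_kind = character(0),
             recurrence = integer(0), mean_level_pct = numeric(0),
             context = character(0), context_group = integer(0),
             affected_samples = character(0), stringsAsFactors = FALSE)
}

#' Detect a one-strand coverage drop at a position
#'
#' Compares each strand's depth at the site against the median depth of the
#' flanking window.  A position is flagged when one strand drops to at most
#' `drop_ratio_max` of its flanking median while the other strand stays at or
#' above `stable_min` of its own -- the asymmetric signature of a mapping or
#' chemistry artifact rather than a true coverage dip.
#'
#' @param pileup A strand-resolved pileup data.frame.
#' @param position Site to test.
#' @param flank Flanking positions per side (>= 3).
#' @param drop_ratio_max,stable_min See [filter_config()].
#' @return A one-row data.frame (`position flag_kind ratio_fwd ratio_rev
#'   truncated`) when flagged, otherwise `NULL`.
#' @export
strand_coverage_drop <- function(pileup, position, flank = 5L,
                                 drop_ratio_max = 0.8, stable_min = 0.9) {
  m <- pileup_matrices(pileup)
  i <- match(position, m$pos)
  if (is.na(i)) stop("position ", position, " not present in pileup")
  offs <- c(-(flank:1), 1:flank)
  widx <- match(normalize_circular(position + offs), m$pos)
  truncated <- anyNA(widx)
  widx <- widx[!is.na(widx)]
  if (length(widx) < 6L) stop("flanking window must retain >= 3 positions per side")
  med_f <- median(m$depth_fwd[widx])
  med_r <- median(m$depth_rev[widx])
  if (med_f == 0 || med_r == 0) return(NULL)
  rf <- m$depth_fwd[i] / med_f
  rr <- m$depth_rev[i] / med_r
  hit <- (rf <= drop_ratio_max && rr >= stable_min) ||
         (rr <= drop_ratio_max && rf >= stable_min)
  if (!hit) return(NULL)
  data.frame(position = as.integer(position), flag_kind = "strand_drop",
             ratio_fwd = rf, ratio_rev = rr, truncated = truncated,
             stringsAsFactors = FALSE)
}

#' Flag neighbor positions whose levels ride on an anchor position
#'
#' Tests, across samples, whether the call levels at candidate neighbor
#' positions are strongly correlated with the levels at an anchor position
#' and occur only in anchor-positive samples -- the pattern of satellite
#' artifacts next to a phantom hotspot.
#'
#' @param calls Calls data.frame with `sample`, `pos` and `level_pct`.
#' @param anchor Anchor position.
#' @param neighbors Candidate neighbor positions.
#' @param cor_min Minimum Pearson correlation (default 0.9).
#' @return data.frame of flags (`position flag_kind anchor correlation n`);
#'   neighbors with fewer than 3 paired observations are reported with
#'   `flag_kind = "indeterminate"` and are not treated as flagged.
#' @export
correlated_neighbors <- function(calls, anchor, neighbors, cor_min = 0.9) {
  a <- calls[calls$pos == anchor, c("sample", "level_pct")]
  if (nrow(a) < 3L) {
    return(data.frame(position = integer(0), flag_kind = character(0),
                      anchor = integer(0), correlation = numeric(0),
                      n = integer(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(setdiff(neighbors, anchor), function(p) {
    nb <- calls[calls$pos == p, c("sample", "level_pct")]
    if (!nrow(nb)) return(NULL)
    if (!all(nb$sample %in% a$sample)) return(NULL)  # occurs without the anchor
    paired <- merge(a, nb, by = "sample", suffixes = c("_anchor", "_nb"))
    if (nrow(paired) < 3L) {
      return(data.frame(position = as.integer(p), flag_kind = "indeterminate",
                        anchor = as.integer(anchor), correlation = NA_real_,
                        n = nrow(paired), stringsAsFactors = FALSE))
    }
    r <- suppressWarnings(cor(paired$level_pct_anchor, paired$level_pct_nb))
    if (!is.na(r) && r >= cor_min) {
      data.frame(position = as.integer(p), flag_kind = "correlated_neighbor",
                 anchor = as.integer(anchor), correlation = r,
                 n = nrow(paired), stringsAsFactors = FALSE)
    } else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(position = integer(0), flag_kind = character(0),
                                      anchor = integer(0), correlation = numeric(0),
                                      n = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag calls inside exclusion zones or at the circular edge
#'
#' @param calls Calls data.frame.
#' @param zones data.frame with `start`, `end`, `reason` (1-based inclusive,
#'   normalized so `start <= end` unless the zone wraps the origin).
#' @param edge_margin Calls within this many bases of position 1/16569 get a
#'   `circular_edge` flag.
#' @return `calls` with a `zone_flag` column (`""`, `"primer_zone"` or
#'   `"circular_edge"`, semicolon-joined if both).
#' @export
zone_exclusion <- function(calls, zones = NULL, edge_margin = 5L) {
  flag <- character(nrow(calls))
  if (!is.null(zones) && nrow(zones)) {
    inzone <- rep(FALSE, nrow(calls))
    for (i in seq_len(nrow(zones))) {
      s <- zones$start[i]; e <- zones$end[i]
      inzone <- inzone | if (s <= e) calls$pos >= s & calls$pos <= e
                         else calls$pos >= s | calls$pos <= e
    }
    flag[inzone] <- "primer_zone"
  }
  edge <- calls$pos <= edge_margin | calls$pos > MT_GENOME_LENGTH - edge_margin
  flag[edge] <- ifelse(nzchar(flag[edge]), paste0(flag[edge], ";circular_edge"),
                       "circular_edge")
  calls$zone_flag <- flag
  calls
}

#' Run the artifact filters over a cohort call set
#'
#' Filters run in a fixed order: recurrent-context flagging, strand coverage
#' drop, correlated neighbors, then zone/edge exclusion.  Filtering is
#' non-destructive -- every input call ends up in exactly one of the `pass` or
#' `excluded` sets, and excluded calls keep all their flags in the `filters`
#' column.  A high-level call at a phantom- or strand-drop-flagged position
#' (minor component above `max_level_pct`) is retained: recurrence evidence
#' only indicts the low-level calls.
#'
#' @param calls Cohort calls data.frame.
#' @param pileups Named list (by sample) of pileup data.frames, used for the
#'   strand-drop diagnostic; `NULL` skips that stage.
#' @param config A [filter_config()].
#' @param genome A [mito_genome()] for sequence-context grouping (optional).
#' @return A list with `pass`, `excluded` (both calls data.frames), `flags`
#'   (position-level flag table) and `log` (per-flag-kind counts).
#' @export
apply_filters <- function(calls, pileups = NULL, config = filter_config(),
                          genome = NULL) {
  if (!inherits(config, "filter_config")) stop("config must be a filter_config()")
  if (!nrow(calls)) {
    return(list(pass = calls, excluded = calls[0, , drop = FALSE],
                flags = empty_flags(),
                log = data.frame(flag_kind = character(0), n_flagged = integer(0),
                                 n_excluded = integer(0))))
  }
  calls$filters <- ""
  exclude <- rep(FALSE, nrow(calls))
  add_flag <- function(idx, kind) {
    has <- nzchar(calls$filters[idx])
    calls$filters[idx] <<- ifelse(has, paste0(calls$filters[idx], ";", kind), kind)
  }
  flags <- empty_flags()
  phantom_pos <- integer(0)

  if ("phantom_context" %in% config$filters && length(unique(calls$sample)) >= 2L) {
    flags <- flag_recurrent_context(calls, genome, config$min_samples,
                                    config$max_level_pct, config$context_window)
    phantom_pos <- flags$position
    idx <- which(calls$pos %in% phantom_pos & calls$minor_pct <= config$max_level_pct)
    add_flag(idx, "phantom_context")
    exclude[idx] <- TRUE
  }

  if ("strand_drop" %in% config$filters && !is.null(pileups)) {
    test_pos <- sort(unique(calls$pos))
    for (s in names(pileups)) {
      pos_s <- intersect(test_pos, calls$pos[calls$sample == s])
      for (p in pos_s) {
        fl <- strand_coverage_drop(pileups[[s]], p, config$flank,
                                   config$drop_ratio_max, config$stable_min)
        if (!is.null(fl)) {
          idx <- which(calls$sample == s & calls$pos == p &
                         calls$minor_pct <= config$max_level_pct)
          add_flag(idx, "strand_drop")
          exclude[idx] <- TRUE
        }
      }
    }
  }

  if ("correlated_neighbor" %in% config$filters && length(phantom_pos)) {
    anchors <- unique(c(phantom_pos))
    for (a in anchors) {
      nb <- setdiff(unique(calls$pos[abs(calls$pos - a) <= config$neighbor_dist]), a)
      if (!length(nb)) next
      fl <- correlated_neighbors(calls, a, nb, config$cor_min)
      hitpos <- fl$position[fl$flag_kind == "correlated_neighbor"]
      idx <- which(calls$pos %in% hitpos)
      add_flag(idx, "correlated_neighbor")
      exclude[idx] <- TRUE
    }
  }

  zoned <- zone_exclusion(calls, if ("primer_zone" %in% config$filters)
    config$zones else NULL,
    if ("circular_edge" %in% config$filters) config$edge_margin else 0L)
  idx <- which(nzchar(zoned$zone_flag))
  for (i in idx) add_flag(i, zoned$zone_flag[i])
  exclude[idx] <- TRUE

  log <- flag_log(calls$filters, exclude)
  list(pass = calls[!exclude, , drop = FALSE],
       excluded = calls[exclude, , drop = FALSE],
       flags = flags, log = log)
}

flag_log <- function(filters, exclude) {
  kinds <- unlist(strsplit(filters[nzchar(filters)], ";"))
  if (!length(kinds)) {
    return(data.frame(flag_kind = character(0), n_flagged = integer(0),
                      n_excluded = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(kinds)
  exc <- vapply(names(tab), function(k)
    sum(exclude & grepl(k, filters, fixed = TRUE)), integer(1))
  data.frame(flag_kind = names(tab), n_flagged = as.integer(tab),
             n_excluded = as.integer(exc), row.names = NULL,
             stringsAsFactors = FALSE)
}
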