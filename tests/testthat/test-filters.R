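# build a minimal cohort call table by hand
mk_call <- function(sample, pos, ref = "T", minor_pct = 1.5, level_pct = minor_pct,
                    major = NULL, minor = NULL) {
  data.frame(sample = sample, pos = as.integer(pos), ref = ref,
             major = major %||% ref, minor = minor %||% "G",
             level_pct = level_pct, minor_pct = minor_pct,
             minor_fwd_pct = minor_pct, minor_rev_pct = minor_pct,
             depth_fwd = 17500L, depth_rev = 17500L, filters = "",
             stringsAsFactors = FALSE)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("recurrent low-level positions are flagged and grouped by context", {
  g <- test_genome()
  samples <- sprintf("S%02d", 1:20)
  calls <- do.call(rbind, c(
    lapply(samples[1:12], function(s) mk_call(s, 414, minor_pct = 1.5)),
    lapply(samples[1:11], function(s) mk_call(s, 72, minor_pct = 1.2)),
    list(mk_call("S01", 9000, minor_pct = 2))  # single-sample: not flagged
  ))
  flags <- flag_recurrent_context(calls, g, min_samples = 8, max_level_pct = 5)
  expect_setequal(flags$position, c(72L, 414L))
  expect_equal(flags$recurrence[flags$position == 414], 12L)
  expect_equal(flags$recurrence[flags$position == 72], 11L)
  expect_equal(flags$mean_level_pct[flags$position == 414], 1.5)
  expect_false(9000 %in% flags$position)
  # context strings bracket the focal base
  expect_match(flags$context[1], "^[ACGT]{4}\\[[ACGT]\\][ACGT]{4}$")
})

test_that("identical flanking contexts group flagged positions together", {
  # plant the same 9-mer at two loci of a copy of the genome
  g <- test_genome()
  motif <- strsplit("GGTATGCAC", "")[[1]]
  seq2 <- g$sequence
  seq2[(72 - 4):(72 + 4)] <- motif
  seq2[(414 - 4):(414 + 4)] <- motif
  g2 <- mito_genome(seq2, name = "planted")
  calls <- do.call(rbind, c(
    lapply(sprintf("S%02d", 1:10), function(s) mk_call(s, 72)),
    lapply(sprintf("S%02d", 1:10), function(s) mk_call(s, 414))
  ))
  flags <- flag_recurrent_context(calls, g2, min_samples = 8)
  expect_equal(flags$context[1], "GGTA[T]GCAC")
  # brute-force pairwise comparison of context strings
  same <- outer(flags$context, flags$context, `==`)
  expect_true(all(same))
  expect_equal(length(unique(flags$context_group)), 1L)
})

test_that("one-strand coverage drop is flagged; symmetric coverage is not", {
  g <- test_genome()
  pu <- build_pileup(data.frame(position = integer(0), base = character(0),
                                base_quality = integer(0),
                                mapping_quality = integer(0),
                                strand = character(0)), g)
  sel_f <- pu$strand == "+" & pu$pos %in% 95:105
  sel_r <- pu$strand == "-" & pu$pos %in% 95:105
  pu$A[sel_f] <- 35000L; pu$A[sel_r] <- 35000L
  pu$A[pu$strand == "+" & pu$pos == 100] <- 18200L  # ratio 0.52
  pu$depth <- pu$A
  fl <- strand_coverage_drop(pu, 100, flank = 5)
  expect_false(is.null(fl))
  expect_equal(fl$ratio_fwd, 18200 / 35000)
  expect_equal(fl$ratio_rev, 1)
  # flat coverage both strands: no flag
  pu$A[pu$strand == "+" & pu$pos == 100] <- 35000L
  pu$depth <- pu$A
  expect_null(strand_coverage_drop(pu, 100, flank = 5))
})

test_that("coverage-drop decisions equal direct ratio recomputation", {
  g <- test_genome()
  set.seed(55)
  for (rep in 1:10) {
    pu <- empty <- build_pileup(data.frame(position = integer(0), base = character(0),
                                           base_quality = integer(0),
                                           mapping_quality = integer(0),
                                           strand = character(0)), g)
    window <- 200:210
    depths_f <- rpois(length(window), 30000)
    depths_r <- rpois(length(window), 30000)
    # randomly depress one or both strands at the centre
    depths_f[6] <- round(depths_f[6] * runif(1, 0.3, 1.1))
    depths_r[6] <- round(depths_r[6] * runif(1, 0.3, 1.1))
    pu$A[pu$strand == "+" & pu$pos %in% window] <- depths_f
    pu$A[pu$strand == "-" & pu$pos %in% window] <- depths_r
    pu$depth <- pu$A
    got <- !is.null(strand_coverage_drop(pu, 205, flank = 5,
                                         drop_ratio_max = 0.8, stable_min = 0.9))
    rf <- depths_f[6] / median(depths_f[-6])
    rr <- depths_r[6] / median(depths_r[-6])
    want <- (rf <= 0.8 && rr >= 0.9) || (rr <= 0.8 && rf >= 0.9)
    expect_equal(got, want, label = sprintf("rep %d rf=%.2f rr=%.2f", rep, rf, rr))
  }
})

test_that("neighbors correlated with an anchor are flagged, others are not", {
  anchors <- c(60.18, 16.62, 27.41)
  calls <- rbind(
    mk_call(c("B04", "B08", "B20"), 72, minor_pct = 4,
            level_pct = anchors)[, ],
    mk_call(c("B04", "B08", "B20"), 73, level_pct = anchors * 0.8),
    mk_call(c("B04", "B08"), 74, level_pct = anchors[1:2] * 0.5),
    mk_call("OTHER", 75, level_pct = 3)  # anchor-negative sample only
  )
  fl <- correlated_neighbors(calls, anchor = 72, neighbors = c(73, 74, 75))
  expect_true(73 %in% fl$position[fl$flag_kind == "correlated_neighbor"])
  expect_false(75 %in% fl$position)
  # 74 has only 2 paired observations: indeterminate, not flagged
  expect_equal(fl$flag_kind[fl$position == 74], "indeterminate")
  # correlation equals the closed-form product-moment value
  r73 <- fl$correlation[fl$position == 73]
  expect_equal(r73, oracle_pearson(anchors, anchors * 0.8))
})

test_that("zone and circular-edge flags hit the documented positions", {
  calls <- rbind(mk_call("S1", 2600), mk_call("S1", 3), mk_call("S1", 5000),
                 mk_call("S1", 16567))
  z <- zone_exclusion(calls, zones = data.frame(start = 2523, end = 2667,
                                                reason = "primer"),
                      edge_margin = 5)
  expect_equal(z$zone_flag[z$pos == 2600], "primer_zone")
  expect_equal(z$zone_flag[z$pos == 3], "circular_edge")
  expect_equal(z$zone_flag[z$pos == 16567], "circular_edge")
  expect_equal(z$zone_flag[z$pos == 5000], "")
})

test_that("apply_filters excludes low-level recurrent calls but keeps high-level ones", {
  g <- test_genome()
  # 8 low-level and 3 high-level calls at one recurrent position
  calls <- do.call(rbind, c(
    lapply(sprintf("L%02d", 1:8), function(s) mk_call(s, 72, minor_pct = 1.5)),
    lapply(c("H1", "H2", "H3"), function(s)
      mk_call(s, 72, minor_pct = 30, level_pct = 30)),
    lapply(sprintf("L%02d", 1:8), function(s) mk_call(s, 9500, minor_pct = 20))
  ))
  res <- apply_filters(calls, config = filter_config(), genome = g)
  excl72 <- res$excluded[res$excluded$pos == 72, ]
  expect_equal(nrow(excl72), 8L)
  expect_true(all(excl72$minor_pct <= 5))
  expect_equal(sum(res$pass$pos == 72), 3L)
  # high-level calls at a non-flagged position untouched
  expect_equal(sum(res$pass$pos == 9500), 8L)
  # partition: pass and excluded split the input exactly
  expect_equal(nrow(res$pass) + nrow(res$excluded), nrow(calls))
  key <- function(d) paste(d$sample, d$pos)
  expect_length(intersect(key(res$pass), key(res$excluded)), 0L)
  # audit counts equal an independent tally
  expect_equal(res$log$n_excluded[res$log$flag_kind == "phantom_context"], 8L)
})

test_that("filtering is idempotent and empty input yields empty output", {
  g <- test_genome()
  calls <- do.call(rbind, c(
    lapply(sprintf("S%02d", 1:10), function(s) mk_call(s, 414, minor_pct = 2)),
    list(mk_call("S01", 2600), mk_call("S02", 8000, minor_pct = 25))
  ))
  res1 <- apply_filters(calls, config = filter_config(), genome = g)
  res2 <- apply_filters(res1$pass, config = filter_config(), genome = g)
  expect_equal(as.data.frame(res2$pass), as.data.frame(res1$pass))
  expect_equal(nrow(res2$excluded), 0L)
  empty <- apply_filters(calls[0, ], config = filter_config(), genome = g)
  expect_equal(nrow(empty$pass), 0L)
  expect_equal(nrow(empty$excluded), 0L)
  expect_equal(nrow(empty$log), 0L)
})

test_that("unknown filter names are a configuration error", {
  expect_error(filter_config(filters = c("phantom_context", "nope")),
               "unknown filter")
})
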