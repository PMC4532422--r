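rec_df <- function(...) {
  # rows of (tissue_class, level_pct, mark)
  rows <- list(...)
  data.frame(
    tissue_class = vapply(rows, `[[`, character(1), 1),
    level_pct = suppressWarnings(as.numeric(vapply(rows, `[[`, character(1), 2))),
    mark = vapply(rows, function(r) if (r[[2]] %in% c("n.a.", "n.d.")) r[[2]] else "",
                  character(1)),
    stringsAsFactors = FALSE
  )
}

test_that("variant classification covers the four statuses", {
  # heteroplasmic in benign, blood and tumor: germline heteroplasmy
  expect_equal(classify_variant(rec_df(
    c("benign_margin", "16.91"), c("blood", "45.62"), c("primary_tumor", "8.21"))),
    "germline_heteroplasmy")
  # absent from benign, present in tumor and recurrence: shared somatic
  expect_equal(classify_variant(rec_df(
    c("benign_margin", "n.d."), c("blood", "n.d."),
    c("primary_tumor", "15.54"), c("recurrence", "71.6"))),
    "somatic_shared")
  # homoplasmic everywhere sampled
  expect_equal(classify_variant(rec_df(
    c("benign_margin", "100"), c("primary_tumor", "100"))),
    "germline_homoplasmic")
  # detected in one tissue only
  expect_equal(classify_variant(rec_df(
    c("benign_margin", "n.d."), c("primary_tumor", "12"), c("recurrence", "n.d."))),
    "somatic_private")
  # nothing available -> classification error
  expect_error(classify_variant(rec_df(
    c("benign_margin", "n.a."), c("primary_tumor", "n.a."))), "no tissue available")
  expect_error(classify_variant(rec_df(c("liver", "5"))), "unknown tissue class")
})

test_that("every record of the published tables receives exactly one status", {
  tb <- study_shared_mutations()
  cl <- classify_cohort(tb)
  expect_equal(nrow(cl), length(unique(paste(tb$patient_id, tb$variant))))
  expect_true(all(cl$status %in% c("germline_homoplasmic", "germline_heteroplasmy",
                                   "somatic_shared", "somatic_private")))
  # the somatic table rows with >= 2 cancer tissues classify as shared somatic
  expect_equal(cl$status[cl$patient_id == "MKG05" & cl$variant == "m.A5894R"],
               "somatic_shared")
  expect_equal(cl$status[cl$patient_id == "MKG04" & cl$variant == "m.T5789Y"],
               "germline_heteroplasmy")
})

test_that("shared-somatic means per tissue class match the published levels", {
  som <- study_shared_mutations()
  som <- som[som$table == "somatic", ]
  ss <- shared_somatic_summary(som)
  m <- setNames(ss$means$mean_level_pct, ss$means$tissue_class)
  expect_equal(round(m[["primary_tumor"]], 1), 17.9)
  expect_equal(round(m[["recurrence"]], 1), 39.6)
  expect_equal(round(m[["lymph_node_metastasis"]], 1), 49.8)
  expect_equal(ss$means$n[ss$means$tissue_class == "primary_tumor"], 12L)
  # single record: mean equals the level
  one <- rec_df(c("primary_tumor", "33.3"))
  one$patient_id <- "P"; one$variant <- "v"
  expect_equal(shared_somatic_summary(one)$means$mean_level_pct, 33.3)
  # means are permutation-invariant
  perm <- som[sample(nrow(som)), ]
  ss2 <- shared_somatic_summary(perm)
  expect_equal(ss2$means[order(ss2$means$tissue_class), ],
               ss$means[order(ss$means$tissue_class), ], ignore_attr = TRUE)
})

test_that("high-level fraction counts strictly-above-boundary records", {
  som <- study_shared_mutations()
  pt <- som$level_pct[som$table == "somatic" & som$tissue_class == "primary_tumor" &
                        som$mark == ""]
  expect_equal(high_level_fraction(pt, 10), 75)
  expect_equal(high_level_fraction(c(1, 2, 3), 10), 0)
  set.seed(4)
  x <- runif(50, 0, 100)
  expect_equal(high_level_fraction(x, 10), 100 * sum(x > 10) / 50)
})

test_that("level-distribution test reproduces uncorrected chi-square", {
  benign <- c(rep(5, 65), rep(20, 17))
  tumor <- c(rep(5, 62), rep(20, 35))
  res <- level_distribution_test(benign, tumor, boundary = 10)
  expect_equal(unname(res$counts["benign", ]), c(65, 17))
  expect_equal(unname(res$counts["tumor", ]), c(62, 35))
  expect_equal(round(res$proportion_low[["benign"]], 1), 79.3)
  expect_equal(round(res$proportion_low[["tumor"]], 1), 63.9)
  oracle <- oracle_chisq_2x2(65, 17, 62, 35)
  expect_equal(res$statistic, oracle$stat)
  expect_equal(res$p_value, oracle$p)
  # counts conserved and bins sum to group sizes
  expect_equal(rowSums(res$counts), c(benign = 82, tumor = 97))
  expect_equal(sum(res$bins$benign), 82)
  expect_equal(sum(res$bins$tumor), 97)
  # identical groups: p ~ 1
  same <- level_distribution_test(benign, benign)
  expect_gt(same$p_value, 0.99)
  expect_error(level_distribution_test(numeric(0), tumor), "non-empty")
})

test_that("regional spectrum proportions are tallied correctly and sum to 1", {
  ann <- test_annotation()
  # all four somatic variants inside one protein gene
  res <- region_spectrum(c(12400L, 12500L, 13000L, 14000L),
                         rep("somatic", 4), ann)
  expect_equal(res$somatic_prop[res$region == "MT-ND5"], 1)
  expect_equal(sum(res$somatic_prop), 1)
  # random placements match a brute-force tally
  set.seed(31)
  pos <- sample.int(16569, 60)
  set <- sample(c("somatic", "inherited"), 60, replace = TRUE)
  res <- region_spectrum(pos, set, ann)
  expect_equal(sum(res$somatic_prop), 1)
  expect_equal(sum(res$inherited_prop), 1)
  grp <- vapply(pos, function(p) {
    r <- locate_gene(p, ann)
    if (r$region_class == "tRNA") "tRNA"
    else if (r$region_class == "control") "control" else r$name
  }, character(1))
  for (g in unique(grp)) {
    expect_equal(res$somatic_n[res$region == g], sum(grp == g & set == "somatic"))
    expect_equal(res$inherited_n[res$region == g], sum(grp == g & set == "inherited"))
  }
  # length fractions cover the genome
  expect_equal(sum(res$length_fraction), 1, tolerance = 1e-9)
})

test_that("spectrum correlations behave at the constructed extremes", {
  ann <- test_annotation()
  set.seed(8)
  pos <- sample.int(16569, 80)
  res <- region_spectrum(pos, rep("somatic", 80), ann)
  res$inherited_prop <- res$somatic_prop  # identical spectra
  sc <- spectrum_correlations(res)
  expect_equal(sc$somatic_vs_inherited$r, 1)
  # proportions proportional to gene length -> r = 1 among protein genes
  res2 <- res
  res2$somatic_prop <- res2$length_fraction / sum(res2$length_fraction)
  res2$inherited_prop <- res2$somatic_prop
  sc2 <- spectrum_correlations(res2)
  expect_equal(sc2$somatic_vs_length$r, 1)
  # random spectra agree with the closed-form computation
  res3 <- res
  res3$somatic_prop <- runif(nrow(res3)); res3$inherited_prop <- runif(nrow(res3))
  sc3 <- spectrum_correlations(res3)
  expect_equal(sc3$somatic_vs_inherited$r,
               oracle_pearson(res3$somatic_prop, res3$inherited_prop))
})

test_that("nonsynonymous enrichment tests the 2x2 table appropriately", {
  res <- nonsyn_enrichment(rep("nonsynonymous", 20), rep("synonymous", 20))
  expect_lt(res$p_value, 0.001)
  same <- nonsyn_enrichment(rep(c("nonsynonymous", "synonymous"), 15),
                            rep(c("nonsynonymous", "synonymous"), 15))
  expect_gt(same$p_value, 0.99)
  # small expected cells switch to Fisher, matching a direct hypergeometric test
  s <- c(rep("nonsynonymous", 6), rep("synonymous", 1))
  g <- c(rep("nonsynonymous", 2), rep("synonymous", 5))
  res2 <- nonsyn_enrichment(s, g)
  expect_equal(res2$method, "fisher")
  expect_equal(res2$p_value, fisher.test(rbind(c(6, 1), c(2, 5)))$p.value)
  # large balanced tables use chi-square and match the closed form
  s <- c(rep("nonsynonymous", 40), rep("synonymous", 20))
  g <- c(rep("nonsynonymous", 25), rep("synonymous", 35))
  res3 <- nonsyn_enrichment(s, g)
  expect_equal(res3$method, "chisq")
  expect_equal(res3$statistic, oracle_chisq_2x2(40, 20, 25, 35)$stat)
  expect_error(nonsyn_enrichment(character(0), "synonymous"), "protein-region")
})

test_that("profile splitting keeps homoplasmies in both and reconstructs the set", {
  vars <- data.frame(
    pos = c(100L, 200L, 300L, 400L, 500L, 600L),
    ref = c("A", "C", "G", "T", "A", "C"),
    major = c("G", "T", "A", "C", "G", "T"),
    minor = c(NA, NA, NA, NA, NA, "C"),
    stringsAsFactors = FALSE
  )
  pr <- split_profiles(vars)
  # both profiles carry the five homoplasmic variants identically
  expect_equal(pr$major$allele[1:5], vars$major[1:5])
  expect_equal(pr$minor$allele[1:5], vars$major[1:5])
  # the heteroplasmic site contributes its two components
  expect_equal(pr$major$allele[6], "T")
  expect_equal(pr$minor$allele[6], "C")
  # merging reconstructs the original variant set
  merged <- unique(rbind(
    data.frame(pos = pr$major$pos, allele = pr$major$allele),
    data.frame(pos = pr$minor$pos, allele = pr$minor$allele)))
  orig <- unique(rbind(
    data.frame(pos = vars$pos, allele = vars$major),
    data.frame(pos = vars$pos[6], allele = vars$minor[6])))
  expect_equal(merged[order(merged$pos, merged$allele), ],
               orig[order(orig$pos, orig$allele), ], ignore_attr = TRUE)
  # no heteroplasmies: identical profiles
  pr2 <- split_profiles(vars[1:3, ])
  expect_equal(pr2$major, pr2$minor)
})
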