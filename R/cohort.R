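BENIGN_CLASSES <- c("benign_margin", "blood", "benign_lymph_node")
CANCER_CLASSES <- c("primary_tumor", "recurrence", "lymph_node_metastasis",
                    "dysplasia", "second_primary")
TISSUE_CLASSES <- c(BENIGN_CLASSES, CANCER_CLASSES)

#' Load the published shared-mutation tables
#'
#' The per-patient levels of mtDNA mutations observed in more than one tissue
#' sample, shipped with the package as a plain-text fixture: the somatic set
#' (absent from benign tissue) and the germline set (shared with benign
#' tissue or blood).  Levels are percentages of the mutated nucleotide
#' relative to the rCRS.
#'
#' @param long Return the long record format used by the cohort functions
#'   (default) instead of the wide table layout.
#' @return With `long = TRUE`, a data.frame with columns `table patient_id
#'   variant tissue_class level_pct mark` where `mark` is `""` (observed),
#'   `"n.a."` (tissue not available) or `"n.d."` (not detected above the 1%
#'   threshold); otherwise the wide table.
#' @export
study_shared_mutations <- function(long = TRUE) {
  path <- system.file("extdata", "study_shared_mutations.tsv", package = "mitohet")
  wide <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                     colClasses = "character")
  if (!long) return(wide)
  tissue_cols <- c(benign = "benign_margin", blood = "blood",
                   primary_tumor = "primary_tumor", recurrence = "recurrence",
                   lymph_node_metastasis = "lymph_node_metastasis")
  rows <- lapply(seq_len(nrow(wide)), function(i) {
    vals <- unlist(wide[i, names(tissue_cols)])
    data.frame(
      table = wide$table[i], patient_id = wide$patient[i],
      variant = wide$mutation[i],
      tissue_class = unname(tissue_cols),
      level_pct = suppressWarnings(as.numeric(vals)),
      mark = ifelse(vals %in% c("n.a.", "n.d."), vals, ""),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

is_detected <- function(record) record$mark == "" & !is.na(record$level_pct)

minor_component <- function(level_pct) pmin(level_pct, 100 - level_pct)

#' Classify a variant of one patient across tissues
#'
#' Takes the per-tissue levels of a single variant in a single patient and
#' assigns one of four statuses:
#' * `germline_homoplasmic` -- homoplasmic in every sampled tissue;
#' * `germline_heteroplasmy` -- heteroplasmic in at least one benign-class
#'   tissue (resection margin, blood, benign lymph node) and in at least one
#'   cancerous tissue: a germline heteroplasmy carried into the tumor;
#' * `somatic_shared` -- absent from all benign-class tissues but present in
#'   two or more cancerous tissues;
#' * `somatic_private` -- anything else (detected in a single tissue only, or
#'   in benign tissue only).
#'
#' "Not detected" (below the 1% calling threshold) counts as absence;
#' unavailable tissues are ignored entirely.
#'
#' @param record data.frame with columns `tissue_class`, `level_pct`, `mark`
#'   (one row per tissue; `mark` as in [study_shared_mutations()]).
#' @param het_threshold_pct Minor-component percentage above which an
#'   observation counts as heteroplasmic (default 1).
#' @param homoplasmy_min_pct Level at or above which an observation counts as
#'   homoplasmic for the mutated allele (default 99).
#' @return One of the four status strings.
#' @export
classify_variant <- function(record, het_threshold_pct = 1,
                             homoplasmy_min_pct = 99) {
  stopifnot(all(c("tissue_class", "level_pct", "mark") %in% names(record)))
  bad <- setdiff(record$tissue_class, TISSUE_CLASSES)
  if (length(bad)) stop("unknown tissue class: ", paste(bad, collapse = ", "))
  avail <- record[record$mark != "n.a.", , drop = FALSE]
  if (!nrow(avail)) stop("cannot classify: no tissue available for this variant")
  det <- avail[is_detected(avail), , drop = FALSE]
  if (nrow(det) == 0L) stop("cannot classify: variant not detected in any tissue")
  homo <- det$level_pct >= homoplasmy_min_pct
  het <- minor_component(det$level_pct) >= het_threshold_pct & !homo
  if (all(homo) && nrow(det) == nrow(avail)) return("germline_homoplasmic")
  in_benign_het <- any(het & det$tissue_class %in% BENIGN_CLASSES)
  in_cancer <- det$tissue_class %in% CANCER_CLASSES
  if (in_benign_het && any(het & in_cancer)) return("germline_heteroplasmy")
  benign_detected <- any(det$tissue_class %in% BENIGN_CLASSES)
  if (!benign_detected && sum(in_cancer) >= 2L) return("somatic_shared")
  "somatic_private"
}

#' Classify every patient-variant record of a cohort
#'
#' @param records Long records data.frame (`patient_id`, `variant`,
#'   `tissue_class`, `level_pct`, `mark`).
#' @param ... Passed to [classify_variant()].
#' @return data.frame with one row per patient-variant (`patient_id`,
#'   `variant`, `status`).
#' @export
classify_cohort <- function(records, ...) {
  key <- interaction(records$patient_id, records$variant, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(r) {
    data.frame(patient_id = r$patient_id[1], variant = r$variant[1],
               status = classify_variant(r, ...), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mean level of shared somatic mutations per tissue class
#'
#' Averages the observed levels of shared somatic mutations within each
#' tissue class, and reports per patient-variant trajectories (level change
#' and fold change) from the primary tumor to recurrences and lymph-node
#' metastases.  Unavailable and undetected tissues never enter a mean.
#'
#' @param records Long records data.frame of shared somatic mutations
#'   (`patient_id`, `variant`, `tissue_class`, `level_pct`, `mark`).
#' @return List with `means` (data.frame `tissue_class n mean_level_pct`)
#'   and `trajectories` (data.frame `patient_id variant from to delta ratio`).
#' @export
shared_somatic_summary <- function(records) {
  det <- records[is_detected(records), , drop = FALSE]
  if (!nrow(det)) stop("no observed levels among the records")
  means <- do.call(rbind, lapply(split(det, det$tissue_class), function(r) {
    data.frame(tissue_class = r$tissue_class[1], n = nrow(r),
               mean_level_pct = mean(r$level_pct), stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL
  key <- interaction(det$patient_id, det$variant, drop = TRUE)
  traj <- do.call(rbind, lapply(split(det, key), function(r) {
    from <- r$level_pct[r$tissue_class == "primary_tumor"]
    if (!length(from)) return(NULL)
    to_class <- intersect(c("recurrence", "lymph_node_metastasis"), r$tissue_class)
    if (!length(to_class)) return(NULL)
    do.call(rbind, lapply(to_class, function(tc) {
      to <- r$level_pct[r$tissue_class == tc]
      data.frame(patient_id = r$patient_id[1], variant = r$variant[1],
                 from = "primary_tumor", to = tc,
                 level_from = from[1], level_to = to[1],
                 delta = to[1] - from[1], ratio = to[1] / from[1],
                 stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(traj)) rownames(traj) <- NULL
  list(means = means, trajectories = traj)
}

#' Fraction of high-level heteroplasmies
#'
#' @param levels Numeric levels (percent).
#' @param boundary High-level boundary; strictly above counts (default 10).
#' @return Percentage in \[0, 100\].
#' @export
high_level_fraction <- function(levels, boundary = 10) {
  levels <- levels[!is.na(levels)]
  if (!length(levels)) stop("no levels supplied")
  100 * sum(levels > boundary) / length(levels)
}

#' Compare heteroplasmy level distributions between two tissue groups
#'
#' Counts heteroplasmies below versus at-or-above a level boundary in each
#' group and tests the 2x2 table with Pearson's chi-square *without*
#' continuity correction.  One-percent-wide binned frequency distributions
#' (6.0-6.9%, 7.0-7.9%, ...) are returned alongside for plotting.
#'
#' @param benign_levels,tumor_levels Numeric heteroplasmy levels (percent of
#'   the minor component) per group.
#' @param boundary Level boundary (default 10).
#' @return List with `counts` (2x2 matrix), `proportion_low` (per group, %),
#'   `statistic`, `df`, `p_value` and `bins` (data.frame of 1%-bin counts per
#'   group).
#' @export
level_distribution_test <- function(benign_levels, tumor_levels, boundary = 10) {
  benign_levels <- benign_levels[!is.na(benign_levels)]
  tumor_levels <- tumor_levels[!is.na(tumor_levels)]
  if (!length(benign_levels) || !length(tumor_levels)) {
    stop("both groups must be non-empty")
  }
  counts <- rbind(
    benign = c(low = sum(benign_levels < boundary),
               high = sum(benign_levels >= boundary)),
    tumor = c(low = sum(tumor_levels < boundary),
              high = sum(tumor_levels >= boundary))
  )
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  breaks <- seq(0, 100, by = 1)
  bins <- data.frame(
    bin = paste0(sprintf("%.1f", breaks[-length(breaks)]), "-",
                 sprintf("%.1f", breaks[-1] - 0.1)),
    benign = as.integer(table(cut(benign_levels, breaks, right = FALSE))),
    tumor = as.integer(table(cut(tumor_levels, breaks, right = FALSE))),
    stringsAsFactors = FALSE
  )
  list(counts = counts,
       proportion_low = 100 * counts[, "low"] / rowSums(counts),
       statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, bins = bins)
}

#' Regional spectrum of somatic and inherited variants
#'
#' Maps variant positions onto gene regions and tabulates counts and
#' proportions separately for the somatic and the inherited set.  Regions are
#' grouped with each protein gene and rRNA on its own, all tRNAs pooled, and
#' the control region pooled (including the minor non-coding features) --
#' or per broad class with `grouping = "class"`.
#'
#' @param positions Integer vector of variant positions.
#' @param set Character vector (`"somatic"`/`"inherited"`) parallel to
#'   `positions`.
#' @param annotation A [read_region_annotation()] table.
#' @param grouping `"gene"` (default) or `"class"`.
#' @return A data.frame of class `spectrum_table`: `region region_class
#'   length_fraction somatic_n somatic_prop inherited_n inherited_prop`.
#' @export
region_spectrum <- function(positions, set, annotation, grouping = c("gene", "class")) {
  grouping <- match.arg(grouping)
  if (length(positions) != length(set)) stop("positions and set must be parallel")
  if (!all(set %in% c("somatic", "inherited"))) {
    stop("set must be 'somatic' or 'inherited'")
  }
  reg <- lapply(positions, locate_gene, annotation = annotation)
  nm <- vapply(reg, function(r) r$name, character(1))
  cl <- vapply(reg, function(r) r$region_class, character(1))
  group_of <- function(name, class) {
    if (grouping == "class") class
    else if (class == "tRNA") "tRNA"
    else if (class == "control") "control"
    else name
  }
  grp <- mapply(group_of, nm, cl)
  # region universe with genome length fractions, under the same grouping
  agrp <- mapply(group_of, annotation$name, annotation$region_class)
  lens <- tapply(relative_gene_length(annotation), agrp, sum)
  acls <- tapply(annotation$region_class, agrp, function(x) x[1])
  regions <- names(lens)
  tab <- function(which_set) {
    n <- vapply(regions, function(g) sum(grp == g & set == which_set), numeric(1))
    prop <- if (sum(n) > 0) n / sum(n) else n
    list(n = n, prop = prop)
  }
  som <- tab("somatic"); inh <- tab("inherited")
  out <- data.frame(
    region = regions, region_class = as.character(acls[regions]),
    length_fraction = as.numeric(lens[regions]),
    somatic_n = as.integer(som$n), somatic_prop = som$prop,
    inherited_n = as.integer(inh$n), inherited_prop = inh$prop,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("spectrum_table", "data.frame")
  out
}

#' Correlations over a regional variant spectrum
#'
#' Three product-moment correlations: somatic versus inherited proportions
#' over all regions, and -- among protein-coding genes -- each set's
#' proportion versus the gene's relative length.
#'
#' @param spectrum A [region_spectrum()] table.
#' @return List with `somatic_vs_inherited`, `somatic_vs_length`,
#'   `inherited_vs_length`, each a `pearson_r()` result.
#' @export
spectrum_correlations <- function(spectrum) {
  if (nrow(spectrum) < 3L) stop("need at least 3 regions")
  prot <- spectrum[spectrum$region_class == "protein", , drop = FALSE]
  list(
    somatic_vs_inherited = pearson_r(spectrum$somatic_prop, spectrum$inherited_prop),
    somatic_vs_length = pearson_r(prot$somatic_prop, prot$length_fraction),
    inherited_vs_length = pearson_r(prot$inherited_prop, prot$length_fraction)
  )
}

#' Test enrichment of non-synonymous variants in the somatic set
#'
#' 2x2 test (non-synonymous/synonymous x somatic/germline) over
#' protein-region variants, Pearson chi-square without continuity correction,
#' replaced by Fisher's exact test when any expected cell count falls below 5.
#'
#' @param somatic_effects,germline_effects Character vectors of
#'   [classify_coding_effect()] results; non-protein classes are dropped.
#' @return List with `counts`, `method`, `statistic` (chi-square only),
#'   `p_value`.
#' @export
nonsyn_enrichment <- function(somatic_effects, germline_effects) {
  keep <- c("synonymous", "nonsynonymous")
  s <- somatic_effects[somatic_effects %in% keep]
  g <- germline_effects[germline_effects %in% keep]
  if (!length(s) || !length(g)) stop("need protein-region variants in both sets")
  counts <- rbind(
    somatic = c(nonsynonymous = sum(s == "nonsynonymous"),
                synonymous = sum(s == "synonymous")),
    germline = c(nonsynonymous = sum(g == "nonsynonymous"),
                 synonymous = sum(g == "synonymous"))
  )
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    ft <- fisher.test(counts)
    list(counts = counts, method = "fisher", statistic = NA_real_,
         p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
    list(counts = counts, method = "chisq", statistic = unname(ct$statistic),
         p_value = ct$p.value)
  }
}

#' Split a sample into major and minor component profiles
#'
#' For contamination QC a sample is rendered as two haplotype profiles: both
#' contain every homoplasmic variant; each heteroplasmic site contributes its
#' major allele to the major profile and its minor allele to the minor
#' profile.  Merging the two profiles reconstructs the variant set.
#'
#' @param variants data.frame with columns `pos`, `ref`, `major`, `minor`
#'   (`minor` `NA` for homoplasmic variants).
#' @return List with `major` and `minor` profile data.frames (`pos`, `ref`,
#'   `allele`, `heteroplasmic`).
#' @export
split_profiles <- function(variants) {
  het <- !is.na(variants$minor)
  prof <- function(allele_col) {
    data.frame(pos = variants$pos, ref = variants$ref,
               allele = ifelse(het, variants[[allele_col]], variants$major),
               heteroplasmic = het, stringsAsFactors = FALSE)
  }
  list(major = prof("major"), minor = prof("minor"))
}
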