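# run expr under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Synthetic mitochondrial reference genome
#'
#' A random 16,569-bp sequence used as a stand-in reference for simulations
#' and tests.  It shares the rCRS coordinate system and length but not its
#' sequence; anything that depends on actual rCRS bases must be given a real
#' reference FASTA via [read_genome_fasta()].
#'
#' @param seed RNG seed.
#' @return A [mito_genome()] named `"synthetic-rCRS-standin"`.
#' @export
synthetic_genome <- function(seed = 1) {
  with_seed(seed, {
    mito_genome(sample(BASES, MT_GENOME_LENGTH, replace = TRUE),
                name = "synthetic-rCRS-standin")
  })
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Generate a two-haplotype mixture design
#'
#' Haplotype A is the reference itself; haplotype B carries transition
#' substitutions at `n_diff` uniformly placed sites, emulating two donor
#' genomes that differ at a known set of positions (27 in the dilution
#' experiment this models).
#'
#' @param genome A [mito_genome()].
#' @param n_diff Number of differing sites (default 27).
#' @param fraction_b Minor mixing fraction in \[0, 0.5\] (default 0.01, the
#'   1+99 dilution).
#' @param coverage_per_strand Expected per-strand depth (default 17,500, i.e.
#'   ~35,000x total).
#' @param error_rate Per-base miscall probability after quality filtering
#'   (default 0.001, the Q30 operating point).
#' @param seed RNG seed for site placement.
#' @return A list of class `mixture_design` with `haplotype_a`,
#'   `haplotype_b` (character vectors), `differing_sites`, `alt_alleles`,
#'   `fraction_b`, `coverage_per_strand`, `error_rate`.
#' @export
make_haplotype_pair <- function(genome, n_diff = 27L, fraction_b = 0.01,
                                coverage_per_strand = 17500,
                                error_rate = 0.001, seed = NULL) {
  if (n_diff < 0L || n_diff > genome$length) {
    stop("n_diff must be between 0 and the genome length")
  }
  if (fraction_b < 0 || fraction_b > 0.5) {
    stop("fraction_b is the minor component and must lie in [0, 0.5]")
  }
  with_seed(seed, {
    sites <- sort(sample.int(genome$length, n_diff))
    hb <- genome$sequence
    hb[sites] <- unname(TRANSITION[hb[sites]])
    structure(list(
      haplotype_a = genome$sequence, haplotype_b = hb,
      differing_sites = sites, alt_alleles = hb[sites],
      fraction_b = fraction_b, coverage_per_strand = coverage_per_strand,
      error_rate = error_rate, genome_name = genome$name
    ), class = "mixture_design")
  })
}

# distribute n error reads over the three non-source bases, uniformly
scatter_errors <- function(counts_row, source_base, n_err) {
  if (n_err == 0L) return(counts_row)
  others <- setdiff(BASES, source_base)
  add <- rmultinom(1L, n_err, rep(1 / 3, 3))[, 1L]
  counts_row[others] <- counts_row[others] + add
  counts_row[source_base] <- counts_row[source_base] - n_err
  counts_row
}

#' Simulate strand-resolved base counts for a haplotype mixture
#'
#' Per position and strand, depth is Poisson around the target per-strand
#' coverage; the number of reads drawn from haplotype B is binomial with the
#' mixing fraction; uniform per-base miscalls are then scattered over the
#' three alternative bases.  Deterministic under `seed`.
#'
#' @param design A [make_haplotype_pair()] result.
#' @param seed RNG seed.
#' @return A pileup data.frame (see [build_pileup()]) with `ref` set to
#'   haplotype A (the reference).
#' @export
simulate_mixture_counts <- function(design, seed = NULL) {
  stopifnot(inherits(design, "mixture_design"))
  with_seed(seed, {
    L <- length(design$haplotype_a)
    out <- vector("list", 2L)
    for (si in 1:2) {
      depth <- rpois(L, design$coverage_per_strand)
      nb <- rbinom(L, depth, design$fraction_b)
      counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
      ia <- match(design$haplotype_a, BASES)
      ib <- match(design$haplotype_b, BASES)
      counts[cbind(seq_len(L), ia)] <- depth - nb
      diff_site <- ia != ib
      counts[cbind(which(diff_site), ib[diff_site])] <-
        counts[cbind(which(diff_site), ib[diff_site])] + nb[diff_site]
      counts[cbind(which(!diff_site), ia[!diff_site])] <-
        counts[cbind(which(!diff_site), ia[!diff_site])] + nb[!diff_site]
      if (design$error_rate > 0) {
        # errors out of the A-derived and B-derived read pools separately
        err_a <- rbinom(L, depth - nb, design$error_rate)
        err_b <- rbinom(L, nb, design$error_rate)
        for (i in which(err_a > 0L)) {
          counts[i, ] <- scatter_errors(counts[i, ], design$haplotype_a[i], err_a[i])
        }
        for (i in which(err_b > 0L)) {
          counts[i, ] <- scatter_errors(counts[i, ], design$haplotype_b[i], err_b[i])
        }
      }
      out[[si]] <- counts
    }
    pu <- data.frame(
      pos = rep(seq_len(L), each = 2L),
      ref = rep(design$haplotype_a, each = 2L),
      strand = rep(c("+", "-"), times = L),
      A = 0L, C = 0L, G = 0L, T = 0L, depth = 0L,
      stringsAsFactors = FALSE
    )
    for (b in BASES) {
      pu[[b]][pu$strand == "+"] <- out[[1L]][, b]
      pu[[b]][pu$strand == "-"] <- out[[2L]][, b]
    }
    pu$depth <- pu$A + pu$C + pu$G + pu$T
    class(pu) <- c("mito_pileup", "data.frame")
    pu
  })
}

#' Estimate the mixture fraction from caller output
#'
#' Averages the estimated minor-component fraction over the differing sites
#' that the caller detected.
#'
#' @param calls Calls data.frame from [call_heteroplasmies()].
#' @param design The [make_haplotype_pair()] design (for the site list).
#' @return List with `fraction` (mean minor fraction, 0..0.5), `n_detected`,
#'   `n_sites`, `per_site` (data.frame).
#' @export
estimate_mixture_fraction <- function(calls, design) {
  hit <- calls[calls$pos %in% design$differing_sites, , drop = FALSE]
  alt <- design$alt_alleles[match(hit$pos, design$differing_sites)]
  correct <- hit[hit$minor == alt | hit$major == alt, , drop = FALSE]
  list(
    fraction = if (nrow(correct)) mean(correct$minor_pct) / 100 else NA_real_,
    n_detected = nrow(correct), n_sites = length(design$differing_sites),
    per_site = correct[, c("pos", "minor", "minor_pct")]
  )
}

# ---- cohort simulation ------------------------------------------------------

#' Design of a synthetic multi-tissue cohort
#'
#' Parameter defaults emulate the structure of the study cohort this package
#' models: 28 patients, each with a benign resection margin and a primary
#' tumor; a recurrence in ~21% of patients, a lymph-node metastasis in ~18%,
#' a blood sample in ~14%.  Germline heteroplasmies are drawn at low levels
#' (log-normal, ~80% below 10%) and undergo clonal expansion (log-normal
#' multiplier, median 2.8) in cancerous tissues; shared somatic mutations
#' arise in the tumor and expand further in recurrences/metastases.  Phantom
#' artifacts are injected at fixed positions as recurrent ~1.5% calls with a
#' forward-strand coverage drop, plus satellite neighbor positions whose
#' levels track the anchor.
#'
#' @param n_patients Number of patients (default 28).
#' @param p_recurrence,p_lymph,p_blood Per-patient probabilities of the
#'   optional tissue samples (defaults 6/28, 5/28, 4/28).
#' @param germline_het_rate Mean number of germline heteroplasmies per
#'   patient (default 3).
#' @param germline_meanlog,germline_sdlog Log-normal level distribution (%)
#'   for germline heteroplasmies (defaults log(4), 1).
#' @param somatic_shared_rate Mean number of shared somatic mutations per
#'   patient with a recurrence or metastasis (default 2).
#' @param somatic_private_rate Mean number of private somatic mutations per
#'   cancerous sample (default 1.5).
#' @param expansion_meanlog,expansion_sdlog Log-normal clonal-expansion
#'   multiplier benign->tumor and tumor->recurrence/metastasis (defaults
#'   log(2.8), 0.5).
#' @param n_germline_homo Homoplasmic germline variants per patient
#'   (default 15).
#' @param artifact_positions Anchor positions for injected phantom artifacts
#'   (default 72 and 414).
#' @param artifact_neighbors Satellite positions riding on the first anchor
#'   (default 73 and 74).
#' @param artifact_prob Per-sample probability of each anchor artifact
#'   (default 0.45).
#' @param artifact_level_mean,artifact_level_sd Artifact level distribution
#'   in percent (defaults 1.5, 0.3; truncated to \[1, 4.9\]).
#' @param coverage_per_strand Simulated per-strand depth (default 17,500).
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_patients = 28L, p_recurrence = 6 / 28,
                          p_lymph = 5 / 28, p_blood = 4 / 28,
                          germline_het_rate = 3, germline_meanlog = log(4),
                          germline_sdlog = 1, somatic_shared_rate = 2,
                          somatic_private_rate = 1.5,
                          expansion_meanlog = log(2.8), expansion_sdlog = 0.5,
                          n_germline_homo = 15L,
                          artifact_positions = c(72L, 414L),
                          artifact_neighbors = c(73L, 74L),
                          artifact_prob = 0.45,
                          artifact_level_mean = 1.5, artifact_level_sd = 0.3,
                          coverage_per_strand = 17500) {
  probs <- c(p_recurrence, p_lymph, p_blood, artifact_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (exp(expansion_meanlog) < 1 && somatic_shared_rate > 0) {
    stop("expansion multiplier below 1 contradicts the required ",
         "level-increase pattern in recurrences/metastases")
  }
  structure(as.list(environment()), class = "cohort_design")
}

trunc_level <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# one simulated heteroplasmy call row with binomial per-strand counts
sim_call_row <- function(sample_id, pos, ref, alt, level_pct, cov,
                         fwd_factor = 1) {
  df <- rpois(1L, cov * fwd_factor)
  dr <- rpois(1L, cov)
  nf <- rbinom(1L, df, level_pct / 100)
  nr <- rbinom(1L, dr, level_pct / 100)
  alt_frac <- 100 * (nf + nr) / (df + dr)
  minor_is_alt <- alt_frac <= 50
  data.frame(
    sample = sample_id, pos = as.integer(pos), ref = ref,
    major = if (minor_is_alt) ref else alt,
    minor = if (minor_is_alt) alt else ref,
    level_pct = alt_frac,
    minor_pct = min(alt_frac, 100 - alt_frac),
    minor_fwd_pct = 100 * (if (minor_is_alt) nf else df - nf) / max(df, 1L),
    minor_rev_pct = 100 * (if (minor_is_alt) nr else dr - nr) / max(dr, 1L),
    depth_fwd = df, depth_rev = dr, filters = "",
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-tissue heteroplasmy cohort
#'
#' Generates a sample sheet, per-sample heteroplasmy call sets and a
#' ground-truth table under a [cohort_design()].  Germline heteroplasmies
#' appear in every tissue of a patient (expanded in cancerous ones); shared
#' somatic mutations appear in the primary tumor and its recurrence or
#' lymph-node metastasis with clonal expansion; private somatic mutations
#' appear in single cancerous samples; phantom artifacts recur across
#' samples at low level with a forward-strand coverage drop signature.
#'
#' @param design A [cohort_design()].
#' @param genome A [mito_genome()]; defaults to [synthetic_genome()].
#' @param seed RNG seed.
#' @return List with `samples` (`patient_id sample_id tissue_class`), `calls`
#'   (cohort calls data.frame), `homoplasmies` (`patient_id pos ref alt`),
#'   `truth` (`patient_id pos ref alt truth`), and `design`.
#' @export
simulate_cohort <- function(design = cohort_design(), genome = synthetic_genome(),
                            seed = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    d <- design
    cov <- d$coverage_per_strand
    samples <- list(); calls <- list(); truth <- list(); homo <- list()
    reserved <- c(d$artifact_positions, d$artifact_neighbors)
    sample_positions <- function(n) {
      p <- sample(setdiff(seq_len(genome$length), reserved), n)
      reserved <<- c(reserved, p)
      sort(p)
    }
    for (i in seq_len(d$n_patients)) {
      pid <- sprintf("P%02d", i)
      tissues <- c("benign_margin", "primary_tumor")
      if (runif(1) < d$p_recurrence) tissues <- c(tissues, "recurrence")
      if (runif(1) < d$p_lymph) tissues <- c(tissues, "lymph_node_metastasis")
      if (runif(1) < d$p_blood) tissues <- c(tissues, "blood")
      sids <- setNames(paste0(pid, "_", tissues), tissues)
      samples[[pid]] <- data.frame(patient_id = pid, sample_id = unname(sids),
                                   tissue_class = tissues, stringsAsFactors = FALSE)
      cancer <- intersect(tissues, CANCER_CLASSES)
      benign <- intersect(tissues, BENIGN_CLASSES)

      # homoplasmic germline variants: in every tissue, not heteroplasmy calls
      n_h <- d$n_germline_homo
      if (n_h > 0L) {
        hp <- sample_positions(n_h)
        ref <- genome$sequence[hp]
        homo[[pid]] <- data.frame(patient_id = pid, pos = hp, ref = ref,
                                  alt = unname(TRANSITION[ref]),
                                  stringsAsFactors = FALSE)
        truth[[paste0(pid, "_h")]] <- data.frame(
          patient_id = pid, pos = hp, ref = ref, alt = unname(TRANSITION[ref]),
          truth = "germline_homoplasmic", stringsAsFactors = FALSE)
      }

      # germline heteroplasmies: low level in benign/blood, expanded in cancer
      n_g <- rpois(1L, d$germline_het_rate)
      if (n_g > 0L) {
        gp <- sample_positions(n_g)
        ref <- genome$sequence[gp]
        alt <- unname(TRANSITION[ref])
        for (k in seq_len(n_g)) {
          base_level <- trunc_level(rlnorm(1, d$germline_meanlog, d$germline_sdlog),
                                    1.2, 45)
          for (tc in tissues) {
            lv <- if (tc %in% CANCER_CLASSES) {
              trunc_level(base_level * rlnorm(1, d$expansion_meanlog,
                                              d$expansion_sdlog), 1.2, 99)
            } else base_level
            calls[[length(calls) + 1L]] <-
              sim_call_row(sids[[tc]], gp[k], ref[k], alt[k], lv, cov)
          }
        }
        truth[[paste0(pid, "_g")]] <- data.frame(
          patient_id = pid, pos = gp, ref = ref, alt = alt,
          truth = "germline_heteroplasmy", stringsAsFactors = FALSE)
      }

      # shared somatic mutations: tumor + recurrence/metastasis, expanding
      later <- intersect(c("recurrence", "lymph_node_metastasis"), tissues)
      if (length(later)) {
        n_s <- max(1L, rpois(1L, d$somatic_shared_rate))
        sp <- sample_positions(n_s)
        ref <- genome$sequence[sp]
        alt <- unname(TRANSITION[ref])
        for (k in seq_len(n_s)) {
          t_level <- trunc_level(rlnorm(1, log(10), 0.8), 2, 80)
          calls[[length(calls) + 1L]] <-
            sim_call_row(sids[["primary_tumor"]], sp[k], ref[k], alt[k], t_level, cov)
          for (tc in later) {
            lv <- trunc_level(t_level * rlnorm(1, d$expansion_meanlog,
                                               d$expansion_sdlog), 2, 99)
            calls[[length(calls) + 1L]] <-
              sim_call_row(sids[[tc]], sp[k], ref[k], alt[k], lv, cov)
          }
        }
        truth[[paste0(pid, "_s")]] <- data.frame(
          patient_id = pid, pos = sp, ref = ref, alt = alt,
          truth = "somatic_shared", stringsAsFactors = FALSE)
      }

      # private somatic mutations: one cancerous sample each
      for (tc in cancer) {
        n_p <- rpois(1L, d$somatic_private_rate)
        if (n_p > 0L) {
          pp <- sample_positions(n_p)
          ref <- genome$sequence[pp]
          alt <- unname(TRANSITION[ref])
          for (k in seq_len(n_p)) {
            lv <- trunc_level(rlnorm(1, log(6), 1), 1.2, 95)
            calls[[length(calls) + 1L]] <-
              sim_call_row(sids[[tc]], pp[k], ref[k], alt[k], lv, cov)
          }
          truth[[paste0(pid, "_p", tc)]] <- data.frame(
            patient_id = pid, pos = pp, ref = ref, alt = alt,
            truth = "somatic_private", stringsAsFactors = FALSE)
        }
      }
    }

    samples <- do.call(rbind, samples)
    rownames(samples) <- NULL

    # phantom artifacts: recurrent low-level calls with forward-strand drop
    art <- list()
    anchor1 <- d$artifact_positions[1L]
    for (s in samples$sample_id) {
      for (ap in d$artifact_positions) {
        if (runif(1) < d$artifact_prob) {
          lv <- trunc_level(rnorm(1, d$artifact_level_mean, d$artifact_level_sd),
                            1, 4.9)
          ref <- genome$sequence[ap]
          art[[length(art) + 1L]] <-
            sim_call_row(s, ap, ref, unname(TRANSITION[ref]), lv,
                         cov, fwd_factor = 0.55)
          # satellites ride on the first anchor, levels proportional
          if (ap == anchor1) {
            for (np in d$artifact_neighbors) {
              refn <- genome$sequence[np]
              art[[length(art) + 1L]] <-
                sim_call_row(s, np, refn, unname(TRANSITION[refn]),
                             trunc_level(lv * 0.8, 1, 4.9), cov)
            }
          }
        }
      }
    }
    art_truth <- data.frame(
      patient_id = NA_character_,
      pos = c(d$artifact_positions, d$artifact_neighbors),
      ref = genome$sequence[c(d$artifact_positions, d$artifact_neighbors)],
      alt = unname(TRANSITION[genome$sequence[c(d$artifact_positions,
                                                d$artifact_neighbors)]]),
      truth = "artifact", stringsAsFactors = FALSE)

    calls <- do.call(rbind, c(calls, art))
    if (is.null(calls)) calls <- empty_calls()
    rownames(calls) <- NULL
    truth <- rbind(do.call(rbind, truth), art_truth)
    rownames(truth) <- NULL
    homo <- if (length(homo)) do.call(rbind, homo) else
      data.frame(patient_id = character(0), pos = integer(0),
                 ref = character(0), alt = character(0), stringsAsFactors = FALSE)
    rownames(homo) <- NULL
    list(samples = samples, calls = calls, homoplasmies = homo,
         truth = truth, design = design)
  })
}

#' Assemble per-tissue variant records from cohort calls
#'
#' Joins a cohort call set against the sample sheet into the long record
#' format consumed by [classify_cohort()]: one row per patient, variant
#' position and tissue class, with the observed level, `"n.d."` for tissues
#' sequenced but without a call at the position, and `"n.a."` for tissue
#' classes the patient lacks.  Homoplasmic variant tables (present in every
#' tissue at level 100) can be appended.
#'
#' @param calls Calls data.frame with `sample` ids matching the sheet.
#' @param samples Sample sheet (`patient_id sample_id tissue_class`).
#' @param homoplasmies Optional data.frame (`patient_id pos ...`) of
#'   homoplasmic variants.
#' @return Long records data.frame (`patient_id variant pos tissue_class
#'   level_pct mark`).
#' @export
cohort_records <- function(calls, samples, homoplasmies = NULL) {
  calls <- merge(calls, samples, by.x = "sample", by.y = "sample_id")
  all_classes <- unique(samples$tissue_class)
  out <- list()
  for (pid in unique(samples$patient_id)) {
    pc <- calls[calls$patient_id == pid, , drop = FALSE]
    ptissues <- samples$tissue_class[samples$patient_id == pid]
    ppos <- unique(pc$pos)
    hpos <- if (!is.null(homoplasmies))
      homoplasmies$pos[homoplasmies$patient_id == pid] else integer(0)
    for (p in c(ppos, hpos)) {
      lev <- vapply(all_classes, function(tc) {
        if (!tc %in% ptissues) return(NA_real_)
        if (p %in% hpos) return(100)
        v <- pc$level_pct[pc$tissue_class == tc & pc$pos == p]
        if (length(v)) mean(v) else NA_real_
      }, numeric(1))
      mark <- ifelse(!all_classes %in% ptissues, "n.a.",
                     ifelse(is.na(lev), "n.d.", ""))
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pid, variant = paste0("pos", p), pos = as.integer(p),
        tissue_class = all_classes, level_pct = lev, mark = mark,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write simulation outputs as plain-text fixtures
#'
#' Emits whichever components are present: haplotype FASTA (`haplotypes.fa`),
#' pileup TSV (`pileup.tsv`), calls TSV (`calls.tsv`), sample sheet
#' (`samples.tsv`), homoplasmies (`homoplasmies.tsv`) and ground truth
#' (`truth.json`).  Deterministic inputs produce byte-identical files.
#'
#' @param outputs A list possibly containing `design` (a `mixture_design`),
#'   `pileup`, `calls`, `samples`, `homoplasmies`, `truth`.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_fixture <- function(outputs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  w <- function(x, file) {
    path <- file.path(dir, file)
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  if (!is.null(outputs$design) && inherits(outputs$design, "mixture_design")) {
    path <- file.path(dir, "haplotypes.fa")
    ss <- Biostrings::DNAStringSet(c(
      haplotype_a = paste(outputs$design$haplotype_a, collapse = ""),
      haplotype_b = paste(outputs$design$haplotype_b, collapse = "")))
    Biostrings::writeXStringSet(ss, path)
    written <- c(written, path)
  }
  if (!is.null(outputs$pileup)) w(outputs$pileup, "pileup.tsv")
  if (!is.null(outputs$calls)) w(outputs$calls, "calls.tsv")
  if (!is.null(outputs$samples)) w(outputs$samples, "samples.tsv")
  if (!is.null(outputs$homoplasmies)) w(outputs$homoplasmies, "homoplasmies.tsv")
  if (!is.null(outputs$truth)) {
    path <- file.path(dir, "truth.json")
    jsonlite::write_json(outputs$truth, path, dataframe = "rows", digits = NA)
    written <- c(written, path)
  }
  invisible(written)
}
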