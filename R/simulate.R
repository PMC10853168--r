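# Seeded synthetic-cohort generator. Produces mutually consistent allele
# alignments, genotypes, binding predictions, mutation summaries, survival,
# LOH calls, TCR repertoires and response labels so the full pipeline can be
# exercised (and effect recovery tested) without any external data. The
# sequences are synthetic and carry no population structure.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

# Master seed fan-out: stage k of master seed s draws its own seed as
# (s * 7919 + k) mod (2^31 - 2) + 1, so each stage is individually
# reproducible and all seeds stay within 32-bit integer range.
.stage_seed <- function(master, k) {
  as.integer((as.double(master) * 7919 + k) %% 2147483646) + 1L
}

#' Configuration for a synthetic cohort
#'
#' Collects the generator's knobs with defaults chosen to emulate a
#' panel-sequenced checkpoint-inhibitor cohort: moderate allele pools with
#' ~4% per-site divergence from a locus consensus (typical heterozygote
#' divergences of a few units), ~10% homozygous loci, a mean of 30 candidate
#' mutant peptides per patient with log-uniform IC50s spanning the 500 nM
#' call threshold, exponential survival with a protective hazard ratio for
#' high scorers, ~19% patient-level HLA-LOH prevalence, power-law clone
#' abundances, and a logistic response model on (HAPS, TMB, diversity).
#'
#' @param n_patients Cohort size.
#' @param n_alleles_per_locus Allele pool size per locus (>= 2).
#' @param alignment_length Alignment columns (default 181, the
#'   binding-domain convention).
#' @param allele_mutation_rate Per-site substitution probability away from
#'   the locus consensus.
#' @param homozygosity_prob Probability a locus is homozygous.
#' @param mean_peptides Mean candidate mutant peptides per patient (Poisson).
#' @param survival List: `baseline_hazard` (events/month), `hr_high`
#'   (multiplicative hazard for patients at/above `haps_cutoff`; < 1 is
#'   protective), `censoring_rate` (expected fraction censored),
#'   `haps_cutoff` (generative threshold; `NULL` = cohort median HAPS).
#' @param loh_prevalence Patient-level LOH prevalence.
#' @param repertoire List: `n_clones`, `exponent` (power-law abundance
#'   exponent; per-patient exponents are jittered around it), `total_reads`.
#' @param response List of logistic coefficients on standardized features:
#'   `intercept`, `haps`, `tmb`, `tcr_diversity`.
#' @param mode `"wes"` (30 Mb region) or `"panel"` (1.09 Mb region) for the
#'   mutation summaries.
#' @param seed Mandatory master seed; fans out to per-stage seeds.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100,
                          n_alleles_per_locus = 6,
                          alignment_length = 181,
                          allele_mutation_rate = 0.04,
                          homozygosity_prob = 0.1,
                          mean_peptides = 30,
                          survival = list(baseline_hazard = 0.04,
                                          hr_high = 0.5,
                                          censoring_rate = 0.2,
                                          haps_cutoff = NULL),
                          loh_prevalence = 0.19,
                          repertoire = list(n_clones = 150,
                                            exponent = 1.0,
                                            total_reads = 1e5),
                          response = list(intercept = -0.25,
                                          haps = 0.8,
                                          tmb = 0.5,
                                          tcr_diversity = 0.5),
                          mode = c("wes", "panel"),
                          seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  mode <- match.arg(mode)
  probs <- c(homozygosity_prob, loh_prevalence,
             survival$censoring_rate %||% 0.2)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_alleles_per_locus < 2) abort("allele pool needs >= 2 per locus")
  if (alignment_length < 1) abort("`alignment_length` must be >= 1")
  if ((survival$hr_high %||% 0.5) <= 0) abort("`hr_high` must be positive")
  if ((repertoire$exponent %||% 1) <= 0) abort("`exponent` must be positive")
  structure(list(
    n_patients = n_patients,
    n_alleles_per_locus = n_alleles_per_locus,
    alignment_length = alignment_length,
    allele_mutation_rate = allele_mutation_rate,
    homozygosity_prob = homozygosity_prob,
    mean_peptides = mean_peptides,
    survival = utils::modifyList(
      list(baseline_hazard = 0.04, hr_high = 0.5, censoring_rate = 0.2,
           haps_cutoff = NULL), survival),
    loh_prevalence = loh_prevalence,
    repertoire = utils::modifyList(
      list(n_clones = 150, exponent = 1.0, total_reads = 1e5), repertoire),
    response = utils::modifyList(
      list(intercept = -0.25, haps = 0.8, tmb = 0.5, tcr_diversity = 0.5),
      response),
    mode = mode,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Simulate an allele pool and cohort genotypes
#'
#' Builds a random consensus sequence per locus and derives each allele by
#' substituting residues at the configured rate, then draws two alleles per
#' locus per patient with the configured homozygosity probability.
#'
#' @param config A [cohort_config()].
#' @return List with `alleles` (tibble `allele`, `sequence`) and `genotypes`
#'   (tibble `patient_id`, `A1` .. `C2`).
#' @export
simulate_alleles <- function(config) {
  withr::with_seed(.stage_seed(config$seed, 1), {
    len <- config$alignment_length
    loci <- c("A", "B", "C")
    alleles <- purrr::map(loci, function(locus) {
      consensus <- sample(.AA20, len, replace = TRUE)
      purrr::map(seq_len(config$n_alleles_per_locus), function(i) {
        s <- consensus
        flip <- runif(len) < config$allele_mutation_rate
        s[flip] <- sample(.AA20, sum(flip), replace = TRUE)
        tibble(allele = sprintf("%s*%02d:01", locus, i),
               sequence = paste(s, collapse = ""))
      }) |> bind_rows()
    }) |> bind_rows()

    n <- config$n_patients
    pick_pairs <- function(locus) {
      pool <- alleles$allele[startsWith(alleles$allele, locus)]
      a1 <- sample(pool, n, replace = TRUE)
      a2 <- sample(pool, n, replace = TRUE)
      homo <- runif(n) < config$homozygosity_prob
      a2[homo] <- a1[homo]
      list(a1 = a1, a2 = a2)
    }
    pa <- pick_pairs("A"); pb <- pick_pairs("B"); pc <- pick_pairs("C")
    genotypes <- tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      A1 = pa$a1, A2 = pa$a2, B1 = pb$a1, B2 = pb$a2,
      C1 = pc$a1, C2 = pc$a2)
    list(alleles = alleles, genotypes = genotypes)
  })
}

#' Simulate MHC-I binding predictions
#'
#' Draws a Poisson number of candidate 9-mer mutant peptides per patient,
#' assigns each to one of the patient's alleles, and gives it a log-uniform
#' IC50 spanning the 500 nM call threshold plus a correlated percentile
#' rank.
#'
#' @param genotypes Genotype tibble.
#' @param config A [cohort_config()].
#' @return Tibble of binding records (`patient_id`, `peptide`, `allele`,
#'   `ic50_nm`, `rank_pct`).
#' @export
simulate_binding <- function(genotypes, config) {
  withr::with_seed(.stage_seed(config$seed, 2), {
    n <- nrow(genotypes)
    n_pep <- rpois(n, config$mean_peptides)
    total <- sum(n_pep)
    pat_idx <- rep.int(seq_len(n), n_pep)
    pep_mat <- matrix(sample(.AA20, 9 * total, replace = TRUE), ncol = 9)
    peptides <- do.call(paste0, as.data.frame(pep_mat))
    geno_mat <- as.matrix(genotypes[, c("A1", "A2", "B1", "B2", "C1", "C2")])
    slot <- sample.int(6, total, replace = TRUE)
    ic50 <- 10^runif(total, 1, 5)
    tibble(
      patient_id = genotypes$patient_id[pat_idx],
      peptide = peptides,
      allele = geno_mat[cbind(pat_idx, slot)],
      ic50_nm = ic50,
      rank_pct = pmin(100, (ic50 / 500) * exp(rnorm(total, 0, 0.3)))
    )
  })
}

#' Simulate survival driven by a score threshold
#'
#' Event times are exponential with the baseline hazard, multiplied by
#' `hr_high` for patients whose score is at or above the generative
#' threshold. With probability `censoring_rate` a patient is censored at an
#' independent uniform fraction of the event time.
#'
#' @param scores Named or plain numeric vector of per-patient scores.
#' @param patient_id Patient ids aligned with `scores`.
#' @param config A [cohort_config()]; uses the `survival` block. A `NULL`
#'   generative `haps_cutoff` defaults to the median score.
#' @return Tibble `patient_id`, `os_months`, `os_event`, plus mirrored
#'   `pfs_months`, `pfs_event`.
#' @export
simulate_survival <- function(scores, patient_id, config) {
  sv <- config$survival
  if (sv$hr_high <= 0) abort("`hr_high` must be positive")
  cutoff <- sv$haps_cutoff %||% median(scores)
  withr::with_seed(.stage_seed(config$seed, 3), {
    n <- length(scores)
    hazard <- sv$baseline_hazard * ifelse(scores >= cutoff, sv$hr_high, 1)
    t_event <- rexp(n, hazard)
    censored <- runif(n) < sv$censoring_rate
    obs <- ifelse(censored, t_event * runif(n), t_event)
    pfs_frac <- runif(n, 0.3, 1)
    tibble(
      patient_id = patient_id,
      os_months = obs,
      os_event = as.integer(!censored),
      pfs_months = obs * pfs_frac,
      pfs_event = as.integer(!censored)
    )
  })
}

#' Simulate a TCR repertoire
#'
#' Clone frequencies follow a power law in abundance rank with the given
#' exponent; counts are a multinomial draw of `total_reads`. CDR3s are
#' random 8-20mers framed by the canonical "CASS...F" motif.
#'
#' @param n_clones Number of clones (>= 1).
#' @param exponent Power-law exponent (> 0; larger = more clonal).
#' @param total_reads Total read count to distribute.
#' @param seed Integer seed.
#' @return Clone tibble (`cdr3_aa`, `count`), zero-count clones dropped.
#' @export
simulate_repertoire <- function(n_clones, exponent, total_reads = 1e5,
                                seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is required")
  if (n_clones < 1) abort("`n_clones` must be >= 1")
  if (exponent <= 0) abort("`exponent` must be positive")
  withr::with_seed(seed, {
    cdr3 <- character(0)
    while (length(cdr3) < n_clones) {
      fresh <- vapply(seq_len(n_clones - length(cdr3)), function(k) {
        core <- sample(.AA20, sample(3:15, 1), replace = TRUE)
        paste0("CASS", paste(core, collapse = ""), "F")
      }, character(1))
      cdr3 <- unique(c(cdr3, fresh))
    }
    p <- seq_len(n_clones)^(-exponent)
    counts <- as.vector(rmultinom(1, total_reads, p / sum(p)))
    out <- tibble(cdr3_aa = cdr3, count = counts)
    out[out$count > 0, , drop = FALSE]
  })
}

#' Simulate a complete cohort bundle
#'
#' Runs every sub-generator and ties them together: per-patient HAPS is
#' computed from the simulated alleles and binding calls with the package's
#' own scoring functions, survival is generated from that score, LOH calls
#' honor the configured prevalence, per-patient repertoires vary in
#' clonality, and response labels follow the configured logistic model on
#' standardized (HAPS, TMB, diversity).
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort_bundle`: `alleles`, `genotypes`,
#'   `binding`, `mutations`, `clinical`, `loh`, `clones`, `features`,
#'   `truth` (generative internals: `haps`, the generative survival cutoff,
#'   response probabilities) and `config`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must come from cohort_config()")
  }
  pool <- simulate_alleles(config)
  binding <- simulate_binding(pool$genotypes, config)

  divergence <- hla_divergence(pool$genotypes, pool$alleles)
  binders <- filter_binders(binding, mode = "ic50")
  burden <- tnb_per_locus(binders, pool$genotypes)
  haps <- compute_haps(divergence, burden)

  patient_id <- pool$genotypes$patient_id
  n <- length(patient_id)

  mutations <- withr::with_seed(.stage_seed(config$seed, 4), {
    region <- if (config$mode == "wes") 30 else 1.09
    per_mb <- pmax(0.5, burden$tnb_total * runif(n, 0.2, 0.6) +
                     rexp(n, 1 / 4))
    tibble(patient_id = patient_id,
           n_nonsynonymous = rpois(n, per_mb * region),
           region_size_mb = region)
  })

  clin <- simulate_survival(haps$haps, patient_id, config)
  gen_cutoff <- config$survival$haps_cutoff %||% median(haps$haps)

  loh <- withr::with_seed(.stage_seed(config$seed, 5), {
    is_loh_patient <- runif(n) < config$loh_prevalence
    lost <- ifelse(is_loh_patient, sample(c("A", "B", "C"), n,
                                          replace = TRUE), "")
    locus <- rep(c("A", "B", "C"), times = n)
    pat <- rep(patient_id, each = 3)
    hit <- locus == rep(lost, each = 3)
    m <- 3 * n
    tibble(
      patient_id = pat,
      locus = locus,
      minor_cn = ifelse(hit, runif(m, 0, 0.45), runif(m, 0.6, 1.3)),
      p_allelic_imbalance = ifelse(hit, runif(m, 0, 0.005),
                                   runif(m, 0.05, 1))
    )
  })

  rep_cfg <- config$repertoire
  clone_seeds <- vapply(seq_len(n), function(i)
    .stage_seed(config$seed, 100 + i), integer(1))
  exponents <- withr::with_seed(.stage_seed(config$seed, 6),
                                rep_cfg$exponent * runif(n, 0.5, 1.5))
  clones <- purrr::map(seq_len(n), function(i) {
    rep <- simulate_repertoire(rep_cfg$n_clones, exponents[i],
                               rep_cfg$total_reads, clone_seeds[i])
    rep$patient_id <- patient_id[i]
    rep$timepoint <- "baseline"
    rep
  }) |> bind_rows()

  # clones from the generator are already unique per patient, so Shannon
  # reduces to plain grouped arithmetic
  diversity <- clones |>
    group_by(.data$patient_id) |>
    summarise(tcr_diversity = {
      p <- .data$count / sum(.data$count)
      -sum(p * log(p))
    }, .groups = "drop")

  tmb_tbl <- tmb(mutations)
  features <- haps |>
    select("patient_id", "haps") |>
    left_join(tmb_tbl, by = "patient_id") |>
    left_join(diversity, by = "patient_id")

  z <- scale(as.matrix(features[, c("haps", "tmb", "tcr_diversity")]))
  beta <- config$response
  lin <- beta$intercept + z %*% c(beta$haps, beta$tmb, beta$tcr_diversity)
  pr <- stats::plogis(as.vector(lin))
  response <- withr::with_seed(.stage_seed(config$seed, 7),
                               ifelse(runif(n) < pr, "DCR", "PD"))
  features$response <- response
  clin$response <- response

  structure(list(
    alleles = pool$alleles,
    genotypes = pool$genotypes,
    binding = binding,
    mutations = mutations,
    clinical = clin,
    loh = loh,
    clones = clones,
    features = features,
    truth = list(haps = haps, survival_cutoff = gen_cutoff,
                 response_prob = pr),
    config = config
  ), class = "cohort_bundle")
}

#' Write a cohort bundle to disk
#'
#' Emits the FASTA alignment, the TSV tables and a `manifest.json` recording
#' the configuration, in the layout [run_haps_pipeline()] reads.
#'
#' @param bundle A `cohort_bundle` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  if (!inherits(bundle, "cohort_bundle")) {
    abort("`bundle` must come from simulate_cohort()")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_allele_fasta(bundle$alleles, file.path(dir, "alleles.fasta"))
  tables <- c("genotypes", "binding", "mutations", "clinical", "loh",
              "clones", "features")
  for (nm in tables) {
    readr::write_tsv(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     na = ".")
  }
  cfg <- unclass(bundle$config)
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
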