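#' Configuration for a synthetic prostate-cancer cohort
#'
#' Builds the parameter set for [generate_cohort()]. Defaults emulate a
#' radical-prostatectomy cohort profiled on SNP and expression arrays:
#' `K_true` latent molecular subtypes, each defined by recurrent copy-number
#' gains/losses hitting contiguous genomic regions; linear *cis* dosage
#' coupling of copy number to log2 expression for genes inside those regions;
#' additive batch effects; matched benign samples (diploid, no subtype
#' structure); and exponential time-to-biochemical-relapse with
#' subtype-specific hazards under administrative censoring.
#'
#' @param n_tumour,n_benign Sample counts. Defaults mirror a discovery cohort
#'   of 125 tumours with matched benign tissue.
#' @param n_genes Number of genes, spread evenly over the genome.
#' @param n_chromosomes,genome_length_per_chrom Genome layout; the default
#'   20 x 1.5e8 gives a 3e9-base genome, the denominator conventionally used
#'   for percent genome altered.
#' @param K_true Number of latent subtypes (>= 1).
#' @param cn_event_regions Tibble with columns `subtype`, `chrom`, `start`,
#'   `end`, `state` (0/1 loss, 3/4 gain), `penetrance`. `NULL` builds a
#'   default layout: each subtype gets one 30 Mb deletion (state 1) and one
#'   30 Mb gain (state 3) on its own pair of chromosomes.
#' @param penetrance Carrier probability used by the default region layout.
#' @param beta_dosage Log2 expression shift per copy-number unit for
#'   dosage-coupled (eQTL) genes.
#' @param sigma_noise Residual log2 expression SD.
#' @param n_batches,batch_shift Number of processing batches and the additive
#'   log2 shift applied per batch step (batch b is shifted by
#'   `batch_shift * (b - 1)`).
#' @param hazard_by_subtype Relapse hazards (events/month), recycled to
#'   `K_true`. Defaults span a ~3-fold good-to-poor prognosis range around a
#'   median time-to-relapse of roughly 100 months for the best group.
#' @param censor_time Administrative censoring time in months.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 intensity
#'   distribution (drawn once per gene).
#' @param prop_second_probe Fraction of genes carrying a second, attenuated
#'   probe (exercises probe collapse).
#' @param prop_imperfect Fraction of genes whose only probe is flagged
#'   non-perfect.
#' @param cohort Cohort label written to the clinical table.
#' @param seed Integer seed; all randomness in the generator flows from it.
#'
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_tumour = 125L,
                       n_benign = 125L,
                       n_genes = 2000L,
                       n_chromosomes = 20L,
                       genome_length_per_chrom = 1.5e8,
                       K_true = 5L,
                       cn_event_regions = NULL,
                       penetrance = 0.9,
                       beta_dosage = 1.5,
                       sigma_noise = 0.5,
                       n_batches = 2L,
                       batch_shift = 0.5,
                       hazard_by_subtype = c(0.020, 0.004, 0.025, 0.003, 0.008),
                       censor_time = 100,
                       baseline_mean = 8,
                       baseline_sd = 1,
                       prop_second_probe = 0.15,
                       prop_imperfect = 0.02,
                       cohort = "discovery",
                       seed = 1L) {
  if (is.null(cn_event_regions)) {
    cn_event_regions <- default_event_regions(
      K_true, n_chromosomes, genome_length_per_chrom, penetrance
    )
  }
  cn_event_regions <- as_tibble(cn_event_regions)
  hazard_by_subtype <- rep_len(hazard_by_subtype, K_true)
  cfg <- structure(
    list(
      n_tumour = as.integer(n_tumour), n_benign = as.integer(n_benign),
      n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
      genome_length_per_chrom = genome_length_per_chrom,
      K_true = as.integer(K_true), cn_event_regions = cn_event_regions,
      beta_dosage = beta_dosage, sigma_noise = sigma_noise,
      n_batches = as.integer(n_batches), batch_shift = batch_shift,
      hazard_by_subtype = hazard_by_subtype, censor_time = censor_time,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      prop_second_probe = prop_second_probe, prop_imperfect = prop_imperfect,
      cohort = cohort, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

default_event_regions <- function(K, n_chrom, chrom_len, penetrance) {
  len <- min(3e7, chrom_len)
  purrr::map(seq_len(K), function(k) {
    tibble(
      subtype = k,
      chrom = paste0("chr", (c(2L * k - 1L, 2L * k) - 1L) %% n_chrom + 1L),
      start = 0,
      end = len,
      state = c(1L, 3L),
      penetrance = penetrance
    )
  }) |> list_rbind()
}

validate_sim_config <- function(cfg) {
  reg <- cfg$cn_event_regions
  if (cfg$K_true < 1L) abort("K_true must be >= 1")
  if (any(cfg$hazard_by_subtype <= 0)) abort("all hazards must be > 0")
  if (nrow(reg)) {
    if (any(reg$penetrance < 0 | reg$penetrance > 1)) {
      abort("penetrance must lie in [0, 1]")
    }
    if (any(reg$start < 0 | reg$end > cfg$genome_length_per_chrom |
              reg$start >= reg$end)) {
      abort("event regions must lie within chromosome bounds with start < end")
    }
    if (!all(reg$state %in% c(0L, 1L, 3L, 4L))) {
      abort("event region states must be in {0, 1, 3, 4}")
    }
    # overlapping regions of conflicting state on the same subtype are
    # unrealisable in a single integer CN profile
    conflicts <- reg |>
      group_by(.data$subtype, .data$chrom) |>
      group_overlap_conflict()
    if (conflicts) {
      abort("overlapping event regions with conflicting CN state on the same subtype")
    }
  }
  invisible(cfg)
}

group_overlap_conflict <- function(grouped) {
  any(dplyr::group_map(grouped, function(g, key) {
    if (nrow(g) < 2L) return(FALSE)
    for (i in seq_len(nrow(g) - 1L)) {
      for (j in seq(i + 1L, nrow(g))) {
        overlaps <- g$start[i] < g$end[j] && g$start[j] < g$end[i]
        if (overlaps && g$state[i] != g$state[j]) return(TRUE)
      }
    }
    FALSE
  }) |> unlist())
}

#' Generate a synthetic cohort with recoverable ground truth
#'
#' Draws a full cohort under the generative model described in
#' [sim_config()]: subtype labels, per-sample copy-number segments (rank 1),
#' probe-level log2 expression with *cis* dosage effects and batch shifts,
#' gene annotation, a clinical table with censored time-to-relapse, and a
#' `truth` component holding the latent structure.
#'
#' Expression of gene g in sample s is
#' `baseline_g + beta_dosage * (CN_gs - 2) * [g is dosage-coupled] +
#'  batch_shift * (batch_s - 1) + N(0, sigma_noise^2)`.
#' Benign samples are diploid everywhere and carry no subtype effects.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort` with elements `segments`
#'   (tibble: sample, chrom, start, end, cn, rank; 0-based half-open),
#'   `expression` (list: `values` probe x sample log2 matrix, `features`
#'   tibble with `feature_id`, `gene_id`, `quality_flag`), `clinical`
#'   (tibble), `annotation` (tibble of gene loci), and `truth` (subtype per
#'   sample, dosage-coupled genes, true gene x sample CN states, region
#'   carrier draws, survival parameters).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

#' Generate a structureless null cohort
#'
#' As [generate_cohort()] but with a single subtype, no copy-number event
#' regions and a common relapse hazard: the correct negative control for
#' type-I-error and recurrence-filter calibration.
#'
#' @inheritParams generate_cohort
#' @export
generate_null_cohort <- function(config) {
  config$K_true <- 1L
  config$cn_event_regions <- config$cn_event_regions[0, , drop = FALSE]
  config$hazard_by_subtype <- rep(config$hazard_by_subtype[1], 1L)
  generate_cohort(config)
}

generate_cohort_impl <- function(cfg) {
  ann <- synthetic_annotation(cfg)
  tumour_ids <- sprintf("T%03d", seq_len(cfg$n_tumour))
  benign_ids <- sprintf("B%03d", seq_len(cfg$n_benign))
  samples <- c(tumour_ids, benign_ids)

  subtype <- sample(rep_len(seq_len(cfg$K_true), cfg$n_tumour))
  names(subtype) <- tumour_ids

  # copy number: Bernoulli(penetrance) carrier draws per subtype region
  reg <- cfg$cn_event_regions
  carriers <- tibble(sample = character(), region = integer(), carried = logical())
  seg_rows <- list()
  cn_true <- matrix(2L, nrow = nrow(ann), ncol = length(samples),
                    dimnames = list(ann$gene_id, samples))
  if (nrow(reg)) {
    for (i in seq_len(nrow(reg))) {
      members <- tumour_ids[subtype == reg$subtype[i]]
      hit <- rbinom(length(members), 1L, reg$penetrance[i]) == 1L
      carriers <- bind_rows(carriers, tibble(
        sample = members, region = i, carried = hit
      ))
      for (s in members[hit]) {
        seg_rows[[length(seg_rows) + 1L]] <- tibble(
          sample = s, chrom = reg$chrom[i],
          start = reg$start[i], end = reg$end[i],
          cn = reg$state[i], rank = 1L
        )
        # gene midpoint rule: genes centred inside the region take its state
        mid <- (ann$start + ann$end) / 2
        inside <- ann$chrom == reg$chrom[i] & mid >= reg$start[i] & mid < reg$end[i]
        cn_true[inside, s] <- reg$state[i]
      }
    }
  }
  segments <- if (length(seg_rows)) {
    list_rbind(seg_rows) |> merge_same_state_segments()
  } else {
    tibble(sample = character(), chrom = character(), start = numeric(),
           end = numeric(), cn = integer(), rank = integer())
  }

  # dosage-coupled genes: every gene inside any event region
  eqtl_genes <- character()
  if (nrow(reg)) {
    mid <- (ann$start + ann$end) / 2
    hit <- rep(FALSE, nrow(ann))
    for (i in seq_len(nrow(reg))) {
      hit <- hit | (ann$chrom == reg$chrom[i] & mid >= reg$start[i] & mid < reg$end[i])
    }
    eqtl_genes <- ann$gene_id[hit]
  }

  batch <- paste0("b", rep_len(seq_len(cfg$n_batches), length(samples)))
  names(batch) <- samples

  expr <- synthetic_expression(cfg, ann, cn_true, eqtl_genes, batch)
  clinical <- synthetic_clinical(cfg, tumour_ids, benign_ids, subtype, batch)

  structure(
    list(
      segments = segments,
      expression = expr,
      clinical = clinical,
      annotation = ann,
      truth = list(
        subtype_of_sample = tibble(sample = tumour_ids,
                                   subtype = unname(subtype[tumour_ids])),
        eqtl_genes = eqtl_genes,
        cn_state = cn_true,
        region_carriers = carriers,
        survival_params = tibble(subtype = seq_len(cfg$K_true),
                                 hazard = cfg$hazard_by_subtype)
      ),
      config = cfg
    ),
    class = "synthetic_cohort"
  )
}

synthetic_annotation <- function(cfg) {
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chromosomes)
  idx <- seq_len(cfg$n_genes) - 1L
  chrom_i <- idx %/% per_chrom + 1L
  pos_i <- idx %% per_chrom
  spacing <- cfg$genome_length_per_chrom / per_chrom
  start <- floor(pos_i * spacing)
  tibble(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    chrom = paste0("chr", chrom_i),
    start = start,
    end = pmin(start + 1e4, cfg$genome_length_per_chrom),
    strand = "+"
  )
}

merge_same_state_segments <- function(segs) {
  segs |>
    group_by(.data$sample, .data$chrom, .data$cn, .data$rank) |>
    arrange(.data$start, .by_group = TRUE) |>
    group_by(.data$sample, .data$chrom, .data$cn, .data$rank) |>
    dplyr::group_modify(function(g, key) {
      keep <- list()
      cur <- g[1, ]
      for (i in seq_len(nrow(g))[-1]) {
        if (g$start[i] <= cur$end) {
          cur$end <- max(cur$end, g$end[i])
        } else {
          keep[[length(keep) + 1L]] <- cur
          cur <- g[i, ]
        }
      }
      keep[[length(keep) + 1L]] <- cur
      list_rbind(keep)
    }) |>
    ungroup() |>
    select("sample", "chrom", "start", "end", "cn", "rank") |>
    arrange(.data$sample, .data$chrom, .data$start)
}

synthetic_expression <- function(cfg, ann, cn_true, eqtl_genes, batch) {
  baseline <- rnorm(nrow(ann), cfg$baseline_mean, cfg$baseline_sd)
  names(baseline) <- ann$gene_id
  samples <- colnames(cn_true)
  coupled <- ann$gene_id %in% eqtl_genes

  dosage <- cfg$beta_dosage * (cn_true - 2L) * coupled
  batch_eff <- cfg$batch_shift * (as.integer(sub("^b", "", batch[samples])) - 1L)
  signal <- baseline + sweep(dosage, 2L, batch_eff, "+")

  second <- runif(nrow(ann)) < cfg$prop_second_probe
  imperfect_only <- runif(nrow(ann)) < cfg$prop_imperfect

  p1 <- signal + matrix(rnorm(length(signal), 0, cfg$sigma_noise),
                        nrow = nrow(signal))
  feat <- tibble(
    feature_id = paste0(ann$gene_id, "_p1"),
    gene_id = ann$gene_id,
    quality_flag = ifelse(imperfect_only, "other", "perfect")
  )
  values <- p1
  rownames(values) <- feat$feature_id

  if (any(second)) {
    # second probe carries attenuated dosage signal: lower IQR, so probe
    # collapse should prefer the primary probe
    att <- sweep(baseline[second] + 0.3 * dosage[second, , drop = FALSE],
                 2L, batch_eff, "+")
    p2 <- att + matrix(rnorm(sum(second) * length(samples), 0, cfg$sigma_noise),
                       nrow = sum(second))
    rownames(p2) <- paste0(ann$gene_id[second], "_p2")
    feat2 <- tibble(
      feature_id = rownames(p2),
      gene_id = ann$gene_id[second],
      quality_flag = sample(c("perfect", "other"), sum(second),
                            replace = TRUE, prob = c(0.7, 0.3))
    )
    values <- rbind(values, p2)
    feat <- bind_rows(feat, feat2)
  }
  colnames(values) <- samples
  ord <- order(feat$feature_id)
  list(values = values[feat$feature_id[ord], , drop = FALSE],
       features = feat[ord, ])
}

synthetic_clinical <- function(cfg, tumour_ids, benign_ids, subtype, batch) {
  n_t <- length(tumour_ids)
  hz <- cfg$hazard_by_subtype[subtype[tumour_ids]]
  t_raw <- rexp(n_t, hz)
  event <- as.integer(t_raw <= cfg$censor_time)
  time <- pmin(t_raw, cfg$censor_time)
  gl1 <- sample(c(3L, 4L, 5L), n_t, replace = TRUE, prob = c(0.5, 0.4, 0.1))
  gl2 <- sample(c(3L, 4L, 5L), n_t, replace = TRUE, prob = c(0.5, 0.4, 0.1))
  tum <- tibble(
    sample = tumour_ids,
    tissue = "tumour",
    cohort = cfg$cohort,
    batch = unname(batch[tumour_ids]),
    cellularity_pct = round(runif(n_t, 20, 90)),
    psa = round(rlnorm(n_t, log(8), 0.6), 1),
    gleason_primary = gl1,
    gleason_secondary = gl2,
    stage = sample(c("T2", "T3"), n_t, replace = TRUE, prob = c(0.6, 0.4)),
    ece = as.integer(runif(n_t) < 0.3),
    psm = as.integer(runif(n_t) < 0.25),
    time_to_bcr = time,
    bcr_event = event
  )
  ben <- tibble(
    sample = benign_ids,
    tissue = "benign",
    cohort = cfg$cohort,
    batch = unname(batch[benign_ids]),
    cellularity_pct = 0,
    psa = NA_real_, gleason_primary = NA_integer_,
    gleason_secondary = NA_integer_, stage = NA_character_,
    ece = NA_integer_, psm = NA_integer_,
    time_to_bcr = NA_real_, bcr_event = NA_integer_
  )
  bind_rows(tum, ben)
}

#' Write all cohort components to a directory of plain-text files
#'
#' Emits the same SEG/TSV/BED/clinical formats the readers in this package
#' accept, plus the ground truth as a sidecar TSV.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_seg(cohort$segments, file.path(dir, "segments.seg"))
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_bed(cohort$annotation, file.path(dir, "genes.bed"))
  readr::write_tsv(cohort$truth$subtype_of_sample, file.path(dir, "truth_subtypes.tsv"))
  invisible(dir)
}
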