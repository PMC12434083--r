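#' Configuration for the synthetic pull-down simulator
#'
#' Describes a synthetic triple-sample experiment: background proteins
#' centered on L/H = 1 in every sample type, a bait and its interactors
#' enriched only in `BAIT_WT` (and absent from `WT_WT`, where the untagged
#' strain yields no purified bait), nonspecific binders at ratio 1
#' everywhere, and control decoys enriched in a designated control sample
#' as well as in `BAIT_WT` (the biotinylated-contaminant pattern that the
#' control-based exclusion logic exists to catch). Observed peptide log2
#' L/H ratios are the protein's true log2 fold plus a per-run mixing error
#' (log-normal, emulating imperfect 1:1 pellet mixing) plus log-normal
#' peptide noise; ions go missing independently and a small fraction draws
#' a failing q-value.
#'
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical outputs.
#' @param n_background_proteins Number of background proteins.
#' @param n_replicates Biological replicates per sample type (default 4).
#' @param conditions,fa_levels Design cells to emulate.
#' @param bait `list(accession =, true_fold =)` for the bait (default fold
#'   256, the order of magnitude a well-enriched bait reaches), or `NULL`
#'   for a bait-free (null) dataset.
#' @param interactors Tibble/data.frame with `accession` and `true_fold`,
#'   plus an optional `condition` column restricting the enrichment to one
#'   condition (`NA` or absent = enriched in every condition), which is how
#'   stress-specific interactors are emulated.
#' @param nonspecific_binders Character vector of accessions detected at
#'   fold 1 in every sample type.
#' @param control_decoys Tibble with `accession`, `control` (`"WT_WT"` or
#'   `"BAIT_BAIT"`) and `true_fold`.
#' @param peptide_count_range,peptide_length_range Integer ranges for the
#'   number and length of peptides per protein.
#' @param protein_length_range Clamp for emitted protein lengths.
#' @param coverage_fraction_range Range of the fraction of each protein
#'   sequence covered by its peptides (drives the sequence-coverage filter).
#' @param peptide_noise_sd SD of log2 peptide noise (default 0.3).
#' @param replicate_mix_error_sd SD of the per-run log2 mixing error
#'   (default 0.2).
#' @param missing_rate Probability an ion is unobserved in a run.
#' @param q_fail_rate Fraction of ions drawing a q-value above the cutoff.
#' @param q_value_max The q cutoff the q-value model is built around.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_background_proteins = 100,
                       n_replicates = 4,
                       conditions = "control",
                       fa_levels = "fa_0.2",
                       bait = list(accession = "BAIT_TS", true_fold = 256),
                       interactors = tibble::tibble(
                         accession = c("INT_A", "INT_B", "INT_C", "INT_D"),
                         true_fold = c(40, 20, 5, 2.5)
                       ),
                       nonspecific_binders = "NSB_PYCA_LIKE",
                       control_decoys = tibble::tibble(
                         accession = character(), control = character(),
                         true_fold = numeric()
                       ),
                       peptide_count_range = c(6, 12),
                       peptide_length_range = c(8, 18),
                       protein_length_range = c(120, 800),
                       coverage_fraction_range = c(0.55, 0.75),
                       peptide_noise_sd = 0.3,
                       replicate_mix_error_sd = 0.2,
                       missing_rate = 0.05,
                       q_fail_rate = 0.02,
                       q_value_max = 0.01) {
  interactors <- tibble::as_tibble(interactors)
  if (!"condition" %in% names(interactors)) {
    interactors$condition <- rep(NA_character_, nrow(interactors))
  }
  control_decoys <- tibble::as_tibble(control_decoys)
  stopifnot(n_background_proteins >= 0, n_replicates >= 1,
            missing_rate >= 0, missing_rate <= 1,
            q_fail_rate >= 0, q_fail_rate <= 1,
            peptide_noise_sd >= 0, replicate_mix_error_sd >= 0)
  if (!is.null(bait)) stopifnot(bait$true_fold > 0)
  if (nrow(interactors) > 0) stopifnot(all(interactors$true_fold > 0))
  if (nrow(control_decoys) > 0) {
    stopifnot(all(control_decoys$control %in% c("WT_WT", "BAIT_BAIT")),
              all(control_decoys$true_fold > 0))
  }
  cfg <- list(seed = as.integer(seed),
              n_background_proteins = n_background_proteins,
              n_replicates = n_replicates,
              conditions = conditions, fa_levels = fa_levels,
              bait = bait, interactors = interactors,
              nonspecific_binders = nonspecific_binders,
              control_decoys = control_decoys,
              peptide_count_range = peptide_count_range,
              peptide_length_range = peptide_length_range,
              protein_length_range = protein_length_range,
              coverage_fraction_range = coverage_fraction_range,
              peptide_noise_sd = peptide_noise_sd,
              replicate_mix_error_sd = replicate_mix_error_sd,
              missing_rate = missing_rate,
              q_fail_rate = q_fail_rate,
              q_value_max = q_value_max)
  special <- c(if (!is.null(bait)) bait$accession, interactors$accession,
               nonspecific_binders, control_decoys$accession)
  if (anyDuplicated(special)) {
    stop("config error: duplicated special accessions", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Deterministic 31-bit stream seed from (seed, sample_id), so adding runs
# never perturbs existing ones.
run_stream_seed <- function(seed, sample_id) {
  h <- 0
  for (c in utf8ToInt(sample_id)) h <- (h * 31 + c) %% 2147483647
  as.integer((seed * 2654435 + h) %% 2147483647)
}

random_peptide <- function(len, taken) {
  repeat {
    pep <- paste(sample(AA_LETTERS, len, replace = TRUE), collapse = "")
    if (!pep %in% taken) return(pep)
  }
}

#' Simulate a triple-sample pull-down experiment with ground truth
#'
#' Emits a peptide-level report, a FASTA protein database in which every
#' simulated peptide is embedded as a true substring at a recorded
#' position, the sample sheet, and the ground truth (per-protein true log2
#' folds, per-run mixing errors, peptide positions).
#'
#' @param config A [sim_config()].
#' @return A list of class `isopull_sim` with elements `report`,
#'   `proteins` (database tibble as from [read_fasta()]), `sample_sheet`,
#'   `truth` (list of `proteins`, `runs`, `peptides` tibbles) and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  roles <- dplyr::bind_rows(
    if (config$n_background_proteins > 0) {
      tibble::tibble(
        protein_id = sprintf("BG%04d", seq_len(config$n_background_proteins)),
        role = "background", true_fold = 1
      )
    },
    if (!is.null(config$bait)) {
      tibble::tibble(protein_id = config$bait$accession, role = "bait",
                     true_fold = config$bait$true_fold)
    },
    if (nrow(config$interactors) > 0) {
      tibble::tibble(protein_id = config$interactors$accession,
                     role = "interactor",
                     true_fold = config$interactors$true_fold,
                     cond_spec = config$interactors$condition)
    },
    if (length(config$nonspecific_binders) > 0) {
      tibble::tibble(protein_id = config$nonspecific_binders,
                     role = "nonspecific", true_fold = 1)
    },
    if (nrow(config$control_decoys) > 0) {
      tibble::tibble(protein_id = config$control_decoys$accession,
                     role = paste0("decoy_", tolower(
                       sub("^(WT)_WT$", "wt",
                           sub("^BAIT_BAIT$", "bait",
                               config$control_decoys$control)))),
                     true_fold = config$control_decoys$true_fold)
    }
  )
  if (anyDuplicated(roles$protein_id)) {
    stop("config error: special accession collides with background accession",
         call. = FALSE)
  }

  # --- structure: sequences, peptides, positions (base-seed stream) ---
  set.seed(config$seed)
  taken <- character(0)
  prot_rows <- vector("list", nrow(roles))
  pep_rows <- vector("list", nrow(roles))
  for (i in seq_len(nrow(roles))) {
    n_pep <- sample(config$peptide_count_range[1]:config$peptide_count_range[2], 1)
    lens <- sample(config$peptide_length_range[1]:config$peptide_length_range[2],
                   n_pep, replace = TRUE)
    peps <- character(n_pep)
    for (j in seq_len(n_pep)) {
      peps[j] <- random_peptide(lens[j], taken)
      taken <- c(taken, peps[j])
    }
    total_pep <- sum(lens)
    frac <- stats::runif(1, config$coverage_fraction_range[1],
                         config$coverage_fraction_range[2])
    L <- round(total_pep / frac)
    L <- min(max(L, config$protein_length_range[1]),
             config$protein_length_range[2])
    L <- max(L, total_pep) # linkers may vanish but peptides always fit
    linker_total <- L - total_pep
    shares <- as.vector(stats::rmultinom(1, linker_total,
                                         rep(1, n_pep + 1)))
    segs <- character(2 * n_pep + 1)
    starts <- integer(n_pep)
    pos <- 1
    for (j in seq_len(n_pep)) {
      link <- if (shares[j] > 0) {
        paste(sample(AA_LETTERS, shares[j], replace = TRUE), collapse = "")
      } else ""
      segs[2 * j - 1] <- link
      pos <- pos + shares[j]
      starts[j] <- pos
      segs[2 * j] <- peps[j]
      pos <- pos + lens[j]
    }
    segs[2 * n_pep + 1] <- if (shares[n_pep + 1] > 0) {
      paste(sample(AA_LETTERS, shares[n_pep + 1], replace = TRUE),
            collapse = "")
    } else ""
    seqc <- paste(segs, collapse = "")
    prot_rows[[i]] <- tibble::tibble(
      protein_id = roles$protein_id[i],
      description = paste("synthetic", roles$role[i], "protein"),
      sequence = seqc, length = nchar(seqc)
    )
    pep_rows[[i]] <- tibble::tibble(protein_id = roles$protein_id[i],
                                    peptide_seq = peps, start = starts,
                                    end = starts + lens - 1L)
  }
  proteins <- dplyr::bind_rows(prot_rows)
  peptides <- dplyr::bind_rows(pep_rows)

  # --- truth: per (protein, sample_type, condition) true log2 fold ---
  if (!"cond_spec" %in% names(roles)) roles$cond_spec <- NA_character_
  decoy_ctrl <- stats::setNames(
    as.list(config$control_decoys$control), config$control_decoys$accession)
  truth_proteins <- tidyr::expand_grid(
    roles, sample_type = SAMPLE_TYPES, condition = config$conditions
  ) |>
    dplyr::mutate(
      present = dplyr::case_when(
        .data$role %in% c("bait", "interactor") &
          .data$sample_type == "WT_WT" ~ FALSE,
        TRUE ~ TRUE
      ),
      cond_hit = is.na(.data$cond_spec) | .data$condition == .data$cond_spec,
      true_log2_fold = dplyr::case_when(
        .data$role %in% c("bait", "interactor") & .data$cond_hit &
          .data$sample_type == "BAIT_WT" ~ log2(.data$true_fold),
        startsWith(.data$role, "decoy") &
          (.data$sample_type == "BAIT_WT" |
             .data$sample_type == vapply(
               .data$protein_id, function(p) {
                 if (p %in% names(decoy_ctrl)) decoy_ctrl[[p]] else ""
               }, character(1))) ~ log2(.data$true_fold),
        TRUE ~ 0
      )
    ) |>
    dplyr::select("protein_id", "role", "sample_type", "condition",
                  "present", "true_log2_fold")

  sheet <- enumerate_samples(config$conditions, config$fa_levels,
                             config$n_replicates,
                             wt_label = "WT", bait_label = "BaitStrain")

  cell_keys <- tidyr::expand_grid(sample_type = SAMPLE_TYPES,
                                  condition = config$conditions)
  ions_by_cell <- lapply(seq_len(nrow(cell_keys)), function(k) {
    tp <- truth_proteins |>
      dplyr::filter(.data$sample_type == cell_keys$sample_type[k],
                    .data$condition == cell_keys$condition[k],
                    .data$present)
    peptides |>
      dplyr::inner_join(dplyr::select(tp, "protein_id", "true_log2_fold"),
                        by = "protein_id")
  })
  names(ions_by_cell) <- paste(cell_keys$sample_type, cell_keys$condition)

  # --- observations: one RNG stream per run ---
  report <- vector("list", nrow(sheet))
  run_truth <- vector("list", nrow(sheet))
  for (r in seq_len(nrow(sheet))) {
    ions <- ions_by_cell[[paste(sheet$sample_type[r], sheet$condition[r])]]
    n <- nrow(ions)
    set.seed(run_stream_seed(config$seed, sheet$sample_id[r]))
    mix <- stats::rnorm(1, 0, config$replicate_mix_error_sd)
    miss <- stats::runif(n)
    eps <- stats::rnorm(n, 0, config$peptide_noise_sd)
    qf <- stats::runif(n)
    q_lo <- stats::runif(n, 0, config$q_value_max * 0.9)
    q_hi <- stats::runif(n, config$q_value_max * 1.5, 1)
    obs_log2 <- ions$true_log2_fold + mix + eps
    keep <- miss >= config$missing_rate
    report[[r]] <- tibble::tibble(
      sample_id = sheet$sample_id[r],
      protein_id = ions$protein_id[keep],
      peptide_seq = ions$peptide_seq[keep],
      ratio_hl = 2^(-obs_log2[keep]),
      q_value = ifelse(qf[keep] < config$q_fail_rate, q_hi[keep], q_lo[keep])
    )
    run_truth[[r]] <- tibble::tibble(sample_id = sheet$sample_id[r],
                                     mix_error_log2 = mix,
                                     mix_factor = 2^mix)
  }

  structure(
    list(report = dplyr::bind_rows(report),
         proteins = proteins,
         sample_sheet = sheet,
         truth = list(proteins = truth_proteins,
                      runs = dplyr::bind_rows(run_truth),
                      peptides = peptides),
         config = config),
    class = "isopull_sim"
  )
}

#' Write a simulated experiment to disk
#'
#' Emits the same dialects the readers consume: `report.tsv`,
#' `proteins.fasta`, `sample_sheet.tsv`, the truth tables as TSV and a JSON
#' sidecar with the configuration.
#'
#' @param sim An `isopull_sim` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "isopull_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(sim$report, file.path(dir, "report.tsv"))
  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  write_sample_sheet(sim$sample_sheet, file.path(dir, "sample_sheet.tsv"))
  readr::write_tsv(sim$truth$proteins, file.path(dir, "truth_proteins.tsv"))
  readr::write_tsv(sim$truth$runs, file.path(dir, "truth_runs.tsv"))
  readr::write_tsv(sim$truth$peptides, file.path(dir, "truth_peptides.tsv"))
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Canonical fixture datasets
#'
#' Builds four small canonical simulations used throughout the test suite:
#' \describe{
#'   \item{smoke}{10 background proteins + bait + two interactors, fully
#'     noiseless - the pipeline must recover every fold exactly.}
#'   \item{null}{background only, default noise - no candidates expected.}
#'   \item{tiers}{bait + interactors at folds 40/20/5/2.5, echoing the
#'     magnitude spectrum from strong polymerase-core partners down to
#'     weak transient ones.}
#'   \item{decoys}{low-noise dataset with one planted decoy per control
#'     sample type for the classifier's exclusion logic.}
#' }
#'
#' @param out_dir If non-`NULL`, each fixture is also written under
#'   `out_dir/<name>/` via [write_simulation()].
#' @param seed Base seed.
#' @return Named list of `isopull_sim` objects.
#' @export
make_fixture_suite <- function(out_dir = NULL, seed = 42) {
  fixtures <- list(
    smoke = simulate_experiment(sim_config(
      seed = seed, n_background_proteins = 10,
      interactors = tibble::tibble(accession = c("INT_A", "INT_B"),
                                   true_fold = c(8, 4)),
      peptide_noise_sd = 0, replicate_mix_error_sd = 0,
      missing_rate = 0, q_fail_rate = 0
    )),
    null = simulate_experiment(sim_config(
      seed = seed + 1, n_background_proteins = 200, bait = NULL,
      interactors = tibble::tibble(accession = character(),
                                   true_fold = numeric()),
      nonspecific_binders = character(0)
    )),
    tiers = simulate_experiment(sim_config(
      seed = seed + 2, n_background_proteins = 100
    )),
    decoys = simulate_experiment(sim_config(
      seed = seed + 3, n_background_proteins = 50,
      control_decoys = tibble::tibble(
        accession = c("DEC_WT", "DEC_BB"),
        control = c("WT_WT", "BAIT_BAIT"),
        true_fold = c(4, 4)
      ),
      peptide_noise_sd = 0.05, replicate_mix_error_sd = 0.02,
      missing_rate = 0, q_fail_rate = 0
    ))
  )
  if (!is.null(out_dir)) {
    for (nm in names(fixtures)) {
      write_simulation(fixtures[[nm]], file.path(out_dir, nm))
    }
  }
  fixtures
}
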