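# Study configuration for the synthetic-community generator.

#' Default planted group effects
#'
#' Twenty-one species-level effects (2 enrichments, 19 depletions) whose
#' log10 case/control fold changes span 0.45 to -1.77, the observed range in
#' the dysbiosis cohort this pipeline emulates.  Six of the planted species
#' are "novel": excluded from the reference database so their reads fail the
#' 96% mapping threshold and surface as de-novo OTUs.
#'
#' @return data.frame with columns `log10_fc` and `novel`.
#' @export
default_planted_effects <- function() {
  fc <- c(0.45, 0.44, -0.23, -0.36, -0.43, -0.46, -0.5, -0.63, -0.66,
          -0.82, -0.82, -0.83, -0.86, -0.92, -1.07, -1.08, -1.11, -1.11,
          -1.15, -1.43, -1.77)
  novel <- rep(FALSE, length(fc))
  novel[c(6, 8, 14, 16, 18, 19)] <- TRUE
  data.frame(log10_fc = fc, novel = novel)
}

#' Synthetic study configuration
#'
#' Bundles every tunable of the synthetic-data generator.  The defaults are
#' the study conditions the pipeline is designed around: 20 case (MS) and 40
#' control (HC) cross-sectional samples, 18 longitudinal control subjects
#' sampled at 9 timepoints, a fixed profiling depth of 3,000 reads per sample
#' drawn from raw yields of roughly 7,080 +/- 825 (case) and 7,590 +/- 616
#' (control) reads, a per-base substitution error rate of 0.5%, and 21
#' planted differential species.
#'
#' @param seed integer master seed; every random stage derives its substream
#'   from it, so a fixed seed gives byte-identical outputs.
#' @param n_ref_species number of species present in the reference database.
#' @param n_novel_species community species deliberately absent from the
#'   reference database (sources of de-novo OTUs).
#' @param n_community_species total species with non-zero abundance
#'   (includes the novel ones).
#' @param defect_counts named integer vector `short`, `ambiguous`,
#'   `eukaryote`: defective records planted in the raw reference collection.
#' @param redundancy integer vector of per-species copy numbers sampled for
#'   reference redundancy (copies are >= 99.8% identical).
#' @param n_case_samples,n_control_samples cross-sectional group sizes.
#' @param n_longitudinal_subjects,n_timepoints longitudinal design.
#' @param reads_per_sample profiling depth after subsampling (>= 3000).
#' @param raw_read_mean,raw_read_sd named numeric vectors (`case`,
#'   `control`): negative-binomial raw read yield per sample.
#' @param planted_effects data.frame with columns `log10_fc`, `novel`.
#' @param error_rate per-base substitution probability of the simulated
#'   sequencer.
#' @param quality_profile named numeric vector `mean`, `sd_between`,
#'   `sd_within`: Phred quality model (per-read mean, per-base scatter).
#' @param sample_conc,subject_conc,timepoint_conc Dirichlet concentration
#'   parameters for sample-, subject- and timepoint-level compositional
#'   variability.
#' @param core_len,tail_len,head_len lengths of the variable V1-V2 core, the
#'   conserved 3' tail and the 5' head of the synthetic full-length gene.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_ref_species = 150L,
                       n_novel_species = 10L,
                       n_community_species = 134L,
                       defect_counts = c(short = 6L, ambiguous = 4L, eukaryote = 2L),
                       redundancy = 1:3,
                       n_case_samples = 20L,
                       n_control_samples = 40L,
                       n_longitudinal_subjects = 18L,
                       n_timepoints = 9L,
                       reads_per_sample = 3000L,
                       raw_read_mean = c(case = 7080, control = 7590),
                       raw_read_sd = c(case = 825, control = 616),
                       planted_effects = default_planted_effects(),
                       error_rate = 0.005,
                       quality_profile = c(mean = 32, sd_between = 4, sd_within = 3),
                       sample_conc = 150,
                       subject_conc = 150,
                       timepoint_conc = 500,
                       core_len = 310L,
                       tail_len = 1120L,
                       head_len = 30L) {
  cfg <- list(seed = as.integer(seed), n_ref_species = as.integer(n_ref_species),
              n_novel_species = as.integer(n_novel_species),
              n_community_species = as.integer(n_community_species),
              defect_counts = defect_counts, redundancy = redundancy,
              n_case_samples = as.integer(n_case_samples),
              n_control_samples = as.integer(n_control_samples),
              n_longitudinal_subjects = as.integer(n_longitudinal_subjects),
              n_timepoints = as.integer(n_timepoints),
              reads_per_sample = as.integer(reads_per_sample),
              raw_read_mean = raw_read_mean, raw_read_sd = raw_read_sd,
              planted_effects = planted_effects, error_rate = error_rate,
              quality_profile = quality_profile, sample_conc = sample_conc,
              subject_conc = subject_conc, timepoint_conc = timepoint_conc,
              core_len = as.integer(core_len), tail_len = as.integer(tail_len),
              head_len = as.integer(head_len))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$reads_per_sample < 3000L)
    stop("reads_per_sample must be >= 3000")
  if (any(cfg$defect_counts < 0))
    stop("defect counts must be non-negative")
  if (!all(c("short", "ambiguous", "eukaryote") %in% names(cfg$defect_counts)))
    stop("defect_counts must name short, ambiguous and eukaryote")
  pe <- cfg$planted_effects
  if (!is.null(pe) && nrow(pe) > 0) {
    if (!all(c("log10_fc", "novel") %in% names(pe)))
      stop("planted_effects needs columns log10_fc and novel")
    if (sum(pe$novel) > cfg$n_novel_species)
      stop("more novel planted effects than novel species")
    if (nrow(pe) > cfg$n_community_species)
      stop("more planted effects than community species")
  }
  if (cfg$n_community_species - cfg$n_novel_species > cfg$n_ref_species)
    stop("community needs more database species than n_ref_species provides")
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) stop("error_rate outside [0,1)")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic 16S study configuration\n")
  cat(sprintf("  seed %d; %d DB species (+%d novel), community %d species\n",
              x$seed, x$n_ref_species, x$n_novel_species, x$n_community_species))
  cat(sprintf("  samples: %d case + %d control; longitudinal %d x %d\n",
              x$n_case_samples, x$n_control_samples,
              x$n_longitudinal_subjects, x$n_timepoints))
  cat(sprintf("  depth %d reads/sample, error rate %.3f, %d planted effects\n",
              x$reads_per_sample, x$error_rate,
              if (is.null(x$planted_effects)) 0L else nrow(x$planted_effects)))
  invisible(x)
}
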