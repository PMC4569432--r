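# Synthetic amplicon read sets: per-sample compositions drawn around the
# group expectations, raw read yields drawn from the study's negative
# binomial, reads as primer-bracketed V1-V2 amplicons with substitution
# noise and Phred-like qualities.

#' Study sample sheet
#'
#' Cross-sectional case/control samples plus the longitudinal control
#' series (one sample per subject and timepoint).
#'
#' @param config a [sim_config()].
#' @param longitudinal include the longitudinal series.
#' @return data.frame with `sample_id`, `subject_id`, `group`
#'   (`MS`/`HC`/`HC_long`), `timepoint` (NA for cross-sectional).
#' @export
sample_sheet <- function(config, longitudinal = TRUE) {
  cs <- data.frame(
    sample_id = c(sprintf("MS_%02d", seq_len(config$n_case_samples)),
                  sprintf("HC_%02d", seq_len(config$n_control_samples))),
    subject_id = c(sprintf("subjMS_%02d", seq_len(config$n_case_samples)),
                   sprintf("subjHC_%02d", seq_len(config$n_control_samples))),
    group = c(rep("MS", config$n_case_samples),
              rep("HC", config$n_control_samples)),
    timepoint = NA_integer_, stringsAsFactors = FALSE)
  if (!longitudinal) return(cs)
  lg <- expand.grid(subject = seq_len(config$n_longitudinal_subjects),
                    timepoint = seq_len(config$n_timepoints))
  lg <- lg[order(lg$subject, lg$timepoint), ]
  long <- data.frame(
    sample_id = sprintf("L%02d_t%d", lg$subject, lg$timepoint),
    subject_id = sprintf("subjL_%02d", lg$subject),
    group = "HC_long", timepoint = lg$timepoint, stringsAsFactors = FALSE)
  rbind(cs, long)
}

# subject-level baseline compositions for the longitudinal series
longitudinal_baselines <- function(config, truth) {
  set.seed(derive_seed(config$seed, "subjects"))
  base <- stats::setNames(truth$composition$control, truth$composition$species)
  out <- lapply(seq_len(config$n_longitudinal_subjects), function(i)
    rdirichlet1(config$subject_conc * base))
  names(out) <- sprintf("subjL_%02d", seq_len(config$n_longitudinal_subjects))
  out
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8), rate = 1)
  stats::setNames(x / sum(x), names(alpha))
}

#' Generate the raw reads of one sample
#'
#' The per-sample substream is derived from the master seed and the sample
#' id, so a single sample is reproducible in isolation.
#'
#' @param config a [sim_config()].
#' @param truth backbone truth.
#' @param sample_id sample identifier (also the substream tag).
#' @param props expected species proportions for this sample's population
#'   (group mean or subject baseline); the realised composition is a
#'   Dirichlet draw around it with concentration `conc`.
#' @param conc Dirichlet concentration (defaults to `config$sample_conc`).
#' @param n_raw raw read count; drawn from the configured negative binomial
#'   for `group` when NULL.
#' @param group `"case"` or `"control"` (sets the raw-yield distribution).
#' @return data.frame `id`, `sequence`, `quality`, `species` (true source).
#' @export
generate_sample_reads <- function(config, truth, sample_id, props,
                                  conc = config$sample_conc,
                                  n_raw = NULL, group = "control") {
  seed_s <- derive_seed(config$seed, sample_id)
  set.seed(seed_s)
  if (is.null(n_raw)) {
    mu <- config$raw_read_mean[[group]]
    sdv <- config$raw_read_sd[[group]]
    size <- mu^2 / max(sdv^2 - mu, 1)
    n_raw <- max(config$reads_per_sample,
                 stats::rnbinom(1, mu = mu, size = size))
  }
  p <- rdirichlet1(conc * props)
  sp <- sample(names(p), n_raw, replace = TRUE, prob = p)
  templates <- unname(truth$amplicons[sp])
  seqs <- cpp_mutate_seqs(templates, config$error_rate,
                          derive_seed(seed_s, "err"))
  qp <- config$quality_profile
  quals <- cpp_quality_strings(nchar(seqs), qp[["mean"]], qp[["sd_between"]],
                               qp[["sd_within"]], derive_seed(seed_s, "qual"))
  data.frame(id = sprintf("%s_r%06d", sample_id, seq_len(n_raw)),
             sequence = seqs, quality = quals, species = sp,
             stringsAsFactors = FALSE)
}

#' Generate every sample of the study
#'
#' @param config a [sim_config()].
#' @param truth backbone truth; generated when omitted.
#' @param longitudinal include the longitudinal series.
#' @param callback optional `function(sample_id, reads)`; when given, reads
#'   are passed to it one sample at a time and not accumulated (keeps memory
#'   flat for full-scale runs).
#' @return list with `sheet` and (when no callback) `samples`, a named list
#'   of read data.frames.
#' @export
generate_samples <- function(config, truth = NULL, longitudinal = TRUE,
                             callback = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- simulate_species_backbone(config)
  sheet <- sample_sheet(config, longitudinal)
  comp <- truth$composition
  ctrl <- stats::setNames(comp$control, comp$species)
  case <- stats::setNames(comp$case, comp$species)
  baselines <- if (longitudinal) longitudinal_baselines(config, truth) else NULL
  samples <- if (is.null(callback)) vector("list", nrow(sheet)) else NULL
  for (i in seq_len(nrow(sheet))) {
    row <- sheet[i, ]
    if (row$group == "MS") {
      reads <- generate_sample_reads(config, truth, row$sample_id, case,
                                     group = "case")
    } else if (row$group == "HC") {
      reads <- generate_sample_reads(config, truth, row$sample_id, ctrl,
                                     group = "control")
    } else {
      reads <- generate_sample_reads(config, truth, row$sample_id,
                                     baselines[[row$subject_id]],
                                     conc = config$timepoint_conc,
                                     group = "control")
    }
    if (is.null(callback)) {
      samples[[i]] <- reads
    } else {
      callback(row$sample_id, reads)
    }
  }
  if (is.null(callback)) {
    names(samples) <- sheet$sample_id
    list(sheet = sheet, samples = samples)
  } else {
    list(sheet = sheet)
  }
}

#' Write a sample's reads as FASTQ and the study sheet as TSV
#'
#' @param out_dir output directory.
#' @param config,truth as in [generate_samples()].
#' @param longitudinal include the longitudinal series.
#' @param gzip compress the FASTQ files.
#' @return invisibly, the sheet with a `fastq` path column.
#' @export
write_study_fastq <- function(out_dir, config, truth = NULL,
                              longitudinal = FALSE, gzip = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  res <- generate_samples(config, truth, longitudinal,
                          callback = function(sid, reads) {
                            write_fastq(reads, file.path(out_dir,
                                                         paste0(sid, ext)))
                          })
  sheet <- res$sheet
  sheet$fastq <- file.path(out_dir, paste0(sheet$sample_id, ext))
  write.table(sheet, file.path(out_dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(sheet)
}
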