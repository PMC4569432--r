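# Alpha diversity from de-novo clustering of each sample's fixed-depth read
# set: observed OTUs at 96% identity, bias-corrected Chao1 richness, and the
# Shannon index in nats.

#' Observed OTUs of one sample
#'
#' Greedily clusters the sample's reads at the given identity threshold and
#' returns the OTU count and size spectrum.  The depth is a contract: all
#' samples must be clustered at the same fixed depth for their OTU counts to
#' be comparable, so a deviating read count is an error rather than a
#' warning.
#'
#' @param reads data.frame of trimmed reads (`id`, `sequence`).
#' @param threshold clustering identity (default 0.96).
#' @param depth required read count (default 3000).
#' @param band alignment band half-width for read-vs-read comparisons.
#' @return list with `observed` (OTU count) and `spectrum` (named integer
#'   vector of OTU sizes).
#' @export
observed_otus <- function(reads, threshold = 0.96, depth = 3000L,
                          band = 24L) {
  if (nrow(reads) != depth)
    stop(sprintf("expected exactly %d reads, got %d (rarefied depths only)",
                 depth, nrow(reads)))
  cl <- greedy_cluster(stats::setNames(reads$sequence, reads$id), threshold,
                       band = band)
  spectrum <- table(cl$cluster)
  list(observed = length(spectrum),
       spectrum = stats::setNames(as.integer(spectrum), names(spectrum)))
}

#' Bias-corrected Chao1 richness
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with F1 singletons and F2
#' doubletons; the bias-corrected form is defined when no doubletons exist.
#'
#' @param spectrum integer vector of OTU sizes.
#' @return Chao1 estimate (>= observed richness).
#' @export
chao1 <- function(spectrum) {
  spectrum <- spectrum[spectrum > 0]
  s_obs <- length(spectrum)
  f1 <- sum(spectrum == 1)
  f2 <- sum(spectrum == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon index (nats)
#'
#' `H = -sum p_i ln p_i` over the positive entries, with `0 ln 0 := 0`.
#'
#' @param x non-negative counts or proportions, sum > 0.
#' @return entropy in nats.
#' @export
shannon_index <- function(x) {
  if (any(x < 0) || anyNA(x)) stop("counts must be non-negative and finite")
  if (sum(x) == 0) stop("undefined for an all-zero vector")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Per-sample alpha diversity
#'
#' @param sample_reads named list of per-sample trimmed read data.frames.
#' @param threshold,depth,band as in [observed_otus()].
#' @return data.frame `sample_id`, `observed`, `chao1`, `shannon`, `F1`,
#'   `F2`.
#' @export
alpha_diversity <- function(sample_reads, threshold = 0.96, depth = 3000L,
                            band = 24L) {
  rows <- lapply(names(sample_reads), function(sid) {
    oo <- observed_otus(sample_reads[[sid]], threshold, depth, band)
    data.frame(sample_id = sid, observed = oo$observed,
               chao1 = chao1(oo$spectrum),
               shannon = shannon_index(oo$spectrum),
               F1 = sum(oo$spectrum == 1), F2 = sum(oo$spectrum == 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
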