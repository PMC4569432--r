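# Independent oracles and fixture builders shared across the suite.
# Oracles never call the package's alignment/clustering code paths.

# random ACGT string under the current RNG
rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# mutate exactly k positions of a sequence (substitutions only, so the
# optimal alignment is the unique gap-free diagonal and every aligner
# agrees on identity)
mutate_k <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# Biostrings overlap alignment with the package's scoring; returns the
# span identity, clustering (query-penalised) identity and coverage
bs_align <- function(q, r) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(q, r, type = "overlap",
                                      substitutionMatrix = sm,
                                      gapOpening = 5, gapExtension = 2)
  matches <- Biostrings::nmatch(pa)
  columns <- Biostrings::nchar(pa)
  qlen <- nchar(q)
  span <- Biostrings::width(Biostrings::pattern(pa))
  list(identity = matches / columns,
       gid = matches / (columns + qlen - span),
       coverage = span / qlen,
       score = Biostrings::score(pa))
}

# brute-force greedy clustering replaying the package's insertion order
# (descending length, ties by id), identities via the Biostrings oracle
greedy_oracle <- function(seqs, threshold) {
  ord <- order(-nchar(seqs), names(seqs))
  s <- seqs[ord]
  centroids <- integer(0)
  assign <- integer(length(s))
  for (i in seq_along(s)) {
    joined <- 0L
    for (ci in seq_along(centroids)) {
      if (bs_align(s[[i]], s[[centroids[ci]]])$gid >= threshold) {
        joined <- ci
        break
      }
    }
    if (joined == 0L) {
      centroids <- c(centroids, i)
      joined <- length(centroids)
    }
    assign[i] <- joined
  }
  stats::setNames(assign, names(s))
}

# exhaustive best-hit mapping oracle via Biostrings: the best hit is the
# highest-identity reference among those passing BOTH thresholds (degenerate
# short overlaps against unrelated references carry perfect span identity
# but near-zero coverage, so ranking across all references would be wrong)
map_oracle <- function(reads, refdb, min_identity = 0.96,
                       min_coverage = 0.90) {
  refdb <- refdb[order(names(refdb))]
  out <- t(vapply(reads$sequence, function(q) {
    res <- vapply(refdb, function(r) {
      a <- bs_align(q, r)
      c(a$identity, a$coverage)
    }, numeric(2))
    pass <- which(res[1, ] >= min_identity & res[2, ] >= min_coverage)
    if (!length(pass)) return(c(NA_real_, NA_real_, NA_real_))
    best <- unname(pass[order(-res[1, pass], -res[2, pass],
                              names(refdb)[pass])][1])
    c(best, unname(res[1, best]), unname(res[2, best]))
  }, numeric(3)))
  colnames(out) <- c("ref", "identity", "coverage")
  out
}

# naive ANOSIM with exhaustive enumeration of two-group assignments
anosim_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  r <- matrix(0, n, n)
  r[upper.tri(r)] <- rank(d[upper.tri(d)])
  stat <- function(g) {
    rw <- c(); rb <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (g[i] == g[j]) rw <- c(rw, r[i, j]) else rb <- c(rb, r[i, j])
    }
    (mean(rb) - mean(rw)) / (n * (n - 1) / 4)
  }
  R_obs <- stat(groups)
  n1 <- sum(groups == unique(groups)[1])
  sets <- utils::combn(n, n1)
  Rs <- apply(sets, 2, function(ix) {
    g <- rep("b", n); g[ix] <- "a"
    stat(g)
  })
  list(R = R_obs, p = mean(Rs >= R_obs - 1e-12))
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# Welch's t statistic/df/p via the textbook formulas
welch_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / m + vy / n
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / m)^2 / (m - 1) + (vy / n)^2 / (n - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# small read data.frame with constant qualities
make_reads <- function(seqs, q = 35, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%04d", seq_along(seqs))
  data.frame(id = ids, sequence = seqs,
             quality = vapply(nchar(seqs), function(L)
               paste(rep(intToUtf8(33 + q), L), collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

# a small abundance_table built directly from a counts matrix
make_table <- function(counts, groups, depth = 3000L, subject = NULL,
                       timepoint = NULL) {
  sheet <- data.frame(sample_id = colnames(counts),
                      subject_id = if (is.null(subject))
                        paste0("subj_", colnames(counts)) else subject,
                      group = groups,
                      timepoint = if (is.null(timepoint)) NA_integer_
                        else timepoint,
                      stringsAsFactors = FALSE)
  out <- list(counts = counts, depth = as.integer(depth), sheet = sheet,
              kind = ifelse(grepl("^rclust", rownames(counts)),
                            "rclust", "unmap_OTU"))
  class(out) <- "abundance_table"
  out
}
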