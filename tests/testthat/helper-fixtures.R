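# Independent brute-force oracle for the permutation CDF statistic:
# enumerates every distinct assignment of the label multiset and applies
# the standardized-max-deviation definition position by position.
oracle_s_exact <- function(x, y, sigma_floor = 1e-12) {
  o <- order(x)
  ys <- y[o]
  n <- length(y)
  n1 <- sum(y)
  cdf_real <- cumsum(ys) / n1
  idx <- utils::combn(n, n1)
  cdfs <- apply(idx, 2, function(i) {
    yy <- integer(n); yy[i] <- 1L
    cumsum(yy) / n1
  })
  mu <- rowMeans(cdfs)
  sdv <- apply(cdfs, 1, stats::sd)
  keep <- sdv >= sigma_floor
  max(abs(cdf_real - mu)[keep] / sdv[keep])
}

# O(n^2) pairwise-rank oracle for the AUC (ties counted half)
oracle_auc_pairs <- function(prob, y) {
  pos <- prob[y == 1]
  neg <- prob[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# wrap a complete numeric matrix into a peptide_table with generic metadata
make_table <- function(m, scale = "log2") {
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  peptide_table(m,
                peptide = sprintf("K.TST%04dR.A", seq_len(nrow(m))),
                protein_id = sprintf("T%03d|TST_HUMAN", seq_len(nrow(m))),
                scale = scale)
}

balanced_labels <- function(n_ctrl = 6, n_case = 6,
                            ids = sprintf("s%02d", seq_len(n_ctrl + n_case)))
  group_labels(c(rep(0L, n_ctrl), rep(1L, n_case)), ids)

ref_path <- function(f) system.file("extdata", f, package = "serumsig")
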