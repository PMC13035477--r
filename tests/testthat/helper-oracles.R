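# Independent oracles used across the suite. These deliberately use naive
# algorithms (triple loops, exhaustive search, explicit summation) so they
# stay independent of the package implementations they check.

# brute-force attraction: triple loop over senders, receivers, LR pairs
oracle_attraction <- function(vals, ids, registry) {
  n <- length(ids)
  lr <- paste(registry$ligand, registry$receptor, sep = "_")
  rows <- list()
  meta <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sc <- numeric(length(lr))
    for (k in seq_len(nrow(registry)))
      sc[k] <- sqrt(vals[registry$ligand[k], ids[i]] *
                      vals[registry$receptor[k], ids[j]])
    rows[[length(rows) + 1]] <- sc
    meta[[length(meta) + 1]] <- c(ids[i], ids[j])
  }
  m <- do.call(rbind, rows)
  colnames(m) <- lr
  list(scores = m,
       sender = vapply(meta, `[`, character(1), 1),
       receiver = vapply(meta, `[`, character(1), 2))
}

# O(n^2) mean pairwise Euclidean distance
oracle_mean_dist <- function(x) {
  n <- nrow(x)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sqrt(sum((x[i, ] - x[j, ])^2))
  tot / (n * (n - 1) / 2)
}

# brute-force k nearest neighbour composition
oracle_knn_composition <- function(xy, types, k) {
  n <- nrow(xy)
  utypes <- sort(unique(types))
  comp <- matrix(0, n, length(utypes), dimnames = list(NULL, utypes))
  for (i in seq_len(n)) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    d[i] <- Inf
    nn <- order(d)[seq_len(k)]
    tt <- table(factor(types[nn], levels = utypes))
    comp[i, ] <- as.numeric(tt) / k
  }
  comp
}

# two-sided Fisher exact p by explicit hypergeometric summation
# (same relative-error convention as stats::fisher.test)
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_          # margin: total "type"/deg
  k <- a + b           # margin: in neighborhood / target size
  n_tot <- a + b + c_ + d
  lo <- max(0, k - (n_tot - m))
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n_tot - m, k)
  p_obs <- dhyper(a, m, n_tot - m, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive Otsu: naive search over every histogram bin edge, computing
# class weights and means from the binned data for each candidate split
oracle_otsu <- function(values, n_bins = 256L) {
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  best <- -Inf
  best_thr <- NA
  for (split in 1:(n_bins - 1)) {
    n0 <- sum(counts[1:split])
    n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:split] * mids[1:split]) / n0
    mu1 <- sum(counts[(split + 1):n_bins] * mids[(split + 1):n_bins]) / n1
    w0 <- n0 / sum(counts)
    bcv <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (bcv > best * (1 + 1e-12)) { best <- bcv; best_thr <- breaks[split + 1] }
  }
  best_thr
}

# brute-force radius ligand-receptor proximity score
oracle_lr_score <- function(xy, lpos, rpos, radius) {
  n <- nrow(xy)
  score <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
    if (d <= radius && ((lpos[i] && rpos[j]) || (rpos[i] && lpos[j])))
      score[i] <- score[i] + 1L
  }
  score
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# rank-based AUC of score separating binary labels
auc_of <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label); n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# small helper: rLN-like profile whose ligands are carried only by stroma
stroma_only_profile <- function() {
  prof <- entity_profile("rLN")
  reg <- lr_registry()
  is_lig <- prof$programs$gene %in% reg$ligand
  strom <- compartment_of(prof$programs$cell_type) == "stromal"
  prof$programs <- prof$programs[!is_lig | strom, ]
  prof
}

# planted two-program pair matrix: follicular CXCL13-CXCR5 rows vs
# T-zone CCL19/CCL21-CCR7 rows over the bundled registry columns
make_planted_pairs <- function(n_per = 250, seed = 1, noise_sd = 0.3) {
  reg <- lr_registry()
  cols <- lr_pair_ids(reg)
  withr::with_seed(seed, {
    n <- 2 * n_per
    m <- matrix(abs(rnorm(n * length(cols), mean = 0.6, sd = noise_sd)),
                nrow = n, dimnames = list(NULL, cols))
    m[seq_len(n_per), "CXCL13_CXCR5"] <-
      abs(rnorm(n_per, 5, noise_sd))
    m[n_per + seq_len(n_per), "CCL19_CCR7"] <-
      abs(rnorm(n_per, 5, noise_sd))
    m[n_per + seq_len(n_per), "CCL21_CCR7"] <-
      abs(rnorm(n_per, 4, noise_sd))
    pairs <- data.frame(sender = sprintf("s%04d", seq_len(n)),
                        receiver = sprintf("r%04d", seq_len(n)),
                        sample_id = "sim")
    pm <- lymphochemnet:::pair_matrix(m, pairs)
    list(pm = pm, labels = rep(c("follicle", "t_zone"), each = n_per))
  })
}
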