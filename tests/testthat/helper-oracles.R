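# Independent brute-force oracles. These deliberately avoid the package's
# compiled k-mer engine and vectorized statistics: k-mers are handled as
# character strings, pairwise statistics by explicit enumeration.

library(data.table)

revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

canon_str <- function(s) {
  r <- revcomp_str(s)
  if (s <= r) s else r
}

# all valid canonical k-mers of seq, one per start position (NA if invalid)
brute_position_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  out <- character(n - k + 1)
  for (i in seq_len(n - k + 1)) {
    km <- substr(seq, i, i + k - 1)
    out[i] <- if (grepl("[^ACGT]", km)) NA_character_ else canon_str(km)
  }
  out
}

brute_kmer_set <- function(seqs, k) {
  unique(unlist(lapply(seqs, function(s) {
    v <- brute_position_kmers(s, k)
    v[!is.na(v)]
  })))
}

# per-window base-depth coverage sums (depth mode) for one sequence
brute_window_cov <- function(seq, set_strings, k, width) {
  n <- nchar(seq)
  depth <- integer(n)
  pk <- brute_position_kmers(seq, k)
  for (i in seq_along(pk)) {
    if (!is.na(pk[i]) && pk[i] %in% set_strings)
      depth[i:(i + k - 1)] <- depth[i:(i + k - 1)] + 1L
  }
  nwin <- ceiling(n / width)
  vapply(seq_len(nwin), function(w) {
    lo <- (w - 1) * width + 1
    hi <- min(w * width, n)
    sum(depth[lo:hi]) / (hi - lo + 1)
  }, numeric(1))
}

# per-window variation counts: maximal absent-runs over valid positions
brute_window_variations <- function(seq, set_strings, k, width) {
  n <- nchar(seq)
  pk <- brute_position_kmers(seq, k)
  nwin <- ceiling(n / width)
  counts <- integer(nwin)
  prev_absent_at <- -10L
  for (i in seq_along(pk)) {
    if (is.na(pk[i])) next
    if (!(pk[i] %in% set_strings)) {
      if (prev_absent_at != i - 1L) {
        w <- floor((i - 1) / width) + 1
        counts[w] <- counts[w] + 1L
      }
      prev_absent_at <- i
    }
  }
  counts
}

# windowed pi by explicit enumeration of all sample pairs
brute_window_pi <- function(sites, gt, width, chrom_lengths) {
  res <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = width)
    vals <- numeric(length(starts))
    for (w in seq_along(starts)) {
      lo <- starts[w]; hi <- min(lo + width, L)
      rows <- which(sites$chrom == ch & sites$pos > lo & sites$pos <= hi)
      tot <- 0
      for (r in rows) {
        g <- gt[r, ]
        g[g == 2L] <- NA_integer_
        g <- g[!is.na(g)]
        if (length(g) < 2) next
        num <- 0; np <- 0
        for (i in seq_len(length(g) - 1)) for (j in (i + 1):length(g)) {
          np <- np + 1
          if (g[i] != g[j]) num <- num + 1
        }
        tot <- tot + num / np
      }
      vals[w] <- tot / (hi - lo)
    }
    res[[ch]] <- vals
  }
  unlist(res, use.names = FALSE)
}

# per-site Weir-Cockerham theta computed from raw 0/1 vectors via the
# ANOVA sums of squares (haploid individuals, r = 2 populations)
brute_wc_theta <- function(x1, x2) {
  x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 1 || n2 < 1 || n1 + n2 < 3) return(NA_real_)
  p1 <- mean(x1); p2 <- mean(x2)
  pbar <- mean(c(x1, x2))
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2
  ssg <- sum((x1 - p1)^2) + sum((x2 - p2)^2)
  msg <- ssg / (n1 + n2 - 2)
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  denom <- msp + (nc - 1) * msg
  if (denom == 0) return(NA_real_)
  (msp - msg) / denom
}

# random small variant table over populations of haploid-coded samples
random_variant_table <- function(n_sites, samples, chrom = "c1",
                                 chrom_len = 1e5, p_missing = 0.1,
                                 seed = 1) {
  set.seed(seed)
  pos <- sort(sample(chrom_len, n_sites))
  gt <- matrix(sample(c(0L, 1L), n_sites * length(samples), replace = TRUE),
               n_sites, length(samples))
  gt[matrix(runif(length(gt)) < p_missing, nrow(gt))] <- NA_integer_
  ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
  alt <- ifelse(ref == "A", "G", "A")
  variant_table(data.table(chrom = chrom, pos = pos, ref = ref, alt = alt),
                gt, samples)
}

# tiny window_track builder for hand-crafted tracks
toy_track <- function(values, width = 1e6, chrom = "c1", n_sites = NULL) {
  lens <- setNames(length(values) * width, chrom)
  trk <- make_window_track(lens, width, value = 0)
  trk$value <- as.numeric(values)
  trk$n_sites <- if (is.null(n_sites)) rep(1L, length(values))
  else as.integer(n_sites)
  trk
}
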