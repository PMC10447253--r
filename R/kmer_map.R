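# Species-specific k-mer mapping: canonical k-mer sets, set differences,
# windowed specific-k-mer coverage of a recipient genome, and segment
# calling from paired donor/other coverage tracks.
#
# "Mapping full-length k-mers with no mismatches" is implemented as exact
# canonical-membership lookup: a genome position matches when the canonical
# form of the k-mer starting there is present in the set. Coverage is
# base-level depth (each matched k-mer covers its k bases), with a
# match-start count mode behind `mode = "starts"`.

as_char_seqs <- function(x) {
  if (inherits(x, "DNAStringSet")) return(setNames(as.character(x), names(x)))
  if (inherits(x, "XString")) return(as.character(x))
  if (is.character(x)) return(x)
  stop("expected sequences as DNAStringSet or character")
}

#' Count canonical k-mers
#'
#' Builds the set of distinct canonical k-mers (lexicographic min of each
#' k-mer and its reverse complement) over all input sequences or reads.
#' K-mers spanning non-ACGT symbols are skipped; sequences shorter than k
#' contribute nothing.
#'
#' @param x sequences: a `DNAStringSet`, character vector, or path(s) to
#'   FASTA/FASTQ files (gzipped or plain).
#' @param k odd k-mer size, 15-63 (default 51).
#' @param label free-text source label.
#' @return a `kmer_set`.
#' @export
count_kmers <- function(x, k = 51, label = "") {
  if (k %% 2 == 0 || k < 15 || k > 63)
    stop("k must be odd and within 15..63")
  if (is.character(x) && length(x) >= 1 && all(file.exists(x))) {
    seqs <- unlist(lapply(x, function(f) {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", f)) "fastq" else "fasta"
      as.character(Biostrings::readDNAStringSet(f, format = fmt))
    }))
  } else seqs <- as_char_seqs(x)
  structure(list(ptr = cpp_kmer_build(seqs, as.integer(k)),
                 k = as.integer(k), label = label),
            class = "kmer_set")
}

new_kmer_set <- function(ptr, k, label = "") {
  structure(list(ptr = ptr, k = as.integer(k), label = label),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set: %s canonical %d-mers%s\n",
              format(kmer_size(x), big.mark = ","), x$k,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Number of k-mers in a set
#' @param ks a `kmer_set`.
#' @export
kmer_size <- function(ks) cpp_kmer_size(ks$ptr)

#' k of a k-mer set
#' @param ks a `kmer_set`.
#' @export
kmer_k <- function(ks) ks$k

check_same_k <- function(a, b) {
  if (a$k != b$k) stop("k-mer sets have different k (", a$k, " vs ", b$k, ")")
}

#' Source-specific k-mers (set difference)
#'
#' Returns the k-mers of `set_a` absent from `set_b`.
#'
#' @param set_a,set_b `kmer_set`s with equal k.
#' @return a `kmer_set` holding `a \ b`.
#' @export
specific_kmers <- function(set_a, set_b) {
  check_same_k(set_a, set_b)
  new_kmer_set(cpp_kmer_setdiff(set_a$ptr, set_b$ptr), set_a$k,
               label = paste0(set_a$label, "-specific"))
}

#' Intersection of two k-mer sets
#' @param set_a,set_b `kmer_set`s with equal k.
#' @export
common_kmers <- function(set_a, set_b) {
  check_same_k(set_a, set_b)
  new_kmer_set(cpp_kmer_intersect(set_a$ptr, set_b$ptr), set_a$k, "common")
}

#' Union of two k-mer sets
#' @param set_a,set_b `kmer_set`s with equal k.
#' @export
union_kmers <- function(set_a, set_b) {
  check_same_k(set_a, set_b)
  new_kmer_set(cpp_kmer_union(set_a$ptr, set_b$ptr), set_a$k, "union")
}

#' Decode a k-mer set to character strings
#' @param ks a `kmer_set` (refuses sets above 10 million members).
#' @return sorted character vector of canonical k-mers.
#' @export
kmer_strings <- function(ks) cpp_kmer_decode(ks$ptr)

#' Membership test for k-mer strings
#' @param ks a `kmer_set`.
#' @param kmers character vector of k-mers (canonicalized before lookup);
#'   entries containing non-ACGT symbols return NA.
#' @export
kmer_contains <- function(ks, kmers) cpp_kmer_contains(ks$ptr, kmers)

#' Write a k-mer set as plain text
#'
#' One canonical k-mer per line after a `#k=<k> n=<count> label=<label>`
#' header line.
#'
#' @param ks a `kmer_set`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_kmers <- function(ks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#k=%d n=%.0f label=%s", ks$k, kmer_size(ks), ks$label),
             con)
  writeLines(kmer_strings(ks), con)
  invisible(path)
}

#' Read a k-mer set written by [write_kmers()]
#' @param path text file.
#' @return a `kmer_set`.
#' @export
read_kmers <- function(path) {
  lines <- readLines(path)
  m <- regmatches(lines[1], regexec("^#k=(\\d+) n=(\\d+) label=(.*)$", lines[1]))[[1]]
  if (length(m) != 4) stop("not a wheatscan k-mer set file: ", path)
  k <- as.integer(m[2])
  new_kmer_set(cpp_kmer_from_strings(lines[-1], k), k, label = m[4])
}

#' Windowed specific-k-mer coverage of a genome
#'
#' A position matches when its canonical k-mer is in `kmer_set`; in
#' `mode = "depth"` (default) each match adds 1 to the per-base depth of the
#' k bases it covers and the window value is the mean per-base depth
#' (window sum / true window width). `mode = "starts"` reports match-start
#' counts per window instead.
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param kmer_set a `kmer_set`.
#' @param width window width in bp (default 1 Mb).
#' @param mode `"depth"` or `"starts"`.
#' @return a `window_track`.
#' @export
window_specific_coverage <- function(genome, kmer_set, width = 1e6,
                                     mode = c("depth", "starts")) {
  mode <- match.arg(mode)
  seqs <- as_char_seqs(genome)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  trk <- make_window_track(setNames(nchar(seqs), names(seqs)), width, value = 0)
  for (ch in names(seqs)) {
    sums <- cpp_window_cov_sums(seqs[[ch]], kmer_set$ptr, width,
                                mode == "starts")
    rows <- which(trk$chrom == ch)
    stopifnot(length(rows) == length(sums))
    if (mode == "depth") {
      set(trk, rows, "value", sums / (trk$end[rows] - trk$start[rows]))
    } else {
      set(trk, rows, "value", sums)
    }
  }
  trk
}

#' Call introgression segments from donor/other k-mer coverage tracks
#'
#' Windows with donor coverage >= `min_donor_cov` and other-source coverage
#' <= `max_other_cov` are grouped into segments; segments separated by at
#' most `merge_gap` bp are merged; merged segments shorter than `min_len`
#' are dropped.
#'
#' @param donor_track,other_track `window_track`s on identical windows.
#' @param min_donor_cov minimum mean donor-specific coverage (default 5).
#' @param max_other_cov maximum mean other-specific coverage (default 1).
#' @param merge_gap maximum gap merged, in bp (default 1 Mb).
#' @param min_len minimum segment length in bp (default 50 kb).
#' @return data.table of segments (chrom, start, end, n_windows, score =
#'   mean donor coverage).
#' @export
call_kmer_segments <- function(donor_track, other_track,
                               min_donor_cov = 5, max_other_cov = 1,
                               merge_gap = 1e6, min_len = 5e4) {
  check_same_windows(donor_track, other_track)
  dt <- data.table(chrom = donor_track$chrom, start = donor_track$start,
                   end = donor_track$end, donor = donor_track$value,
                   other = other_track$value)
  dt <- dt[donor >= min_donor_cov & other <= max_other_cov]
  if (nrow(dt) == 0)
    return(data.table(chrom = character(), start = numeric(), end = numeric(),
                      n_windows = integer(), score = numeric()))
  setorder(dt, chrom, start)
  dt[, gap_break := c(TRUE, chrom[-1] != chrom[-.N] |
                        start[-1] - end[-.N] > merge_gap)]
  dt[, seg := cumsum(gap_break)]
  seg <- dt[, .(chrom = chrom[1], start = min(start), end = max(end),
                n_windows = .N, score = mean(donor)), by = seg][, seg := NULL][]
  seg[end - start >= min_len]
}
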