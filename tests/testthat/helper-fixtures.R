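# Small shared fixtures, all built in code.

toy_layout <- function(len = 10000, chroms = "chr1") {
  genome_layout(stats::setNames(rep(len, length(chroms)), chroms))
}

# binary track from 0-based half-open intervals on one chromosome
bt <- function(starts, ends, layout = toy_layout(), chr = "chr1",
               resolution = 1L) {
  binary_track(data.frame(chr = rep_len(chr, length(starts)),
                          start = starts, end = ends),
               layout, resolution = resolution)
}

# score track from 0-based half-open runs
st <- function(starts, ends, scores, layout = toy_layout(), chr = "chr1",
               resolution = 1L) {
  score_track(data.frame(chr = chr, start = starts, end = ends,
                         score = scores),
              layout, resolution = resolution)
}

# constant score track over a whole toy genome
const_track <- function(value, layout = toy_layout()) {
  st(0, layout$lengths[[1]], value, layout = layout)
}

# independent brute-force Bayes oracle for the annotation mixture
oracle_posterior <- function(pi, p, a) {
  num <- pi
  den0 <- 1 - pi
  for (i in seq_along(a)) {
    num <- num * (if (a[i] == 1) p[i, 2] else 1 - p[i, 2])
    den0 <- den0 * (if (a[i] == 1) p[i, 1] else 1 - p[i, 1])
  }
  num / (num + den0)
}

all_patterns <- function(K) {
  as.matrix(expand.grid(rep(list(0:1), K)))
}

# tiny sumstats table
toy_sumstats <- function(p, chr = "chr1", bp = seq_along(p) * 1000,
                         study = "toy", n = 10000) {
  sumstats(data.frame(snp = paste0("s", seq_along(p)), chr = chr, bp = bp,
                      p = p),
           study = study, n = n)
}
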