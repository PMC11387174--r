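# Shared fixtures, all built in code at test time.

# a small deterministic benchmark; cheap enough for many tests
small_benchmark <- function(seed = 7L, n_sites = 100L, noise_rate = 0.1,
                            L = 21L, motif = "GxAG") {
  spec <- synthetic_spec(n_transcripts = 20L, transcript_length = 600L,
                         n_positive_sites = n_sites, motif = motif,
                         noise_rate = noise_rate, seed = seed)
  make_benchmark(spec, L = L)
}

# random equal-length windows with G centre (for dedupe/split tests)
random_windows <- function(n, L = 11L, seed = 1L, label = "positive") {
  withr::with_seed(seed, {
    half <- (L - 1L) %/% 2L
    wins <- vapply(seq_len(n), function(i) {
      s <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
      s[half + 1L] <- "G"
      paste(s, collapse = "")
    }, character(1))
    data.frame(transcript_id = paste0("w", seq_len(n)),
               position = rep(100L, n), window = wins, label = label,
               stringsAsFactors = FALSE)
  })
}

# brute-force O(n^2) AUROC oracle: concordant pairs, ties counted 1/2
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# 2-D toy data: separable blobs far apart
separable_toy <- function(n = 40L, seed = 3L) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n, mean = 0, sd = 0.3), ncol = 2),
               matrix(rnorm(n, mean = 4, sd = 0.3), ncol = 2))
    list(x = x, y = rep(c("negative", "positive"), each = n / 2))
  })
}
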