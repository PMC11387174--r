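# Canonical encoder order; combined vectors always concatenate in this
# order no matter how the request was written.
ENCODER_ORDER <- c("OH", "NAC", "ANF", "PKC", "CP", "EIIP")

# Electron-ion interaction pseudopotentials of the four ribonucleotides.
EIIP_VALUES <- c(A = 0.1260, C = 0.1340, G = 0.0806, U = 0.1335, N = 0)

# Chemical-property triples: ring structure (purine = 1), functional group
# (amino = 1, keto = 0), hydrogen bonds (two = 1, three = 0).
CP_CODES <- matrix(
  c(1, 1, 1,   # A
    0, 1, 0,   # C
    1, 0, 0,   # G
    0, 0, 1,   # U
    0, 0, 0),  # N
  nrow = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "U", "N"), c("ring", "group", "hbond")))

#' Encoder configuration
#'
#' Holds the constants and tunables shared by the six encoders. The EIIP
#' values and chemical-property codes default to the published constants
#' and rarely need changing; the pseudo k-tuple composition (PKC) settings
#' are genuinely tunable.
#'
#' @param eiip_values named numeric vector of per-base EIIP constants
#'   (must cover A, C, G, U; N is always 0).
#' @param cp_codes 4x3 (or 5x3) 0/1 matrix of chemical-property codes with
#'   rownames A, C, G, U (N row added automatically as zeros).
#' @param pkc_k k-tuple size for PKC (default 2).
#' @param pkc_lambda number of sequence-order correlation tiers (default 2;
#'   0 reduces PKC to plain k-tuple composition).
#' @param pkc_weight weight of the correlation terms, in (0, 1]
#'   (default 0.1).
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(eiip_values = EIIP_VALUES[c("A", "C", "G", "U")],
                           cp_codes = CP_CODES[c("A", "C", "G", "U"), ],
                           pkc_k = 2L, pkc_lambda = 2L, pkc_weight = 0.1) {
  stopifnot(all(c("A", "C", "G", "U") %in% names(eiip_values)),
            is.matrix(cp_codes), ncol(cp_codes) == 3L,
            all(c("A", "C", "G", "U") %in% rownames(cp_codes)),
            pkc_k >= 1L, pkc_lambda >= 0L,
            pkc_weight > 0, pkc_weight <= 1)
  eiip <- c(eiip_values[c("A", "C", "G", "U")], N = 0)
  cp <- rbind(cp_codes[c("A", "C", "G", "U"), , drop = FALSE],
              N = c(0, 0, 0))
  structure(list(eiip_values = eiip, cp_codes = cp,
                 pkc_k = as.integer(pkc_k),
                 pkc_lambda = as.integer(pkc_lambda),
                 pkc_weight = pkc_weight),
            class = "encoder_config")
}

# split a sequence string into a character vector of bases, validated
seq_chars <- function(seq) {
  s <- strsplit(normalize_rna(seq), "")[[1]]
  if (length(s) == 0L) stop("empty sequence")
  s
}

# lexicographic k-tuples over ACGU, e.g. k=2: AA AC AG AU CA ... UU
ktuple_names <- function(k) {
  grid <- expand.grid(rep(list(c("A", "C", "G", "U")), k),
                      stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse for lexicographic
  sort(apply(grid, 1L, paste, collapse = ""))
}

#' One-hot (binary) encoding
#'
#' Each base becomes a 4-bit indicator in channel order A, C, G, U;
#' `N` encodes as all zeros. Output length is 4L for a sequence of
#' length L.
#'
#' @param seq a single RNA sequence (character scalar).
#' @return Numeric vector of length `4 * nchar(seq)`.
#' @export
encode_onehot <- function(seq) {
  s <- seq_chars(seq)
  channels <- c("A", "C", "G", "U")
  out <- vapply(s, function(b) as.numeric(channels == b), numeric(4))
  as.vector(out)
}

#' Dinucleotide (nucleic acid) composition
#'
#' Relative frequencies of the 16 overlapping dinucleotides AA..UU in
#' lexicographic order. Dinucleotides containing `N` are excluded from
#' both numerator and denominator; if no valid dinucleotide remains the
#' vector is all zeros.
#'
#' @param seq a single RNA sequence of length >= 2.
#' @return Numeric vector of length 16, summing to 1 for N-free input.
#' @export
encode_nac <- function(seq) {
  ktuple_composition(seq, k = 2L)
}

# overlapping k-tuple relative frequencies, N-containing tuples dropped
ktuple_composition <- function(seq, k) {
  s <- seq_chars(seq)
  L <- length(s)
  if (L < k) stop("sequence shorter than tuple size k = ", k)
  names_k <- ktuple_names(k)
  tuples <- vapply(seq_len(L - k + 1L),
                   function(i) paste(s[i:(i + k - 1L)], collapse = ""),
                   character(1))
  tuples <- tuples[!grepl("N", tuples, fixed = TRUE)]
  out <- stats::setNames(numeric(length(names_k)), names_k)
  if (length(tuples)) {
    tab <- table(tuples)
    out[names(tab)] <- as.numeric(tab) / length(tuples)
  }
  out
}

#' Accumulated nucleotide frequency
#'
#' Position i carries the relative frequency of the base at i within the
#' prefix s[1..i] (cumulative count divided by i). `N` positions encode
#' as 0.
#'
#' @param seq a single RNA sequence.
#' @return Numeric vector of length `nchar(seq)`.
#' @export
encode_anf <- function(seq) {
  s <- seq_chars(seq)
  counts <- c(A = 0L, C = 0L, G = 0L, U = 0L, N = 0L)
  out <- numeric(length(s))
  for (i in seq_along(s)) {
    counts[s[i]] <- counts[s[i]] + 1L
    out[i] <- if (s[i] == "N") 0 else counts[[s[i]]] / i
  }
  out
}

#' Chemical-property encoding
#'
#' Per-base 3-bit code for ring structure, functional group and
#' hydrogen-bonding capacity: A = (1,1,1), C = (0,1,0), G = (1,0,0),
#' U = (0,0,1); N encodes as (0,0,0).
#'
#' @param seq a single RNA sequence.
#' @param config an [encoder_config()].
#' @return Numeric vector of length `3 * nchar(seq)`.
#' @export
encode_cp <- function(seq, config = encoder_config()) {
  s <- seq_chars(seq)
  as.vector(t(config$cp_codes[s, , drop = FALSE]))
}

#' Electron-ion interaction pseudopotential encoding
#'
#' Per-base EIIP constant: A = 0.1260, C = 0.1340, G = 0.0806,
#' U = 0.1335; N encodes as 0.
#'
#' @param seq a single RNA sequence.
#' @param config an [encoder_config()].
#' @return Numeric vector of length `nchar(seq)`.
#' @export
encode_eiip <- function(seq, config = encoder_config()) {
  s <- seq_chars(seq)
  unname(config$eiip_values[s])
}

#' Pseudo k-tuple composition (type-I PseKNC)
#'
#' The first 4^k entries are the normalized overlapping k-tuple
#' frequencies damped by the sequence-order factor,
#' d_u = f_u / (1 + w * sum_j theta_j); the last lambda entries are
#' d_(4^k + j) = w * theta_j / (1 + w * sum_j theta_j). The tier-j
#' correlation theta_j is the mean squared EIIP difference between bases
#' j apart:
#' theta_j = (1/(L-j)) * sum_i (EIIP(s_i) - EIIP(s_(i+j)))^2.
#' EIIP is the single physicochemical property used. The full vector sums
#' to 1 for N-free input.
#'
#' @param seq a single RNA sequence with `nchar(seq) > pkc_k + pkc_lambda`.
#' @param config an [encoder_config()]; fields `pkc_k`, `pkc_lambda`,
#'   `pkc_weight` control the encoding.
#' @return Numeric vector of length `4^pkc_k + pkc_lambda`.
#' @export
encode_pkc <- function(seq, config = encoder_config()) {
  k <- config$pkc_k
  lambda <- config$pkc_lambda
  w <- config$pkc_weight
  s <- seq_chars(seq)
  L <- length(s)
  if (L <= k + lambda) {
    stop("PKC needs sequence length > k + lambda = ", k + lambda,
         ", got ", L)
  }
  f <- ktuple_composition(seq, k)
  theta <- numeric(lambda)
  if (lambda > 0L) {
    e <- unname(config$eiip_values[s])
    for (j in seq_len(lambda)) {
      d <- e[seq_len(L - j)] - e[(1L + j):L]
      theta[j] <- mean(d^2)
    }
  }
  denom <- 1 + w * sum(theta)
  c(f / denom, if (lambda > 0L)
    stats::setNames(w * theta / denom, paste0("lambda", seq_len(lambda))))
}

# resolve and order a requested encoder subset
resolve_combo <- function(encoders) {
  if (length(encoders) == 0L) stop("empty encoder set")
  encoders <- toupper(encoders)
  bad <- setdiff(encoders, ENCODER_ORDER)
  if (length(bad)) {
    stop("unknown encoder(s): ", paste(bad, collapse = ", "),
         " (available: ", paste(ENCODER_ORDER, collapse = ", "), ")")
  }
  ENCODER_ORDER[ENCODER_ORDER %in% encoders]
}

#' Combined feature encoding
#'
#' Concatenates the requested encoders in the canonical order OH, NAC,
#' ANF, PKC, CP, EIIP (regardless of request order). The result carries a
#' `blocks` attribute naming each encoder block and its length.
#'
#' @param seq a single RNA sequence.
#' @param encoders non-empty subset of
#'   `c("OH","NAC","ANF","PKC","CP","EIIP")`.
#' @param config an [encoder_config()].
#' @return Numeric vector with attribute `blocks` (named integer vector of
#'   block lengths in concatenation order).
#' @export
encode_combined <- function(seq, encoders = c("NAC", "EIIP", "CP"),
                            config = encoder_config()) {
  combo <- resolve_combo(encoders)
  parts <- lapply(combo, function(e) {
    switch(e,
           OH   = encode_onehot(seq),
           NAC  = encode_nac(seq),
           ANF  = encode_anf(seq),
           PKC  = encode_pkc(seq, config),
           CP   = encode_cp(seq, config),
           EIIP = encode_eiip(seq, config))
  })
  out <- unlist(parts, use.names = FALSE)
  attr(out, "blocks") <- stats::setNames(lengths(parts), combo)
  out
}

#' Encode a set of labeled windows into a feature matrix
#'
#' One row per window; columns follow the block layout of
#' [encode_combined()]. The matrix carries attributes `blocks`, `combo`
#' and `window_length` which trained models use to reject mismatched
#' inputs.
#'
#' @param windows data.frame with a `window` column (and usually `label`),
#'   or a character vector of equal-length sequences.
#' @param encoders encoder subset, as in [encode_combined()].
#' @param config an [encoder_config()].
#' @return Numeric matrix with one row per window.
#' @export
encode_windows <- function(windows, encoders = c("NAC", "EIIP", "CP"),
                           config = encoder_config()) {
  seqs <- if (is.data.frame(windows)) windows$window else as.character(windows)
  if (length(seqs) == 0L) stop("no windows to encode")
  L <- unique(nchar(seqs))
  if (length(L) > 1L) stop("windows have mixed lengths: ",
                           paste(L, collapse = ", "))
  combo <- resolve_combo(encoders)
  first <- encode_combined(seqs[1L], combo, config)
  blocks <- attr(first, "blocks")
  mat <- matrix(NA_real_, nrow = length(seqs), ncol = length(first))
  mat[1L, ] <- first
  if (length(seqs) > 1L) {
    for (i in 2:length(seqs)) {
      mat[i, ] <- encode_combined(seqs[i], combo, config)
    }
  }
  colnames(mat) <- unlist(lapply(names(blocks), function(b)
    paste0(b, ".", seq_len(blocks[[b]]))), use.names = FALSE)
  structure(mat, blocks = blocks, combo = combo, window_length = L)
}
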